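#' Construct a genome object
#'
#' A genome is an organism label plus an ordered set of named contig
#' sequences. Sequences are upper-cased and any character outside
#' `A,C,G,T,N` is replaced by `N`.
#'
#' @param organism single character label identifying the organism.
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#'   of contig sequences; names must be unique and non-empty.
#' @return An object of class `genome` with elements `organism` and
#'   `sequences` (a `DNAStringSet`).
#' @examples
#' g <- genome("orgA", c(chr1 = "ACGTACGT"))
#' @export
genome <- function(organism, sequences) {
  stopifnot(is.character(organism), length(organism) == 1, nzchar(organism))
  seqs <- clean_sequences(sequences)
  if (length(seqs) < 1)
    stop("genome must contain at least one contig")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all contigs must be named")
  if (anyDuplicated(nm))
    stop("duplicate contig name: ", nm[duplicated(nm)][1])
  if (any(Biostrings::width(seqs) < 1))
    stop("contig sequences must have length >= 1")
  structure(list(organism = organism, sequences = seqs), class = "genome")
}

clean_sequences <- function(sequences) {
  if (is.character(sequences)) {
    sequences <- toupper(sequences)
    sequences <- gsub("[^ACGTN]", "N", sequences)
    Biostrings::DNAStringSet(sequences)
  } else {
    x <- Biostrings::DNAStringSet(sequences)
    chr <- toupper(as.character(x))
    chr <- gsub("[^ACGTN]", "N", chr)
    out <- Biostrings::DNAStringSet(chr)
    names(out) <- names(x)
    out
  }
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$organism, "-", length(x$sequences), "contig(s),",
      sum(Biostrings::width(x$sequences)), "bp\n")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' @param path path to a FASTA file (optionally gzipped).
#' @param organism organism label; defaults to the file base name.
#' @return A [genome] object, contigs in file order.
#' @export
read_fasta <- function(path, organism = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(organism))
    organism <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e)))
  if (length(seqs) == 0)
    stop("FASTA format error: no records in ", path)
  # keep only the identifier part of the header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("FASTA format error: duplicate contig name '",
         names(seqs)[duplicated(names(seqs))][1], "' in ", path)
  genome(organism, seqs)
}

#' Write a genome (or combined reference) to FASTA
#'
#' @param x a [genome] or [combined_reference] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- if (inherits(x, "combined_reference")) x$sequences else x$sequences
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}

#' Read annotated features from a GFF3 file
#'
#' Only rows whose `type` column is one of `categories` are returned;
#' coordinates are kept 1-based inclusive as in the file.
#'
#' @param path path to a GFF3 file.
#' @param categories feature types to keep (default the three counted
#'   classes: tRNA, rRNA, CDS).
#' @return A data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `category`, `feature_id`.
#' @export
read_gff3 <- function(path, categories = c("tRNA", "rRNA", "CDS")) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 format error in ", path, ": ",
                             conditionMessage(e)))
  keep <- as.character(gr$type) %in% categories
  gr <- gr[keep]
  if (length(gr) == 0)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      category = character(), feature_id = character(),
                      stringsAsFactors = FALSE))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("GFF3 format error: feature with unknown strand symbol")
  id <- gr$ID
  if (is.null(id)) id <- rep(NA_character_, length(gr))
  id <- ifelse(is.na(id) | !nzchar(id),
               paste0("feature_", seq_along(gr)), id)
  data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr),
             strand = strand,
             category = as.character(gr$type),
             feature_id = as.character(id),
             stringsAsFactors = FALSE)
}

#' Write a feature table to GFF3
#'
#' @param features feature data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  validate_features(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start, end = features$end),
    strand = features$strand)
  gr$type <- features$category
  gr$ID <- features$feature_id
  gr$source <- "dualmapr"
  gr$phase <- ifelse(features$category == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_features <- function(features, genome = NULL) {
  stopifnot(is.data.frame(features))
  need <- c("contig", "start", "end", "strand", "category", "feature_id")
  if (!all(need %in% names(features)))
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  if (nrow(features) == 0) return(invisible(features))
  if (any(features$start < 1) || any(features$start > features$end))
    stop("invalid feature coordinates: need 1 <= start <= end")
  if (any(!features$strand %in% c("+", "-")))
    stop("unknown strand symbol in feature table")
  if (any(!features$category %in% c("tRNA", "rRNA", "CDS")))
    stop("feature category must be one of tRNA, rRNA, CDS")
  if (!is.null(genome)) {
    len <- stats::setNames(Biostrings::width(genome$sequences),
                           names(genome$sequences))
    if (any(!features$contig %in% names(len)))
      stop("feature references unknown contig: ",
           setdiff(features$contig, names(len))[1])
    if (any(features$end > len[features$contig]))
      stop("feature extends beyond contig end")
  }
  invisible(features)
}

#' Concatenate two genomes into a combined (chimeric) reference
#'
#' The combined reference holds the contigs of `a` followed by those of
#' `b`, together with a provenance map recording which organism each
#' contig came from. Contig names that occur in both genomes are prefixed
#' with `"<organism>|"` so a collision can never silently merge contigs.
#'
#' @param a,b [genome] objects with distinct organism labels.
#' @return An object of class `combined_reference` with elements
#'   `sequences` (DNAStringSet), `provenance` (named character:
#'   contig name -> organism) and `organisms` (length-2 character).
#' @export
combine_references <- function(a, b) {
  stopifnot(inherits(a, "genome"), inherits(b, "genome"))
  if (identical(a$organism, b$organism))
    stop("the two genomes must have distinct organism labels")
  na <- names(a$sequences)
  nb <- names(b$sequences)
  clash <- intersect(na, nb)
  if (length(clash)) {
    na[na %in% clash] <- paste0(a$organism, "|", na[na %in% clash])
    nb[nb %in% clash] <- paste0(b$organism, "|", nb[nb %in% clash])
  }
  seqs <- c(a$sequences, b$sequences)
  names(seqs) <- c(na, nb)
  prov <- stats::setNames(c(rep(a$organism, length(na)),
                            rep(b$organism, length(nb))),
                          c(na, nb))
  structure(list(sequences = seqs, provenance = prov,
                 organisms = c(a$organism, b$organism)),
            class = "combined_reference")
}

#' @export
print.combined_reference <- function(x, ...) {
  cat("<combined reference>", paste(x$organisms, collapse = " + "), "-",
      length(x$sequences), "contig(s),",
      sum(Biostrings::width(x$sequences)), "bp\n")
  invisible(x)
}

#' Write / read a combined reference with its provenance sidecar
#'
#' The sequences go to a FASTA file and the contig-to-organism map to a
#' two-column TSV sidecar (`contig`, `organism`), so provenance survives
#' export to third-party tools.
#'
#' @param x a [combined_reference].
#' @param path FASTA output path; the sidecar is written to
#'   `paste0(path, ".provenance.tsv")` unless `sidecar` is given.
#' @param sidecar optional sidecar path.
#' @return `path`, invisibly (for the writer); a `combined_reference`
#'   (for the reader).
#' @export
write_combined_reference <- function(x, path, sidecar = NULL) {
  stopifnot(inherits(x, "combined_reference"))
  if (is.null(sidecar)) sidecar <- paste0(path, ".provenance.tsv")
  Biostrings::writeXStringSet(x$sequences, filepath = path,
                              format = "fasta")
  utils::write.table(
    data.frame(contig = names(x$provenance),
               organism = unname(x$provenance)),
    sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_combined_reference
#' @export
read_combined_reference <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- paste0(path, ".provenance.tsv")
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
  if (!setequal(tab$contig, names(seqs)))
    stop("provenance sidecar does not match FASTA contig names")
  prov <- stats::setNames(tab$organism, tab$contig)[names(seqs)]
  orgs <- unique(unname(prov))
  if (length(orgs) != 2)
    stop("combined reference must contain exactly two organisms")
  structure(list(sequences = clean_sequences(seqs), provenance = prov,
                 organisms = orgs),
            class = "combined_reference")
}

#' Read / write FASTQ libraries
#'
#' A read library is represented as a plain data.frame with columns
#' `read_id`, `sequence` and `quality`. Read names are preserved verbatim
#' (they carry the simulator's truth tags).
#'
#' @param path FASTQ file path (optionally gzipped).
#' @return `read_fastq`: a data.frame of class `read_library`;
#'   `write_fastq`: `path`, invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # strict 4-line parsing: truncated or inconsistent records must fail
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0)
    return(read_library(character(), character(), character()))
  if (length(lines) %% 4 != 0)
    stop("FASTQ format error in ", path, ": truncated record")
  i <- seq(1, length(lines), by = 4)
  if (any(!startsWith(lines[i], "@")) ||
      any(!startsWith(lines[i + 2], "+")))
    stop("FASTQ format error in ", path, ": malformed record header")
  seqs <- lines[i + 1]
  quals <- lines[i + 3]
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ format error in ", path,
         ": sequence and quality lengths differ")
  read_library(substring(lines[i], 2), seqs, quals)
}

#' @rdname read_fastq
#' @param reads a `read_library` data.frame.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_library(reads)
  if (nrow(reads) == 0) {
    # writeXStringSet handles the empty set, but be explicit
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Build a read library object
#'
#' @param read_id,sequence,quality character vectors of equal length.
#' @return data.frame of class `read_library`.
#' @export
read_library <- function(read_id, sequence, quality = NULL) {
  if (is.null(quality))
    quality <- vapply(nchar(sequence),
                      function(n) paste(rep("I", n), collapse = ""), "")
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  if (any(nchar(sequence) != nchar(quality)))
    stop("FASTQ format error: sequence and quality lengths differ")
  if (anyDuplicated(read_id))
    stop("duplicate read names in library")
  structure(data.frame(read_id = as.character(read_id),
                       sequence = toupper(as.character(sequence)),
                       quality = as.character(quality),
                       stringsAsFactors = FALSE),
            class = c("read_library", "data.frame"))
}

as_read_library <- function(x) {
  if (inherits(x, "read_library")) return(x)
  stopifnot(is.data.frame(x),
            all(c("read_id", "sequence", "quality") %in% names(x)))
  read_library(x$read_id, x$sequence, x$quality)
}

#' Drop reads shorter than a minimum length
#'
#' The only trimming rule applied by this package: reads shorter than
#' `min_length` nucleotides (default 20) are removed.
#'
#' @param reads a `read_library`.
#' @param min_length minimum retained read length in nucleotides.
#' @export
trim_short_reads <- function(reads, min_length = 20) {
  reads <- as_read_library(reads)
  reads[nchar(reads$sequence) >= min_length, , drop = FALSE]
}
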