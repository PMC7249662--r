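#' Mapping parameter set
#'
#' Admissibility of a placement is controlled by two fractions: the
#' *minimum length fraction* (aligned read bases / read length) and the
#' *minimum similarity fraction* (matching bases / alignment columns).
#' The defaults, 0.8 and 0.8, are the permissive regime commonly used for
#' mixed eukaryote libraries; `min_length_fraction = 0.9` with
#' `min_similarity_fraction = 0.8` is the stricter regime typical for
#' bacterial libraries.
#'
#' @param min_length_fraction smallest admissible fraction of a read's
#'   bases included in the alignment, in (0, 1].
#' @param min_similarity_fraction smallest admissible fraction of
#'   identical bases among aligned columns, in (0, 1].
#' @param max_hits maximum number of placements reported per read (the
#'   admissible-placement count is tracked before capping).
#' @param kmer_size exact-seed length; must be at least 8.
#' @param max_seed_extensions performance guard: at most this many merged
#'   seed regions are extended per read and strand.
#' @param paired treat input as read pairs.
#' @param insert_min,insert_max admissible outer insert size for a proper
#'   pair (paired mode only), in base pairs.
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(min_length_fraction = 0.8,
                           min_similarity_fraction = 0.8,
                           max_hits = 10,
                           kmer_size = 15,
                           max_seed_extensions = 50,
                           paired = FALSE,
                           insert_min = 100,
                           insert_max = 600) {
  stopifnot(min_length_fraction > 0, min_length_fraction <= 1,
            min_similarity_fraction > 0, min_similarity_fraction <= 1,
            max_hits >= 1, kmer_size >= 1, max_seed_extensions >= 1,
            insert_min <= insert_max)
  structure(list(min_length_fraction = min_length_fraction,
                 min_similarity_fraction = min_similarity_fraction,
                 max_hits = as.integer(max_hits),
                 kmer_size = as.integer(kmer_size),
                 max_seed_extensions = as.integer(max_seed_extensions),
                 paired = isTRUE(paired),
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max)),
            class = "mapping_params")
}

reference_seqs <- function(reference) {
  if (inherits(reference, "genome") ||
      inherits(reference, "combined_reference"))
    return(reference$sequences)
  stop("reference must be a genome or combined_reference")
}

#' Build an exact k-mer index over a reference
#'
#' Seeds are exact k-mers; lookups resolve both strands (a hit on the
#' reverse complement of the query k-mer is reported on the `-` strand).
#'
#' @param reference a [genome] or [combined_reference].
#' @param k seed length (>= 8; seeds shorter than 8 are too unspecific).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(reference, k = 15) {
  seqs <- reference_seqs(reference)
  ptr <- cpp_build_index(names(seqs), as.character(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), reference = reference),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("<k-mer index> k =", info$k, "over", length(info$contigs),
      "contig(s),", format(info$n_kmers, big.mark = ","),
      "distinct k-mers\n")
  invisible(x)
}

#' Look up one k-mer in an index
#'
#' @param index a [build_index()] result.
#' @param kmer a character k-mer of the index's seed length.
#' @return data.frame with columns `contig`, `pos` (1-based), `strand`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"))
  cpp_lookup_kmer(index$ptr, toupper(kmer))
}

status_from_counts <- function(n) {
  ifelse(n == 0L, "unmapped", ifelse(n == 1L, "unique", "multi"))
}

#' Map a batch of reads against an indexed reference
#'
#' Seed-and-extend mapping: exact k-mer seeds on both strands are grouped
#' into candidate regions, each region is aligned by a read-clipped,
#' reference-local dynamic program, and every placement satisfying both
#' admissibility fractions is reported (deduplicated to non-overlapping
#' loci, best score first, capped at `max_hits`).
#'
#' @param reads a `read_library` data.frame (or character vector of
#'   sequences, in which case ids are generated).
#' @param index a [build_index()] result.
#' @param params a [mapping_params()] list.
#' @return An object of class `mapping_set`: list with `read_id`,
#'   `status` (`unique`/`multi`/`unmapped`), `n_admissible`,
#'   `broken_pair` and a `placements` data.frame (one row per reported
#'   placement, `read` column indexes into `read_id`).
#' @export
map_reads <- function(reads, index, params = mapping_params()) {
  stopifnot(inherits(index, "kmer_index"))
  if (is.character(reads))
    reads <- read_library(paste0("read_", seq_along(reads)), reads)
  reads <- as_read_library(reads)
  res <- cpp_map_reads(reads$sequence, index$ptr,
                       params$min_length_fraction,
                       params$min_similarity_fraction,
                       params$max_hits, params$max_seed_extensions)
  if (any(res$too_short))
    warning(sum(res$too_short), " read(s) shorter than the seed length ",
            "were left unmapped")
  info <- cpp_index_info(index$ptr)
  structure(list(read_id = reads$read_id,
                 contig_lengths = stats::setNames(as.integer(info$lengths),
                                                  as.character(info$contigs)),
                 status = status_from_counts(res$n_admissible),
                 n_admissible = res$n_admissible,
                 broken_pair = rep(FALSE, nrow(reads)),
                 placements = res$placements,
                 params = params),
            class = "mapping_set")
}

#' @export
print.mapping_set <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("unique", "multi", "unmapped")))
  cat("<mapping set>", length(x$read_id), "read(s):",
      tab[["unique"]], "unique,", tab[["multi"]], "multi,",
      tab[["unmapped"]], "unmapped\n")
  invisible(x)
}

#' Map a single read
#'
#' @param read a single character sequence or one-row `read_library`.
#' @inheritParams map_reads
#' @return An object of class `mapping_result`: list with `read_id`,
#'   `placements`, `status`, `n_admissible`, `broken_pair`.
#' @export
map_read <- function(read, index, params = mapping_params()) {
  if (is.character(read)) read <- read_library("read_1", read)
  ms <- map_reads(read, index, params)
  mapping_result_from_set(ms, 1L)
}

mapping_result_from_set <- function(ms, i) {
  pl <- ms$placements[ms$placements$read == i, , drop = FALSE]
  pl$read <- NULL
  rownames(pl) <- NULL
  structure(list(read_id = ms$read_id[i], placements = pl,
                 status = ms$status[i], n_admissible = ms$n_admissible[i],
                 broken_pair = ms$broken_pair[i]),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping result>", x$read_id, "-", x$status,
      sprintf("(%d admissible placement(s))", x$n_admissible),
      if (x$broken_pair) "[broken pair]" else "", "\n")
  if (nrow(x$placements)) print(x$placements)
  invisible(x)
}

#' Exhaustive reference mapping (validation aligner)
#'
#' Maps a single read by scanning every reference position with a full,
#' unseeded dynamic program. Quadratic in reference length; intended for
#' validating the seed-and-extend mapper and for tiny references.
#'
#' @param read a single character sequence.
#' @param reference a [genome] or [combined_reference].
#' @param params a [mapping_params()]; seeding fields are ignored.
#' @return A `mapping_result`, as [map_read()].
#' @export
map_read_exhaustive <- function(read, reference,
                                params = mapping_params()) {
  seqs <- reference_seqs(reference)
  res <- cpp_oracle_map(toupper(read), names(seqs), as.character(seqs),
                        params$min_length_fraction,
                        params$min_similarity_fraction, params$max_hits)
  structure(list(read_id = "read_1", placements = res$placements,
                 status = status_from_counts(res$n_admissible),
                 n_admissible = res$n_admissible, broken_pair = FALSE),
            class = "mapping_result")
}

#' Map a read pair
#'
#' Mates are mapped independently; if some placement pair lies on one
#' contig, on opposite strands in forward/reverse orientation, with an
#' outer insert within `params$insert_min..insert_max`, the placements of
#' each mate are restricted to those participating in a proper pair.
#' Otherwise both mates keep their independent placements and are marked
#' as broken pairs; broken-pair reads are retained downstream.
#'
#' @param read1,read2 single character sequences (mate 2 as sequenced,
#'   i.e. on the opposite strand of the fragment).
#' @inheritParams map_reads
#' @return list of two `mapping_result` objects (`mate1`, `mate2`).
#' @export
map_pair <- function(read1, read2, index, params = mapping_params()) {
  r1 <- map_read(read1, index, params)
  r2 <- map_read(read2, index, params)
  p1 <- r1$placements
  p2 <- r2$placements
  proper1 <- logical(nrow(p1))
  proper2 <- logical(nrow(p2))
  if (nrow(p1) && nrow(p2)) {
    for (i in seq_len(nrow(p1))) {
      for (j in seq_len(nrow(p2))) {
        if (p1$contig[i] != p2$contig[j]) next
        if (p1$strand[i] == p2$strand[j]) next
        # forward/reverse orientation: the '+' mate starts at or left of
        # the '-' mate; outer insert spans '+' start to '-' end
        if (p1$strand[i] == "+") {
          pp_start <- p1$start[i]; pm_start <- p2$start[j]
          pm_end <- p2$end[j]
        } else {
          pp_start <- p2$start[j]; pm_start <- p1$start[i]
          pm_end <- p1$end[i]
        }
        insert <- pm_end - pp_start + 1
        if (pp_start <= pm_start && insert >= params$insert_min &&
            insert <= params$insert_max) {
          proper1[i] <- TRUE
          proper2[j] <- TRUE
        }
      }
    }
  }
  if (any(proper1)) {
    r1$placements <- p1[proper1, , drop = FALSE]
    r2$placements <- p2[proper2, , drop = FALSE]
    r1$n_admissible <- nrow(r1$placements)
    r2$n_admissible <- nrow(r2$placements)
    r1$status <- status_from_counts(r1$n_admissible)
    r2$status <- status_from_counts(r2$n_admissible)
  } else {
    r1$broken_pair <- TRUE
    r2$broken_pair <- TRUE
  }
  list(mate1 = r1, mate2 = r2)
}

#' Reverse-complement a nucleotide string
#'
#' @param x character vector of sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write mapping results as SAM
#'
#' Emits mandatory SAM fields plus `NH` (admissible hit count) and, when
#' an organism attribution is supplied, `XO` (assigned organism). The
#' CIGAR places any indel columns as a single block before the final
#' aligned base; per-column gap placement is not tracked by the aligner.
#'
#' @param ms a `mapping_set` from [map_reads()].
#' @param reads the `read_library` that was mapped.
#' @param path output SAM path.
#' @param organism optional character vector (one per read) with the
#'   organism attribution, written as `XO:Z:` tag.
#' @return `path`, invisibly.
#' @export
write_sam <- function(ms, reads, path, organism = NULL) {
  stopifnot(inherits(ms, "mapping_set"))
  reads <- as_read_library(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  info <- unique(ms$placements$contig)
  # header needs contig lengths; take them from the index if recorded
  if (!is.null(ms$contig_lengths)) {
    for (nm in names(ms$contig_lengths))
      writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, ms$contig_lengths[[nm]]),
                 con)
  } else {
    for (nm in info) writeLines(sprintf("@SQ\tSN:%s\tLN:0", nm), con)
  }
  writeLines("@PG\tID:dualmapr\tPN:dualmapr", con)
  pl <- ms$placements
  for (i in seq_along(ms$read_id)) {
    rows <- which(pl$read == i)
    seq_i <- reads$sequence[i]
    qual_i <- reads$quality[i]
    if (!length(rows)) {
      writeLines(paste(ms$read_id[i], 4, "*", 0, 0, "*", "*", 0, 0,
                       seq_i, qual_i, "NH:i:0", sep = "\t"), con)
      next
    }
    for (ri in seq_along(rows)) {
      r <- rows[ri]
      minus <- pl$strand[r] == "-"
      flag <- (if (minus) 16L else 0L) + (if (ri > 1) 256L else 0L)
      L <- nchar(seq_i)
      rb <- pl$aligned_read_bases[r]
      cols <- pl$aligned_columns[r]
      span <- pl$end[r] - pl$start[r] + 1
      del <- cols - rb
      ins <- cols - span
      mm <- rb + span - cols
      clip5 <- pl$read_start[r]
      clip3 <- L - clip5 - rb
      runs <- character()
      if (clip5 > 0) runs <- c(runs, paste0(clip5, "S"))
      if (ins > 0 || del > 0) {
        runs <- c(runs, paste0(mm - 1, "M"),
                  if (ins > 0) paste0(ins, "I"),
                  if (del > 0) paste0(del, "D"), "1M")
      } else {
        runs <- c(runs, paste0(rb, "M"))
      }
      if (clip3 > 0) runs <- c(runs, paste0(clip3, "S"))
      out_seq <- if (minus) revcomp(seq_i) else seq_i
      out_qual <- if (minus) paste(rev(strsplit(qual_i, "")[[1]]),
                                   collapse = "") else qual_i
      tags <- sprintf("NH:i:%d", ms$n_admissible[i])
      if (!is.null(organism))
        tags <- c(tags, sprintf("XO:Z:%s", organism[i]))
      writeLines(paste(ms$read_id[i], flag, pl$contig[r], pl$start[r],
                       if (ri == 1) 60 else 0, paste(runs, collapse = ""),
                       "*", 0, 0, out_seq, out_qual,
                       paste(tags, collapse = "\t"), sep = "\t"), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
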