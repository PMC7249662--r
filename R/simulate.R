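#' Simulation parameter set
#'
#' Describes a synthetic dual-organism experiment: a larger eukaryote-like
#' genome and a smaller prokaryote-like genome, annotated tRNA/rRNA/CDS
#' features, one or more homologous tracts copied from A into B at a
#' controlled divergence (rRNA-like homology is the dominant source of
#' cross-mapping, so the default plants one shared rRNA tract), and
#' truth-tagged reads with i.i.d. substitution errors.
#'
#' @param seed integer seed; every simulation is reproducible from it.
#' @param genome_lengths named pair `c(a=, b=)` of genome sizes in bp.
#' @param n_features list with per-organism named vectors of feature
#'   counts per category.
#' @param homology list of tracts, each `list(length=, divergence=)`;
#'   tract 1 is copied from around A's first rRNA feature into B and
#'   annotated there as rRNA.
#' @param read_length read length in bases.
#' @param substitution_error per-base sequencing substitution rate.
#' @param depth mean reads per feature; per-feature counts are drawn
#'   log-normally with `depth_sdlog` dispersion.
#' @param depth_sdlog log-normal sdlog of per-feature expression.
#' @param rrna_boost multiplier on `depth` for rRNA features, mimicking
#'   the rRNA-dominated composition of unenriched libraries.
#' @param mix_ratio fraction of A's library retained when building the
#'   chimera (deterministic subsample; 1 keeps every read).
#' @param paired simulate read pairs.
#' @param insert_mean,insert_sd fragment-size distribution (paired mode).
#' @param organisms labels of the two organisms.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(seed = 1,
                       genome_lengths = c(a = 200000, b = 50000),
                       n_features = list(
                         a = c(tRNA = 8, rRNA = 2, CDS = 40),
                         b = c(tRNA = 10, rRNA = 2, CDS = 30)),
                       homology = list(list(length = 2000,
                                            divergence = 0.05)),
                       read_length = 75,
                       substitution_error = 0.005,
                       depth = 50,
                       depth_sdlog = 0.5,
                       rrna_boost = 20,
                       mix_ratio = 1,
                       paired = FALSE,
                       insert_mean = 300,
                       insert_sd = 30,
                       organisms = c("orgA", "orgB")) {
  stopifnot(length(genome_lengths) == 2, read_length >= 20,
            substitution_error >= 0, substitution_error < 1,
            mix_ratio > 0, mix_ratio <= 1, depth > 0)
  for (h in homology)
    stopifnot(h$divergence >= 0, h$divergence <= 1, h$length >= 1)
  structure(as.list(environment()), class = "sim_params")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv,
                    inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    alt <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    bases[hit] <- alt
  }
  paste(bases, collapse = "")
}

# vectorised substitution over many reads: number of errors per read is
# binomial, positions uniform without replacement (same i.i.d. model)
mutate_many <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(nerr > 0)) {
    bases <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(bases), nerr[i])
    bases[pos] <- vapply(bases[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
    seqs[i] <- paste(bases, collapse = "")
  }
  seqs
}

# place n non-overlapping intervals of the given lengths on [1, L]
# keeping >= `gap` bp between them; rejection sampling, longest first
# (starts are returned in the original order of `lengths`)
place_intervals <- function(lengths, L, gap = 50, occupied = NULL,
                            max_tries = 5000) {
  starts <- integer(length(lengths))
  occ <- occupied  # data.frame(start, end) or NULL
  if (sum(lengths) + gap * length(lengths) > L)
    stop("features and tracts exceed the genome length")
  for (i in order(lengths, decreasing = TRUE)) {
    len <- lengths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L - len + 1, 1)
      e <- s + len - 1
      if (is.null(occ) ||
          all(s > occ$end + gap | e < occ$start - gap)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("features and tracts exceed the genome length ",
                  "(could not place interval of length ", len, ")")
    starts[i] <- s
    occ <- rbind(occ, data.frame(start = s, end = e))
  }
  starts
}

simulate_one_genome <- function(org, contig_names, contig_lengths,
                                counts, gap = 50, occupied = NULL) {
  feature_len <- function(cat) {
    switch(cat,
           tRNA = sample(70:90, 1),
           rRNA = sample(1500:3000, 1),
           CDS = sample(300:1500, 1))
  }
  cats <- rep(names(counts), counts)
  lens <- vapply(cats, feature_len, 1L)
  # distribute features over contigs proportionally to contig length
  contig_of <- sample(seq_along(contig_names), length(cats),
                      replace = TRUE, prob = contig_lengths)
  feats <- NULL
  for (ci in seq_along(contig_names)) {
    sel <- which(contig_of == ci)
    if (!length(sel)) next
    occ <- NULL
    if (!is.null(occupied))
      occ <- occupied[occupied$contig == contig_names[ci],
                      c("start", "end"), drop = FALSE]
    if (!is.null(occ) && nrow(occ) == 0) occ <- NULL
    starts <- place_intervals(lens[sel], contig_lengths[ci], gap, occ)
    feats <- rbind(feats, data.frame(
      contig = contig_names[ci], start = starts,
      end = starts + lens[sel] - 1,
      strand = sample(c("+", "-"), length(sel), replace = TRUE),
      category = cats[sel], stringsAsFactors = FALSE))
  }
  feats <- feats[order(match(feats$contig, contig_names), feats$start), ,
                 drop = FALSE]
  feats$feature_id <- paste0(org, "_", feats$category, "_",
                             stats::ave(seq_len(nrow(feats)),
                                        feats$category,
                                        FUN = seq_along))
  rownames(feats) <- NULL
  seqs <- stats::setNames(vapply(contig_lengths, random_dna, ""),
                          contig_names)
  list(genome = genome(org, seqs), features = feats)
}

#' Simulate a dual-organism genome pair with planted homology
#'
#' Generates i.i.d.-uniform genome backgrounds for both organisms,
#' places non-overlapping annotated features (>= 50 bp apart), then
#' copies each homology tract from organism A into organism B with
#' per-base substitution at the requested divergence. Tract 1 is taken
#' from around A's first rRNA feature and the overlapped part is
#' annotated as an rRNA feature of B, so rRNA-driven cross-mapping
#' arises exactly as in real host-microbe libraries. Deterministic under
#' `params$seed`.
#'
#' @param params a [sim_params()].
#' @return list of class `sim_genomes`: `genome_a`, `genome_b`,
#'   `features_a`, `features_b`, `homology` (data.frame of realized
#'   tracts, including the realized per-base divergence).
#' @export
simulate_genome_pair <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    La <- params$genome_lengths[[1]]
    Lb <- params$genome_lengths[[2]]
    a <- simulate_one_genome(params$organisms[1], c("chrA1", "chrA2"),
                             c(ceiling(La * 0.6), floor(La * 0.4)),
                             params$n_features$a)
    ga <- a$genome
    fa <- a$features
    rr <- fa[fa$category == "rRNA", , drop = FALSE]
    # pick tract sources in A and reserve tract intervals in B first, so
    # B's own features are placed around them
    n_tracts <- length(params$homology)
    tracts <- vector("list", n_tracts)
    b_occ <- NULL
    for (i in seq_len(n_tracts)) {
      h <- params$homology[[i]]
      len <- h$length
      if (i <= nrow(rr)) {
        f <- rr[i, ]
        clen <- length(ga$sequences[[match(f$contig,
                                           names(ga$sequences))]])
        pad <- max(0, (len - (f$end - f$start + 1)) %/% 2)
        a_start <- max(1, f$start - pad)
        a_end <- min(clen, a_start + len - 1)
        a_start <- max(1, a_end - len + 1)
        src_contig <- f$contig
      } else {
        src_contig <- names(ga$sequences)[1]
        clen <- length(ga$sequences[[1]])
        a_start <- sample.int(max(1, clen - len + 1), 1)
        a_end <- min(clen, a_start + len - 1)
      }
      tract <- as.character(Biostrings::subseq(
        ga$sequences[[match(src_contig, names(ga$sequences))]],
        a_start, a_end))
      mut <- mutate_dna(tract, h$divergence)
      realized <- sum(strsplit(tract, "")[[1]] !=
                        strsplit(mut, "")[[1]]) / nchar(tract)
      b_start <- place_intervals(
        nchar(mut), Lb, gap = 50,
        occupied = if (is.null(b_occ)) NULL
                   else b_occ[, c("start", "end"), drop = FALSE])
      b_end <- b_start + nchar(mut) - 1
      tracts[[i]] <- list(seq = mut, a_contig = src_contig,
                          a_start = a_start, a_end = a_end,
                          b_start = b_start, b_end = b_end,
                          divergence = h$divergence,
                          realized = realized,
                          rr_row = if (i <= nrow(rr)) i else NA)
      b_occ <- rbind(b_occ, data.frame(contig = "chrB",
                                       start = b_start, end = b_end))
    }
    b <- simulate_one_genome(params$organisms[2], "chrB", Lb,
                             params$n_features$b, occupied = b_occ)
    gb <- b$genome
    fb <- b$features
    hom <- NULL
    if (n_tracts > 0) {
      sb <- as.character(gb$sequences[["chrB"]])
      for (i in seq_len(n_tracts)) {
        tr <- tracts[[i]]
        substr(sb, tr$b_start, tr$b_end) <- tr$seq
        # annotate the homolog of A's covered rRNA (if any) as B rRNA
        if (!is.na(tr$rr_row)) {
          f <- rr[tr$rr_row, ]
          o_start <- max(f$start, tr$a_start)
          o_end <- min(f$end, tr$a_end)
          if (o_end - o_start + 1 >= params$read_length) {
            fb <- rbind(fb, data.frame(
              contig = "chrB",
              start = tr$b_start + (o_start - tr$a_start),
              end = tr$b_start + (o_end - tr$a_start),
              strand = f$strand,
              category = "rRNA",
              feature_id = paste0(params$organisms[2], "_rRNA_hom", i),
              stringsAsFactors = FALSE))
          }
        }
        hom <- rbind(hom, data.frame(
          a_contig = tr$a_contig, a_start = tr$a_start,
          a_end = tr$a_end, b_contig = "chrB",
          b_start = tr$b_start, b_end = tr$b_end,
          divergence = tr$divergence,
          realized_divergence = tr$realized,
          stringsAsFactors = FALSE))
      }
      gb <- genome(gb$organism,
                   stats::setNames(sb, names(gb$sequences)))
    }
    fb <- fb[order(fb$start), , drop = FALSE]
    rownames(fb) <- NULL
    structure(list(genome_a = ga, genome_b = gb,
                   features_a = fa, features_b = fb,
                   homology = hom, params = params),
              class = "sim_genomes")
  })
}

#' @export
print.sim_genomes <- function(x, ...) {
  cat("<simulated genome pair>\n  ")
  print(x$genome_a)
  cat("  ")
  print(x$genome_b)
  cat(" ", nrow(x$features_a), "+", nrow(x$features_b), "features,",
      if (is.null(x$homology)) 0 else nrow(x$homology),
      "homologous tract(s)\n")
  invisible(x)
}

#' Simulate truth-tagged reads from annotated features
#'
#' Per-feature read counts are drawn log-normally around `depth` (rRNA
#' features boosted by `rrna_boost`); read starts are uniform within the
#' feature; substitution errors are i.i.d.; qualities are constant.
#' Read names carry complete truth tags
#' (`sim:<org>:<feature>:<contig>:<start>-<end>:<serial>`). Features
#' shorter than the read length yield clipped reads when at least 20 nt
#' remain, and are skipped (with a warning) otherwise.
#'
#' @param genome a [genome].
#' @param features its feature table.
#' @param params a [sim_params()].
#' @param seed seed for this library; defaults to `params$seed` offset
#'   by the organism so the two libraries differ.
#' @return A `read_library` with attribute `per_feature_counts`.
#' @export
simulate_reads <- function(genome, features, params = sim_params(),
                           seed = NULL) {
  stopifnot(inherits(genome, "genome"), nrow(features) > 0)
  validate_features(features, genome)
  if (is.null(seed))
    seed <- params$seed + match(genome$organism, params$organisms,
                                nomatch = 3) * 1000L
  with_seed(seed, {
    rl <- params$read_length
    ids <- character(); seqs <- character()
    drawn <- integer(nrow(features))
    serial <- 0L
    for (fi in seq_len(nrow(features))) {
      f <- features[fi, ]
      flen <- f$end - f$start + 1
      this_rl <- min(rl, flen)
      if (this_rl < 20) {
        warning("feature ", f$feature_id,
                " shorter than 20 nt; skipped")
        next
      }
      mu <- params$depth *
        if (f$category == "rRNA") params$rrna_boost else 1
      n <- round(stats::rlnorm(1, log(mu), params$depth_sdlog))
      drawn[fi] <- n
      if (n == 0) next
      contig_seq <- as.character(
        genome$sequences[[match(f$contig, names(genome$sequences))]])
      if (params$paired) {
        n_pairs <- ceiling(n / 2)
        for (p in seq_len(n_pairs)) {
          frag <- min(max(this_rl, round(stats::rnorm(
            1, params$insert_mean, params$insert_sd))), flen)
          s <- f$start + sample.int(flen - frag + 1, 1) - 1
          e <- s + frag - 1
          fseq <- substr(contig_seq, s, e)
          if (f$strand == "-") fseq <- revcomp(fseq)
          serial <- serial + 1L
          tag <- paste0("sim:", genome$organism, ":", f$feature_id, ":",
                        f$contig, ":", s, "-", e, ":", serial)
          m1 <- mutate_dna(substr(fseq, 1, this_rl),
                           params$substitution_error)
          m2 <- mutate_dna(revcomp(substr(fseq, frag - this_rl + 1,
                                          frag)),
                           params$substitution_error)
          ids <- c(ids, paste0(tag, "/1"), paste0(tag, "/2"))
          seqs <- c(seqs, m1, m2)
        }
      } else {
        starts <- f$start + sample.int(flen - this_rl + 1, n,
                                       replace = TRUE) - 1
        ends <- starts + this_rl - 1
        rseqs <- substring(contig_seq, starts, ends)
        if (f$strand == "-") rseqs <- revcomp(rseqs)
        rseqs <- mutate_many(rseqs, params$substitution_error)
        new_ids <- paste0("sim:", genome$organism, ":", f$feature_id,
                          ":", f$contig, ":", starts, "-", ends, ":",
                          serial + seq_len(n))
        serial <- serial + n
        ids <- c(ids, new_ids)
        seqs <- c(seqs, rseqs)
      }
    }
    lib <- read_library(ids, seqs)
    attr(lib, "per_feature_counts") <-
      data.frame(feature_id = features$feature_id, n_reads = drawn,
                 stringsAsFactors = FALSE)
    lib
  })
}

#' Merge two truth-tagged libraries into a chimera library
#'
#' Concatenates the two libraries (optionally keeping only a
#' deterministic `mix_ratio` fraction of A's reads: the first
#' `floor(mix_ratio * nA)` reads after a seeded shuffle of A) and
#' shuffles the result deterministically under `seed`. Read names, and
#' therefore truth tags, are preserved.
#'
#' @param lib_a,lib_b `read_library` objects.
#' @param mix_ratio fraction of A's library retained (default 1).
#' @param seed shuffle seed.
#' @return A `read_library`.
#' @export
make_chimera <- function(lib_a, lib_b, mix_ratio = 1, seed = 1) {
  lib_a <- as_read_library(lib_a)
  lib_b <- as_read_library(lib_b)
  stopifnot(mix_ratio > 0, mix_ratio <= 1)
  with_seed(seed, {
    if (mix_ratio < 1) {
      keep <- floor(mix_ratio * nrow(lib_a))
      lib_a <- lib_a[sample.int(nrow(lib_a))[seq_len(keep)], ,
                     drop = FALSE]
    }
    out <- rbind(as.data.frame(lib_a), as.data.frame(lib_b))
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    read_library(out$read_id, out$sequence, out$quality)
  })
}

#' Write all artefacts of a simulation to a directory
#'
#' Emits two FASTA genomes, two GFF3 annotations, two per-organism
#' FASTQ libraries, the chimera FASTQ, a truth TSV and a params JSON.
#'
#' @param sim a [simulate_genome_pair()] result.
#' @param dir output directory (created if needed).
#' @param mix_ratio,chimera_seed forwarded to [make_chimera()].
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, mix_ratio = NULL,
                             chimera_seed = NULL) {
  stopifnot(inherits(sim, "sim_genomes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- sim$params
  if (is.null(mix_ratio)) mix_ratio <- p$mix_ratio
  if (is.null(chimera_seed)) chimera_seed <- p$seed
  lib_a <- simulate_reads(sim$genome_a, sim$features_a, p)
  lib_b <- simulate_reads(sim$genome_b, sim$features_b, p)
  chim <- make_chimera(lib_a, lib_b, mix_ratio, chimera_seed)
  paths <- c(
    fasta_a = file.path(dir, "genome_a.fasta"),
    fasta_b = file.path(dir, "genome_b.fasta"),
    gff_a = file.path(dir, "features_a.gff3"),
    gff_b = file.path(dir, "features_b.gff3"),
    fastq_a = file.path(dir, "reads_a.fastq"),
    fastq_b = file.path(dir, "reads_b.fastq"),
    chimera = file.path(dir, "chimera.fastq"),
    truth = file.path(dir, "truth.tsv"),
    params = file.path(dir, "params.json"))
  write_fasta(sim$genome_a, paths["fasta_a"])
  write_fasta(sim$genome_b, paths["fasta_b"])
  write_gff3(sim$features_a, paths["gff_a"])
  write_gff3(sim$features_b, paths["gff_b"])
  write_fastq(lib_a, paths["fastq_a"])
  write_fastq(lib_b, paths["fastq_b"])
  write_fastq(chim, paths["chimera"])
  utils::write.table(parse_truth_tags(chim$read_id), paths["truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    unclass(p)[setdiff(names(p), "n_features")],
    paths["params"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
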