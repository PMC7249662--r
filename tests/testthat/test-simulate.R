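small_params <- function(seed = 1, ...) {
  sim_params(seed = seed,
             genome_lengths = c(a = 30000, b = 15000),
             n_features = list(a = c(tRNA = 2, rRNA = 1, CDS = 6),
                               b = c(tRNA = 2, rRNA = 1, CDS = 5)),
             homology = list(list(length = 1500, divergence = 0)),
             depth = 6, rrna_boost = 4, ...)
}

test_that("the whole simulation is byte-identical under one seed", {
  p <- small_params(seed = 51)
  s1 <- simulate_genome_pair(p)
  s2 <- simulate_genome_pair(p)
  expect_identical(as.character(s1$genome_a$sequences),
                   as.character(s2$genome_a$sequences))
  expect_identical(as.character(s1$genome_b$sequences),
                   as.character(s2$genome_b$sequences))
  expect_identical(s1$features_a, s2$features_a)
  expect_identical(s1$features_b, s2$features_b)
  l1 <- simulate_reads(s1$genome_a, s1$features_a, p)
  l2 <- simulate_reads(s2$genome_a, s2$features_a, p)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  # and file artefacts round-trip identically
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_simulation(s1, d1)
  f2 <- write_simulation(s2, d2)
  expect_identical(readLines(f1["chimera"]), readLines(f2["chimera"]))
  expect_identical(readLines(f1["fasta_b"]), readLines(f2["fasta_b"]))
})

test_that("a zero-divergence tract is an identical shared subsequence", {
  sim <- simulate_genome_pair(small_params(seed = 52))
  h <- sim$homology
  a_sub <- substr(as.character(
    sim$genome_a$sequences[[match(h$a_contig,
                                  names(sim$genome_a$sequences))]]),
    h$a_start, h$a_end)
  b_sub <- substr(as.character(sim$genome_b$sequences[["chrB"]]),
                  h$b_start, h$b_end)
  expect_identical(a_sub, b_sub)
  expect_equal(h$realized_divergence, 0)
})

test_that("realized tract divergence matches the binomial expectation", {
  p <- sim_params(seed = 53,
                  genome_lengths = c(a = 60000, b = 40000),
                  n_features = list(a = c(tRNA = 1, rRNA = 1, CDS = 4),
                                    b = c(tRNA = 1, rRNA = 1, CDS = 3)),
                  homology = list(list(length = 10000,
                                       divergence = 0.1)),
                  depth = 5)
  sim <- simulate_genome_pair(p)
  d <- sim$homology$realized_divergence
  # within 3 binomial standard deviations of the parameter
  expect_lt(abs(d - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("error-free reads are exact substrings of their source feature", {
  p <- small_params(seed = 54, substitution_error = 0)
  sim <- simulate_genome_pair(p)
  lib <- simulate_reads(sim$genome_b, sim$features_b, p)
  tt <- parse_truth_tags(lib$read_id)
  for (i in seq_len(min(nrow(lib), 50))) {
    ref <- as.character(
      sim$genome_b$sequences[[match(tt$contig[i],
                                    names(sim$genome_b$sequences))]])
    sub <- substr(ref, tt$start[i], tt$end[i])
    f <- sim$features_b[sim$features_b$feature_id == tt$feature_id[i], ]
    if (f$strand == "-") sub <- revcomp(sub)
    expect_identical(lib$sequence[i], sub)
    # and the read comes from inside its feature
    expect_gte(tt$start[i], f$start)
    expect_lte(tt$end[i], f$end)
  }
})

test_that("library size equals the recorded per-feature draws", {
  p <- small_params(seed = 55)
  sim <- simulate_genome_pair(p)
  lib <- simulate_reads(sim$genome_a, sim$features_a, p)
  drawn <- attr(lib, "per_feature_counts")
  expect_equal(nrow(lib), sum(drawn$n_reads))
  tt <- parse_truth_tags(lib$read_id)
  observed <- table(tt$feature_id)
  for (f in drawn$feature_id[drawn$n_reads > 0])
    expect_equal(unname(observed[[f]]),
                 drawn$n_reads[drawn$feature_id == f])
})

test_that("truth tags survive a FASTQ round trip", {
  p <- small_params(seed = 56)
  sim <- simulate_genome_pair(p)
  lib <- simulate_reads(sim$genome_b, sim$features_b, p)
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(lib, f)
  back <- read_fastq(f)
  expect_identical(back$read_id, lib$read_id)
  expect_identical(truth_from_names(back$read_id),
                   rep("orgB", nrow(lib)))
})

test_that("short features are clipped or skipped at the 20 nt floor", {
  set.seed(57)
  g <- genome("orgA", c(c1 = rand_dna(2000)))
  feats <- data.frame(contig = "c1", start = c(101, 501, 901),
                      end = c(101 + 74, 501 + 39, 901 + 14),
                      strand = "+", category = "CDS",
                      feature_id = c("full", "short", "tiny"),
                      stringsAsFactors = FALSE)
  p <- sim_params(seed = 57, depth = 4, substitution_error = 0)
  expect_warning(lib <- simulate_reads(g, feats, p, seed = 57),
                 "tiny")
  tt <- parse_truth_tags(lib$read_id)
  expect_false("tiny" %in% tt$feature_id)
  short_len <- nchar(lib$sequence[tt$feature_id == "short"])
  expect_true(all(short_len == 40))   # clipped to the feature length
  expect_true(all(
    nchar(lib$sequence[tt$feature_id == "full"]) == 75))
})

test_that("chimera construction is an exact, seeded merge", {
  mk <- function(org, n) read_library(
    paste0("sim:", org, ":f:c:1-60:", seq_len(n)),
    vapply(seq_len(n), function(i) rand_dna(60), ""))
  set.seed(58)
  la <- mk("orgA", 1000)
  lb <- mk("orgB", 1000)
  ch <- make_chimera(la, lb, seed = 58)
  expect_equal(nrow(ch), 2000)
  expect_equal(as.vector(table(truth_from_names(ch$read_id))),
               c(1000, 1000))
  # deterministic subsample: exactly 90% of A is kept, all of B
  ch9 <- make_chimera(la, lb, mix_ratio = 0.9, seed = 58)
  tt <- table(truth_from_names(ch9$read_id))
  expect_equal(unname(tt[["orgA"]]), 900)
  expect_equal(unname(tt[["orgB"]]), 1000)
  # same seed, same shuffle
  expect_identical(make_chimera(la, lb, seed = 58)$read_id, ch$read_id)
})

test_that("simulation artefacts parse back with standard readers", {
  p <- small_params(seed = 59)
  sim <- simulate_genome_pair(p)
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  expect_true(all(file.exists(paths)))
  ga <- read_fasta(paths[["fasta_a"]], organism = "orgA")
  expect_identical(as.character(ga$sequences),
                   as.character(sim$genome_a$sequences))
  fa <- read_gff3(paths[["gff_a"]])
  expect_equal(nrow(fa), nrow(sim$features_a))
  expect_setequal(fa$feature_id, sim$features_a$feature_id)
  cfg <- jsonlite::read_json(paths[["params"]])
  expect_equal(cfg$seed, 59)
})

test_that("divergence beyond twice the similarity slack kills cross-mapping", {
  # error-free reads cannot pass min_similarity 0.8 on a homolog whose
  # divergence is >= 2 * (1 - 0.8) = 0.4
  p <- small_params(seed = 60, substitution_error = 0)
  p$homology[[1]]$divergence <- 0.4
  sim <- simulate_genome_pair(p)
  lib_b <- simulate_reads(sim$genome_b, sim$features_b, p)
  expect_equal(crossmap_assay(lib_b, sim$genome_a), 0)
})

test_that("paired simulation yields proper mate pairs within the insert range", {
  p <- small_params(seed = 61, paired = TRUE, substitution_error = 0)
  sim <- simulate_genome_pair(p)
  lib <- simulate_reads(sim$genome_b, sim$features_b, p)
  expect_true(all(grepl("/[12]$", lib$read_id)))
  idx <- build_index(sim$genome_b, 15)
  mp <- mapping_params(paired = TRUE, insert_min = 60,
                       insert_max = 600)
  pr <- map_pair(lib$sequence[1], lib$sequence[2], idx, mp)
  expect_false(pr$mate1$broken_pair)
  expect_false(pr$mate2$broken_pair)
})
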