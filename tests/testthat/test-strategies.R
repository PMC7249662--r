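# small handcrafted pair: orgA 4 kb, orgB 2.5 kb, one shared 300 bp
# tract (identical unless stated); reads of 60 nt

test_that("sequential attribution favours the first genome on shared reads", {
  fx <- tiny_pair(seed = 21)
  a_only <- reads_from(fx$a, "chrA", 501, 5, prefix = "a")
  b_only <- reads_from(fx$b, "chrB", 101, 5, prefix = "b")
  shared <- reads_from(fx$a, "chrA", fx$tract_a[1] + 10, 5,
                       prefix = "s")
  lib <- read_library(c(a_only$read_id, b_only$read_id,
                        shared$read_id),
                      c(a_only$sequence, b_only$sequence,
                        shared$sequence))
  tab_a <- sequential_partition(lib, fx$a, fx$b)
  asg <- stats::setNames(tab_a$assigned, tab_a$read_id)
  expect_true(all(asg[a_only$read_id] == "orgA"))
  expect_true(all(asg[b_only$read_id] == "orgB"))
  # shared-tract reads are admissible on both: first genome wins
  expect_true(all(asg[shared$read_id] == "orgA"))
  tab_b <- sequential_partition(lib, fx$b, fx$a)
  asg_b <- stats::setNames(tab_b$assigned, tab_b$read_id)
  expect_true(all(asg_b[shared$read_id] == "orgB"))
  # order sensitivity: A-first attributes at least as many reads to A
  expect_gte(attribution_totals(tab_a)[["orgA"]],
             attribution_totals(tab_b)[["orgA"]])
})

test_that("reads admissible on neither genome stay unmapped", {
  fx <- tiny_pair(seed = 22)
  set.seed(9922)
  lib <- read_library("x", rand_dna(60))
  tab <- sequential_partition(lib, fx$a, fx$b)
  expect_equal(tab$assigned, "unmapped")
})

test_that("combined partitioning removes equal-best reads as ambiguous", {
  fx <- tiny_pair(seed = 23)     # identical tract: exact ties
  shared <- reads_from(fx$a, "chrA", fx$tract_a[1] + 5, 6, prefix = "s")
  a_only <- reads_from(fx$a, "chrA", 1001, 4, prefix = "a")
  lib <- read_library(c(shared$read_id, a_only$read_id),
                      c(shared$sequence, a_only$sequence))
  cr <- combine_references(fx$a, fx$b)
  tab <- combined_partition(lib, cr)
  asg <- stats::setNames(tab$assigned, tab$read_id)
  det <- stats::setNames(tab$detail, tab$read_id)
  expect_true(all(asg[shared$read_id] == "unmapped"))
  expect_true(all(det[shared$read_id] == "ambiguous"))
  expect_true(all(asg[a_only$read_id] == "orgA"))
})

test_that("combined partitioning assigns diverged homologs by best score", {
  # tract diverged by 6 substitutions: reads keep ~1-2 mismatches on the
  # homolog but 0 on their own genome, so the score decides
  fx <- tiny_pair(seed = 24, n_subs = 6)
  shared_a <- reads_from(fx$a, "chrA", fx$tract_a[1], 8, prefix = "sa")
  cr <- combine_references(fx$a, fx$b)
  tab <- combined_partition(read_library(shared_a$read_id,
                                         shared_a$sequence), cr)
  hits <- tab$assigned[tab$assigned != "unmapped"]
  expect_true(length(hits) > 0)
  expect_true(all(hits == "orgA"))
  # cross-check one read against the exhaustive aligner on both genomes
  rd <- shared_a$sequence[1]
  sc_a <- map_read_exhaustive(rd, fx$a)$placements$score[1]
  sc_b <- map_read_exhaustive(rd, fx$b)$placements$score[1]
  expect_gt(sc_a, if (length(sc_b)) sc_b else -Inf)
})

test_that("a widened tie margin removes near-tie reads", {
  fx <- tiny_pair(seed = 25, n_subs = 2)
  shared <- reads_from(fx$a, "chrA", fx$tract_a[1] + 3, 10,
                       prefix = "s")
  cr <- combine_references(fx$a, fx$b)
  lib <- read_library(shared$read_id, shared$sequence)
  t0 <- combined_partition(lib, cr, tie_margin = 0)
  t9 <- combined_partition(lib, cr, tie_margin = 9)
  expect_gte(sum(t9$assigned == "unmapped"),
             sum(t0$assigned == "unmapped"))
})

test_that("every strategy partitions the input exactly", {
  fx <- tiny_pair(seed = 26)
  set.seed(8826)
  lib <- read_library(
    paste0("r", 1:30),
    c(reads_from(fx$a, "chrA", 301, 10)$sequence,
      reads_from(fx$b, "chrB", 301, 10)$sequence,
      vapply(1:10, function(i) rand_dna(60), "")))
  cr <- combine_references(fx$a, fx$b)
  for (tab in list(sequential_partition(lib, fx$a, fx$b),
                   sequential_partition(lib, fx$b, fx$a),
                   combined_partition(lib, cr))) {
    tot <- attribution_totals(tab)
    expect_equal(sum(tot), nrow(lib))
    expect_equal(nrow(tab), nrow(lib))
    expect_false(anyDuplicated(tab$read_id) > 0)
  }
})

test_that("extract_reads splits the stream exactly and keeps order", {
  fx <- tiny_pair(seed = 27)
  lib <- read_library(
    paste0("r", 1:12),
    c(reads_from(fx$a, "chrA", 601, 6)$sequence,
      reads_from(fx$b, "chrB", 601, 6)$sequence))
  tab <- sequential_partition(lib, fx$a, fx$b)
  ra <- extract_reads(tab, lib, "orgA")
  rb <- extract_reads(tab, lib, "orgB")
  ru <- extract_reads(tab, lib, "unmapped")
  expect_setequal(c(ra$read_id, rb$read_id, ru$read_id), lib$read_id)
  expect_equal(length(intersect(ra$read_id, rb$read_id)), 0)
  # input order preserved
  expect_equal(ra$read_id, lib$read_id[lib$read_id %in% ra$read_id])
  # empty extraction still writes a valid (empty) FASTQ
  f <- withr::local_tempfile(fileext = ".fastq")
  tab2 <- tab
  tab2$assigned <- rep("orgA", nrow(tab2))
  extract_reads(tab2, lib, "orgB", out = f)
  expect_equal(nrow(read_fastq(f)), 0)
  # a stream read missing from the table is a consistency error
  extra <- rbind(as.data.frame(lib),
                 data.frame(read_id = "ghost", sequence = rand_dna(60),
                            quality = paste(rep("I", 60),
                                            collapse = "")))
  expect_error(extract_reads(tab, extra, "orgA"), "absent")
})

test_that("closed-form sequential totals follow the attribution rule", {
  # zero cross-mapping: totals equal library sizes under both orders
  expect_equal(
    sequential_attribution_counts(100, 50, 0, 0, "A_first"),
    c(A = 100, B = 50))
  expect_equal(
    sequential_attribution_counts(100, 50, 0, 0, "B_first"),
    c(A = 100, B = 50))
  # cross-mapping moves reads toward the first genome
  expect_equal(
    sequential_attribution_counts(100, 50, 10, 4, "A_first"),
    c(A = 104, B = 46))
  expect_equal(
    sequential_attribution_counts(100, 50, 10, 4, "B_first"),
    c(A = 90, B = 60))
  expect_error(
    sequential_attribution_counts(100, 50, 101, 0, "A_first"),
    "exceed")
})

test_that("sequential partitioning of a pre-filtered chimera matches the closed form", {
  fx <- tiny_pair(seed = 28)
  lib_a <- reads_from(fx$a, "chrA", 801, 8, prefix = "sim:orgA:f:c:1-60")
  lib_b <- reads_from(fx$b, "chrB", 301, 6, prefix = "sim:orgB:f:c:1-60")
  shared_b <- reads_from(fx$b, "chrB", fx$tract_b[1] + 2, 3,
                         prefix = "sim:orgB:h:c:1-60")
  lib <- read_library(c(lib_a$read_id, lib_b$read_id,
                        shared_b$read_id),
                      c(lib_a$sequence, lib_b$sequence,
                        shared_b$sequence))
  # measure cross-mapping with the assay, then predict the totals
  cross_b_to_a <- crossmap_assay(
    read_library(c(lib_b$read_id, shared_b$read_id),
                 c(lib_b$sequence, shared_b$sequence)), fx$a)
  cross_a_to_b <- crossmap_assay(lib_a, fx$b)
  expected <- sequential_attribution_counts(
    8, 9, cross_a_to_b, cross_b_to_a, "A_first",
    organisms = c("orgA", "orgB"))
  tab <- sequential_partition(lib, fx$a, fx$b)
  tot <- attribution_totals(tab)
  expect_equal(tot[["orgA"]], expected[["orgA"]])
  expect_equal(tot[["orgB"]], expected[["orgB"]])
})

test_that("truth tags parse back from read names", {
  ids <- c("sim:orgA:gene7:chrA1:101-175:42", "plainread")
  expect_equal(truth_from_names(ids), c("orgA", NA))
  tt <- parse_truth_tags(ids)
  expect_equal(tt$feature_id[1], "gene7")
  expect_equal(tt$start[1], 101)
  expect_equal(tt$end[1], 175)
  expect_true(is.na(tt$origin[2]))
})
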