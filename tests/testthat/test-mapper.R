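test_that("k-mer index enumerates both strands and rejects tiny seeds", {
  g <- genome("o", c(c1 = "ACGTACGTACGT"))
  expect_error(build_index(g, 7), "unspecific")
  idx <- build_index(g, 8)
  hits <- lookup_kmer(idx, "ACGTACGT")
  fwd <- hits[hits$strand == "+", ]
  expect_setequal(fwd$pos, c(1, 5))  # 1-based positions of the k-mer
  # ACGTACGT is its own reverse complement: same positions on '-'
  expect_setequal(hits$pos[hits$strand == "-"], c(1, 5))
  # a non-palindromic k-mer present only as reverse complement
  g2 <- genome("o", c(c1 = paste0("TTTTTTTT", revcomp("ACGCACGT"),
                                  "TTTTTTTT")))
  h2 <- lookup_kmer(build_index(g2, 8), "ACGCACGT")
  expect_true(all(h2$strand == "-"))
  expect_equal(h2$pos, 9)
})

test_that("index of a combined reference is the union of the parts", {
  set.seed(3)
  a <- genome("orgA", c(a1 = rand_dna(300)))
  b <- genome("orgB", c(b1 = rand_dna(300)))
  cr <- combine_references(a, b)
  k <- "ACGTTGCA"
  ia <- lookup_kmer(build_index(a, 8), k)
  ib <- lookup_kmer(build_index(b, 8), k)
  ic <- lookup_kmer(build_index(cr, 8), k)
  expect_equal(nrow(ic), nrow(ia) + nrow(ib))
})

test_that("exact substring maps uniquely with perfect fractions", {
  set.seed(5)
  g <- genome("o", c(c1 = rand_dna(1500)))
  rd <- substr(as.character(g$sequences[[1]]), 301, 360)
  mr <- map_read(rd, build_index(g, 15))
  expect_equal(mr$status, "unique")
  p <- mr$placements[1, ]
  expect_equal(p$start, 301)
  expect_equal(p$matches, 60)           # similarity fraction 1.0
  expect_equal(p$aligned_read_bases, 60)  # length fraction 1.0
  expect_equal(p$score, 60)
})

test_that("admissibility sits exactly at the similarity threshold", {
  set.seed(42)
  g <- genome("o", c(c1 = rand_dna(200)))
  sub20 <- substr(as.character(g$sequences[[1]]), 101, 120)
  # 4 mismatches in 20 nt: full-length similarity 16/20 = 0.8, admitted
  r4 <- mutate_at(sub20, c(3, 8, 13, 18))
  expect_false(map_read_exhaustive(r4, g)$status == "unmapped")
  # 5 mismatches: 15/20 = 0.75 full-length and no clipped alignment
  # satisfies both fractions either
  r5 <- mutate_at(sub20, c(3, 7, 11, 15, 19))
  expect_equal(map_read_exhaustive(r5, g)$status, "unmapped")
})

test_that("repeats yield multi status, absent reads are unmapped", {
  set.seed(6)
  bg <- rand_dna(2000)
  unit <- substr(bg, 101, 160)
  substr(bg, 1001, 1060) <- unit  # second identical copy
  g <- genome("o", c(c1 = bg))
  idx <- build_index(g, 15)
  mr <- map_read(unit, idx)
  expect_equal(mr$status, "multi")
  expect_equal(nrow(mr$placements), 2)
  expect_setequal(mr$placements$start, c(101, 1001))
  set.seed(7)
  rnd <- map_read(rand_dna(60), idx)
  expect_equal(rnd$status, "unmapped")
  # exhaustive scan agrees that no window is admissible
  set.seed(7)
  expect_equal(map_read_exhaustive(rand_dna(60), g)$n_admissible, 0)
})

test_that("seed-and-extend equals the exhaustive scan on random instances", {
  # smoke-scale version of the full equivalence check in the acceptance
  # suite: both threshold regimes
  p_loose <- mapping_params(0.8, 0.8, kmer_size = 8, max_hits = 50,
                            max_seed_extensions = 1000)
  p_strict <- mapping_params(0.9, 0.8, kmer_size = 8, max_hits = 50,
                             max_seed_extensions = 1000)
  for (i in 1:60) {
    inst <- make_align_instance(5000 + i)
    expect_oracle_equal(inst, p_loose)
    expect_oracle_equal(inst, p_strict)
  }
})

test_that("alignment scores agree with an independent pairwise aligner", {
  # planted reads with interior mismatches; ends clean, so the local
  # optimum is the full-length alignment in both engines
  set.seed(9)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -2, baseOnly = TRUE)
  for (i in 1:10) {
    ref <- rand_dna(800)
    g <- genome("o", c(c1 = ref))
    rd <- mutate_at(substr(ref, 201, 260), c(20, 31, 44))
    pa <- Biostrings::pairwiseAlignment(
      rd, ref, type = "local", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 3)
    mr <- map_read(rd, build_index(g, 11),
                   mapping_params(kmer_size = 11))
    expect_equal(mr$placements$score[1], Biostrings::score(pa))
  }
})

test_that("mapping is deterministic and strand-symmetric", {
  set.seed(10)
  g <- genome("o", c(c1 = rand_dna(3000)))
  idx <- build_index(g, 11)
  rd <- mutate_at(substr(as.character(g$sequences[[1]]), 501, 560),
                  c(5, 22))
  p <- mapping_params(kmer_size = 11)
  m1 <- map_read(rd, idx, p)
  m2 <- map_read(rd, idx, p)
  expect_identical(m1$placements, m2$placements)
  mrc <- map_read(revcomp(rd), idx, p)
  expect_equal(mrc$n_admissible, m1$n_admissible)
  flip <- function(s) ifelse(s == "+", "-", "+")
  a <- m1$placements[order(m1$placements$start), ]
  b <- mrc$placements[order(mrc$placements$start), ]
  expect_equal(b$start, a$start)
  expect_equal(b$end, a$end)
  expect_equal(b$score, a$score)
  expect_equal(b$strand, flip(a$strand))
})

test_that("raising either fraction never adds placements", {
  for (i in 1:25) {
    inst <- make_align_instance(9000 + i)
    idx <- build_index(inst$ref, 8)
    n_loose <- map_read(inst$read, idx,
                        mapping_params(0.8, 0.8, kmer_size = 8,
                                       max_hits = 50))$n_admissible
    for (p in list(mapping_params(0.9, 0.8, kmer_size = 8,
                                  max_hits = 50),
                   mapping_params(0.8, 0.9, kmer_size = 8,
                                  max_hits = 50))) {
      expect_lte(map_read(inst$read, idx, p)$n_admissible, n_loose)
    }
  }
})

test_that("reads shorter than the seed are unmapped with a warning", {
  g <- genome("o", c(c1 = "ACGTACGTACGTACGTACGT"))
  idx <- build_index(g, 15)
  expect_warning(mr <- map_read("ACGTACGTAC", idx), "shorter")
  expect_equal(mr$status, "unmapped")
})

test_that("placement reporting is capped but the admissible count is not", {
  set.seed(12)
  bg <- rand_dna(3000)
  unit <- substr(bg, 101, 160)
  for (s in c(601, 1201, 1801, 2401)) substr(bg, s, s + 59) <- unit
  g <- genome("o", c(c1 = bg))
  mr <- map_read(unit, build_index(g, 15),
                 mapping_params(max_hits = 3))
  expect_equal(mr$n_admissible, 5)
  expect_equal(nrow(mr$placements), 3)
  expect_equal(mr$status, "multi")
})

test_that("proper pairs pass and incoherent pairs are marked broken", {
  set.seed(13)
  bg <- rand_dna(4000)
  g <- genome("o", c(c1 = bg, c2 = rand_dna(1000)))
  idx <- build_index(g, 15)
  p <- mapping_params(paired = TRUE, insert_min = 150, insert_max = 450)
  frag <- substr(bg, 1001, 1300)              # insert 300
  r1 <- substr(frag, 1, 60)
  r2 <- revcomp(substr(frag, 241, 300))
  pr <- map_pair(r1, r2, idx, p)
  expect_false(pr$mate1$broken_pair)
  expect_false(pr$mate2$broken_pair)
  expect_equal(pr$mate1$placements$strand[1], "+")
  expect_equal(pr$mate2$placements$strand[1], "-")
  # mates on different contigs: both mapped, broken
  r2b <- revcomp(substr(as.character(g$sequences[["c2"]]), 501, 560))
  pb <- map_pair(r1, r2b, idx, p)
  expect_true(pb$mate1$broken_pair)
  expect_true(pb$mate2$broken_pair)
  expect_equal(pb$mate1$status, "unique")
  expect_equal(pb$mate2$status, "unique")
  # one mate unmapped: the other is kept, pair broken
  set.seed(14)
  pu <- map_pair(r1, rand_dna(60), idx, p)
  expect_true(pu$mate1$broken_pair)
  expect_equal(pu$mate1$status, "unique")
  expect_equal(pu$mate2$status, "unmapped")
})

test_that("SAM output carries mandatory fields, NH and XO tags", {
  set.seed(15)
  g <- genome("o", c(c1 = rand_dna(500)))
  lib <- read_library(c("r1", "r2"),
                      c(substr(as.character(g$sequences[[1]]), 101, 160),
                        rand_dna(60)))
  ms <- map_reads(lib, build_index(g, 15))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(ms, lib, f, organism = c("orgA", "unmapped"))
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "@SQ\tSN:c1\tLN:500")))
  aln <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(aln[3], "c1")
  expect_equal(as.integer(aln[4]), 101)
  expect_equal(aln[6], "60M")
  expect_true("NH:i:1" %in% aln)
  expect_true("XO:Z:orgA" %in% aln)
  un <- strsplit(grep("^r2\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(un[2]), 4L)
})
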