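# shared fixtures: all built in code, nothing on disk

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos) {
  v <- strsplit(seq, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

# A tiny handcrafted genome pair sharing one tract, for fast strategy
# tests: tract is copied verbatim (divergence 0) unless `divergence`
# given as a number of substitutions.
tiny_pair <- function(seed = 1, tract_len = 300, n_subs = 0) {
  set.seed(seed)
  a_bg <- rand_dna(4000)
  b_bg <- rand_dna(2500)
  tract <- substr(a_bg, 2001, 2000 + tract_len)
  if (n_subs > 0)
    tract <- mutate_at(tract, sample.int(tract_len, n_subs))
  b_seq <- paste0(substr(b_bg, 1, 1000), tract,
                  substr(b_bg, 1001 + tract_len, 2500))
  list(a = genome("orgA", c(chrA = a_bg)),
       b = genome("orgB", c(chrB = b_seq)),
       tract_a = c(2001, 2000 + tract_len),
       tract_b = c(1001, 1000 + tract_len))
}

# reads of length `len` sampled from a window of a genome, optionally
# with planted substitutions in the first half only (so an exact seed
# always survives in the second half)
reads_from <- function(g, contig, start, n, len = 60, n_subs = 0,
                       prefix = "r") {
  seqs <- character(n)
  full <- as.character(g$sequences[[match(contig, names(g$sequences))]])
  for (i in seq_len(n)) {
    s <- start + (i - 1) * 7
    rd <- substr(full, s, s + len - 1)
    if (n_subs > 0)
      rd <- mutate_at(rd, sample.int(floor(len / 2), n_subs))
    seqs[i] <- rd
  }
  read_library(paste0(prefix, "_", seq_len(n)), seqs)
}

# --- instances for the exhaustive-DP equivalence check ----------------
#
# Each instance is a (reference, read) pair. Reads are exact substrings,
# substituted substrings (substitutions confined to the first half of
# the read so an exact 8-mer seed always exists in the clean half),
# indel-bearing substrings, repeat-planted reads, or unrelated random
# sequence. Reference <= 4 kb, read <= 60 nt.
make_align_instance <- function(seed) {
  set.seed(seed)
  ref_len <- sample(500:4000, 1)
  ref <- rand_dna(ref_len)
  L <- sample(30:60, 1)
  kind <- sample(c("exact", "subs", "indel", "repeat", "random"), 1,
                 prob = c(0.2, 0.35, 0.15, 0.15, 0.15))
  s <- sample.int(ref_len - L + 1, 1)
  rd <- substr(ref, s, s + L - 1)
  if (kind == "subs") {
    rd <- mutate_at(rd, sample.int(floor(L / 2),
                                   sample.int(max(1, floor(L / 4)), 1)))
  } else if (kind == "indel") {
    cut <- sample(seq(10, L - 10), 1)
    if (stats::runif(1) < 0.5) {  # deletion of 1-2 ref bases from read
      d <- sample(1:2, 1)
      rd <- paste0(substr(rd, 1, cut), substr(rd, cut + d + 1, L))
    } else {                      # insertion of 1-2 bases into read
      rd <- paste0(substr(rd, 1, cut), rand_dna(sample(1:2, 1)),
                   substr(rd, cut + 1, L))
    }
  } else if (kind == "repeat") {
    # plant 1-2 extra copies of the source window elsewhere
    for (j in seq_len(sample(1:2, 1))) {
      t <- sample.int(ref_len - L + 1, 1)
      substr(ref, t, t + L - 1) <- substr(ref, s, s + L - 1)
    }
  } else if (kind == "random") {
    rd <- rand_dna(L)
  }
  if (stats::runif(1) < 0.3)
    rd <- revcomp(rd)
  list(ref = genome("ref", c(ctg = ref)), read = rd, kind = kind)
}

canonical_placements <- function(mr) {
  pl <- mr$placements
  pl <- pl[order(pl$contig, pl$start, pl$end, pl$strand), ,
           drop = FALSE]
  rownames(pl) <- NULL
  pl[, c("contig", "start", "end", "strand", "score", "matches",
         "aligned_columns", "aligned_read_bases")]
}

expect_oracle_equal <- function(inst, params) {
  seeded <- map_read(inst$read, build_index(inst$ref, params$kmer_size),
                     params)
  full <- map_read_exhaustive(inst$read, inst$ref, params)
  expect_equal(seeded$n_admissible, full$n_admissible,
               info = paste("kind:", inst$kind))
  expect_equal(canonical_placements(seeded), canonical_placements(full),
               info = paste("kind:", inst$kind))
  invisible(seeded)
}
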