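# dualmapr

Read partitioning and cross-mapping evaluation for dual RNA-Seq.

A dual RNA-Seq library mixes the transcriptomes of two interacting
organisms — typically a eukaryotic host and a prokaryotic microbe — in
one sequencing run. Before quantification, every read must be
attributed to one of the two genomes, and the two standard ways of
doing that disagree wherever the genomes share sequence (conserved
rRNA, homologous genes):

* **sequential analysis** maps all reads to a first genome and only the
  unmapped remainder to the second — so the first genome silently
  captures every cross-mappable read;
* **combined analysis** maps once against the concatenation of both
  genomes, attributes each read to the organism with its best
  placement, and removes reads that align equally well to both.

`dualmapr` is for bioinformaticians who need to partition such
libraries reproducibly, measure how many reads cross-map between a
given genome pair, and quantify what each strategy costs. It provides:

* a deterministic seed-and-extend short-read aligner whose placements
  are admitted by a **minimum length fraction** (aligned read bases /
  read length, default 0.8) and a **minimum similarity fraction**
  (matches / alignment columns, default 0.8), plus an exhaustive
  full-scan aligner used to validate it;
* both partitioning strategies over one mapping engine
  (`sequential_partition()`, `combined_partition()`), read extraction
  into per-organism FASTQ files, and the closed-form sequential
  bookkeeping `attributed(first) = n_first + cross(second→first)`;
* feature-level counting into tRNA / rRNA / CDS-unique / CDS-multi
  categories with the conventional exclusions (more than 5 admissible
  placements, intergenic-only placements);
* confusion-matrix benchmarking — sensitivity, specificity, accuracy,
  precision per organism — against known read origins
  (`cross_tabulate()`, `compute_metrics()`, `compare_strategies()`);
* a synthetic dual-organism simulator that plants a homologous
  (rRNA-like) tract at controlled divergence and emits truth-tagged
  chimera libraries, so every attribution can be checked exactly.

## Worked example

Simulate a genome pair sharing one 2 kb tract at 3% divergence, build a
truth-tagged chimera library, and compare all three partitioning runs:

```r
library(dualmapr)

p <- sim_params(seed = 20, genome_lengths = c(a = 60000, b = 30000),
                n_features = list(a = c(tRNA = 3, rRNA = 1, CDS = 12),
                                  b = c(tRNA = 3, rRNA = 1, CDS = 9)),
                homology = list(list(length = 2000, divergence = 0.03)),
                depth = 12, rrna_boost = 8)
sim     <- simulate_genome_pair(p)
lib_a   <- simulate_reads(sim$genome_a, sim$features_a, p)
lib_b   <- simulate_reads(sim$genome_b, sim$features_b, p)
chimera <- make_chimera(lib_a, lib_b, seed = 20)

compare_strategies(chimera, sim$genome_a, sim$genome_b)
#> <strategy comparison> orgA vs orgB
#>
#> attributed reads:
#>                    orgA orgB unmapped
#> sequential_A_first  384  290        0
#> sequential_B_first  223  451        0
#> combined            283  360       31
#>
#> benchmark metrics (rounded half-up to 4 decimals):
#>             strategy organism sensitivity specificity accuracy precision
#> 1 sequential_A_first     orgA      1.0000      0.7592   0.8635    0.7604
#> 2 sequential_A_first     orgB      0.7592      1.0000   0.8635    1.0000
#> 3 sequential_B_first     orgB      1.0000      0.7637   0.8976    0.8470
#> 4 sequential_B_first     orgA      0.7637      1.0000   0.8976    1.0000
#> 5           combined     orgA      1.0000      1.0000   1.0000    1.0000
#> 6           combined     orgB      1.0000      1.0000   1.0000    1.0000
```

The chimera holds 292 true orgA reads and 382 true orgB reads. Each
sequential order inflates its first genome (A-first hands 92 orgB reads
to orgA; B-first hands 69 orgA reads to orgB), which shows up as
precision 0.7604 / 0.8470 for the favoured organism. The combined run
instead removes 31 equally-well-aligning reads as ambiguous and
attributes nothing incorrectly: all four metrics are 1.0000 at 4
decimals.

The same machinery reproduces a published maize / *Herbaspirillum
seropedicae* chimera benchmark purely from its printed library
composition — `chimera_benchmark()` applies the closed-form attribution
rule and the confusion-matrix construction to
`example_chimera_counts()` and returns the attributed totals
(30,621,615 / 36,048,568 eukaryote-first; 44,476,967 / 22,193,216
prokaryote-first) and all sixteen metric cells.

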