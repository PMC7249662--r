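---
title: "Partitioning dual RNA-Seq libraries between two genomes"
author: "dualmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning dual RNA-Seq libraries between two genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmapr)
```

## The problem

A dual RNA-Seq experiment sequences the mixed transcriptomes of two
interacting organisms — typically a eukaryotic host and a prokaryotic
microbe — in a single library. Before any quantification, every read
must be attributed to one of the two genomes. Two strategies are in
common use:

* **Sequential analysis.** All reads are mapped to a first reference
  genome; everything that maps is attributed to that organism, and only
  the unmapped remainder visits the second genome. The order of the
  genomes is a free (and consequential) choice.
* **Combined analysis.** The two reference FASTA files are concatenated
  into one chimeric reference; each read is mapped once, attributed to
  the organism holding its best-scoring placement, and discarded as
  ambiguous when it aligns equally well to both.

The sequential design structurally favours the first genome: any read
that is admissible on both references — because of conserved rRNA
operons, shared metabolic genes, or chance homology — is captured by
whichever genome is mapped first, no matter how much better it fits the
other one. `dualmapr` implements both strategies over one deterministic
aligner, quantifies cross-mapping directly, and scores each strategy
with a confusion matrix against known read origins. The sequential
strategy is deliberately *not* improved (no score comparison across
genomes): its asymmetry is the effect being measured.

## Mapping model

Placements are accepted by two fractions, mirroring the contract of the
mainstream commercial mapper used in this field:

* *minimum length fraction* — aligned read bases / read length
  (default **0.8**; 0.9 is the stricter regime often used for bacterial
  libraries);
* *minimum similarity fraction* — matching bases / alignment columns
  (default **0.8**).

The aligner is seed-and-extend: exact k-mers (default k = 15, both
strands) anchor candidate regions, which are aligned with a
read-clipped, reference-local dynamic program (match +1, mismatch −2,
gap −3, linear gaps). Soft-clipped bases count against the length
fraction; gap columns count against the similarity fraction. Scoring is
deliberately simple — the admissibility filters are fraction-based, not
score-based, so an affine gap model would add parameters without
changing what is being measured.

Placement enumeration is fully deterministic. For every reference end
position the single best alignment tuple is kept (ties broken by
matches, then fewer columns, then more read bases, then leftmost
start); admissible candidates are reduced to non-overlapping loci per
contig and strand, best score first; surviving placements are ordered
by score, then (contig, start, strand), and capped at `max_hits` for
reporting while the uncapped admissible count drives the
unique/multi/unmapped status. Some mappers place equally good
("nonspecific") reads randomly instead; we chose determinism and record
the multiplicity, so repeated runs are bit-identical.

`map_read_exhaustive()` is the same placement semantics computed by an
unseeded full scan of every reference position — quadratic, but an
independent code path. The test suite requires the seeded mapper to
produce *identical* placement sets on hundreds of randomized instances
under both threshold regimes; seeding, window merging, and capping are
the things that check validates. The seeded path can in principle miss
a placement whose alignment contains no exact k-mer seed; at the error
rates the simulator emulates (substitutions around 0.5–3%) such reads
essentially do not occur, and the equivalence tests construct their
mutated reads so that a clean seed provably survives.

Paired reads are mapped as mates; a pair is *proper* when some
placement pair lies on one contig in forward/reverse orientation within
the insert range. Otherwise both mates keep their independent
placements and are flagged as broken pairs — they are retained, not
dropped, in all downstream steps.

## Partitioning and ambiguity

`sequential_partition()` attributes by first admissible genome;
`combined_partition()` compares the best admissible score per organism
over the concatenated reference. Equal best scores (within
`tie_margin`, default 0) mark a read ambiguous: it is removed, and the
attribution table records it as `ambiguous` separately from reads that
simply failed to map (`no_placement`), since the two removal causes are
often conflated in published unmapped totals. A tie margin of 0 removes
only exact score ties; widening it trades sensitivity for precision.

When a chimera library is built from two libraries that were each
pre-filtered by direct mapping to their own genome, sequential
attribution collapses to bookkeeping:
`attributed(first) = n_first + cross(second → first)` and
`attributed(second) = n_second − cross(second → first)`.
`sequential_attribution_counts()` implements this closed form;
`chimera_benchmark()` applies it, together with the confusion-matrix
construction, to the bundled `example_chimera_counts()` — a published
maize + *H. seropedicae* chimera composition — and reproduces all of
that benchmark's attribution totals and metric cells from the printed
inputs alone.

## Evaluation

With truth labels (simulator tags, or library-of-origin in a chimera),
`cross_tabulate()` fills TP/FN/FP/TN per organism; reads removed as
unmapped/ambiguous are excluded from every denominator and reported
separately. The pair of matrices is swap-symmetric, so accuracy is
identical for both organisms and sensitivity of one equals specificity
of the other — properties the tests assert. Metrics are computed at
full precision and reported rounded half-up to 4 decimals (the
convention used when such benchmarks are printed); zero denominators
yield `NA` with a warning, never a silent 0.

## Counting

`count_reads()` re-maps an extracted per-organism library against its
own genome and tallies reads into tRNA, rRNA, CDS-unique and CDS-multi
categories. Reads with more than `max_hits = 5` admissible placements,
and reads overlapping no annotated feature (intergenic), are excluded
and reported in an exclusion breakdown. A read overlapping several
features is assigned once: placements are visited best-score first, and
the feature with maximal overlap wins, ties broken by category priority
rRNA > tRNA > CDS and then by lowest start coordinate. The reference
mapper's own resolution rule for this situation is undocumented; we
need a deterministic one, and rRNA priority reflects that rRNA
dominates these libraries. Strand is ignored in counting (the emulated
protocols are unstranded), multi-placed reads are counted once (never
fractionally distributed), and tRNA/rRNA tallies aggregate unique and
multi reads because only the CDS column is conventionally split. The
conservation identity `tRNA + rRNA + CDS(unique+multi) + unmapped =
input reads` holds exactly and is asserted throughout the tests.

## The simulator

`simulate_genome_pair()` and `simulate_reads()` generate the structure
the analysis assumes, with complete ground truth in the read names:

* a larger "eukaryote-like" genome (default 200 kb over two contigs)
  and a smaller "prokaryote-like" one (50 kb, one contig), i.i.d.
  uniform base composition;
* non-overlapping tRNA/rRNA/CDS features with at least 50 bp spacing
  (defaults: 8/2/40 for A, 10/2/30 for B; tRNA 70–90 bp, rRNA
  1.5–3 kb, CDS 0.3–1.5 kb);
* one homologous tract (default 2 kb at divergence 0.05) copied from
  around A's first rRNA into B and annotated there as rRNA — conserved
  rRNA is the dominant real-world source of cross-mapping, so the
  default plants exactly that situation;
* log-normal per-feature expression around `depth = 50` reads
  (sdlog 0.5) with a 20× rRNA boost, emulating rRNA-dominated
  unenriched libraries; 75 nt reads, i.i.d. substitution errors at
  0.005, constant qualities (nothing downstream uses qualities).

Genome sizes and depths are scaled so a full three-strategy comparison
runs in tens of seconds on one core; they are study conditions of the
synthetic benchmark, fixed once. Everything is deterministic under
`seed`, including `make_chimera()`'s shuffle and its deterministic
`mix_ratio` subsample.

What the simulator does **not** emulate: GC skew and repeat families,
indel sequencing errors, strand-specific protocols, introns/splicing,
PCR duplicates, and expression correlation between organisms. Passing
tests therefore demonstrate the partitioning logic and its measurable
pathologies (first-genome inflation, ambiguity removal, threshold
monotonicity) on idealized data; they do not certify accuracy values
for any particular real library.

Two closed-form consequences anchor the simulator's realism checks: at
divergence 0 the sequential first genome gains *exactly* the reads
generated wholly inside the shared tract (the combined strategy removes
them as ties), and at divergence ≥ 2 × (1 − min similarity fraction)
error-free reads cannot cross-map at all.

## Numerical choices and edge cases

* Coordinates are 1-based inclusive everywhere (the Bioconductor
  convention); GFF3 I/O needs no conversion.
* Admissibility comparisons use a 1e-9 tolerance so that fractions like
  16/20 ≥ 0.8 are decided as printed, not by binary rounding.
* Contig-name collisions in the combined reference are repaired by
  `organism|` prefixing — plain file concatenation would silently
  duplicate names, which a correct tool must not allow. A two-column
  TSV provenance sidecar accompanies every combined FASTA export.
* Reads shorter than the seed length are unmapped with a warning;
  features shorter than the read length yield clipped reads down to a
  20 nt floor (the same floor as the length-trimming rule), below
  which the feature is skipped with a warning.
* The FASTQ reader validates record structure strictly (truncated
  records and sequence/quality length mismatches are format errors)
  because permissive readers pad such records silently.

## Known limitations

* No spliced alignment: eukaryotic CDS counting ignores introns, as the
  emulated workflow does.
* No quality-aware scoring or gapped seeding; only substitution errors
  are simulated.
* Strictly pairwise: exactly two organisms per run.
* No expectation-maximization or fractional reassignment of ambiguous
  reads — ambiguity is reported, not resolved.
* The exhaustive aligner is quadratic and intended for validation and
  small references, not production mapping.
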