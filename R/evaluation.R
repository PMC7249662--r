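#' Confusion counts for one organism of a partitioned pair
#'
#' For organism O of a two-organism partition: TP = reads of O assigned
#' to O; FN = reads of O assigned to the other organism; FP = reads of
#' the other organism assigned to O; TN = reads of the other organism
#' assigned to it. Reads assigned `unmapped` (including ambiguous reads
#' removed by the combined strategy) are excluded from all four cells and
#' tracked in `excluded_unmapped`.
#'
#' @param organism organism label.
#' @param tp,fp,tn,fn non-negative read counts.
#' @param excluded_unmapped reads excluded from the matrix.
#' @return list of class `confusion_counts`.
#' @export
confusion_counts <- function(organism, tp, fp, tn, fn,
                             excluded_unmapped = 0) {
  stopifnot(min(tp, fp, tn, fn, excluded_unmapped) >= 0)
  structure(list(organism = organism, TP = tp, FP = fp, TN = tn, FN = fn,
                 excluded_unmapped = excluded_unmapped),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion counts>", x$organism, "\n")
  cat(sprintf("  TP %s  FN %s\n  FP %s  TN %s  (excluded: %s)\n",
              format(x$TP, big.mark = ","), format(x$FN, big.mark = ","),
              format(x$FP, big.mark = ","), format(x$TN, big.mark = ","),
              format(x$excluded_unmapped, big.mark = ",")))
  invisible(x)
}

#' Cross-tabulate an attribution table against its truth labels
#'
#' @param table an `attribution_table` whose every row carries a truth
#'   label (simulated reads, or a chimera built from pre-filtered
#'   single-organism libraries).
#' @return list of two `confusion_counts`, one per organism. The two are
#'   related by the swap symmetry TP <-> TN, FP <-> FN.
#' @export
cross_tabulate <- function(table) {
  stopifnot(inherits(table, "attribution_table"))
  if (any(is.na(table$truth)))
    stop("cross_tabulate requires a truth label on every read")
  orgs <- attr(table, "organisms")
  if (any(!table$truth %in% orgs))
    stop("truth labels outside the organism pair: ",
         setdiff(table$truth, orgs)[1])
  excl <- sum(table$assigned == "unmapped")
  kept <- table[table$assigned != "unmapped", , drop = FALSE]
  one <- function(o) {
    other <- setdiff(orgs, o)
    confusion_counts(
      o,
      tp = sum(kept$truth == o & kept$assigned == o),
      fn = sum(kept$truth == o & kept$assigned == other),
      fp = sum(kept$truth == other & kept$assigned == o),
      tn = sum(kept$truth == other & kept$assigned == other),
      excluded_unmapped = excl)
  }
  stats::setNames(lapply(orgs, one), orgs)
}

#' Closed-form confusion counts for sequential partitioning
#'
#' Counterpart of [cross_tabulate()] when the chimera library was built
#' from two pre-filtered libraries (each read maps to its own genome, so
#' no read ends up unmapped): mapping A first sends every cross-mappable
#' read of B to A, and nothing of A to B.
#'
#' @inheritParams sequential_attribution_counts
#' @return list of two `confusion_counts` (A then B).
#' @export
sequential_confusion <- function(n_a, n_b, cross_a_to_b, cross_b_to_a,
                                 order = c("A_first", "B_first"),
                                 organisms = c("A", "B")) {
  order <- match.arg(order)
  if (order == "A_first") {
    a <- confusion_counts(organisms[1], tp = n_a, fn = 0,
                          fp = cross_b_to_a, tn = n_b - cross_b_to_a)
    b <- confusion_counts(organisms[2], tp = n_b - cross_b_to_a,
                          fn = cross_b_to_a, fp = 0, tn = n_a)
  } else {
    a <- confusion_counts(organisms[1], tp = n_a - cross_a_to_b,
                          fn = cross_a_to_b, fp = 0, tn = n_b)
    b <- confusion_counts(organisms[2], tp = n_b, fn = 0,
                          fp = cross_a_to_b, tn = n_a - cross_a_to_b)
  }
  stats::setNames(list(a, b), organisms)
}

#' Confusion counts for combined partitioning from per-library counts
#'
#' When each single-organism library is mapped separately against the
#' combined reference, the four attribution counts directly populate the
#' confusion matrix; reads the combined strategy left unmapped or
#' removed as ambiguous are excluded from all denominators.
#'
#' @param a_to_a,a_to_b reads of A's library attributed to A resp. B.
#' @param b_to_a,b_to_b reads of B's library attributed to A resp. B.
#' @param unmapped reads removed (unmapped or ambiguous).
#' @param organisms length-2 character labels.
#' @return list of two `confusion_counts` (A then B).
#' @export
combined_confusion <- function(a_to_a, a_to_b, b_to_a, b_to_b,
                               unmapped = 0, organisms = c("A", "B")) {
  a <- confusion_counts(organisms[1], tp = a_to_a, fn = a_to_b,
                        fp = b_to_a, tn = b_to_b,
                        excluded_unmapped = unmapped)
  b <- confusion_counts(organisms[2], tp = b_to_b, fn = b_to_a,
                        fp = a_to_b, tn = a_to_a,
                        excluded_unmapped = unmapped)
  stats::setNames(list(a, b), organisms)
}

#' Round half away from zero
#'
#' Fixed-precision rounding where `.xxxx5` always rounds up (R's
#' `round()` rounds half to even), matching how benchmark metrics are
#' conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sensitivity, specificity, accuracy and precision
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP). Accuracy is
#' by construction identical for the two organisms of a pair. A zero
#' denominator yields `NA` for that metric with a warning, never a
#' silent 0.
#'
#' @param x a `confusion_counts`.
#' @return list of class `metric_set` with full-precision values;
#'   `print()` reports them rounded half-up to 4 decimals.
#' @export
compute_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    num / den
  }
  structure(list(
    organism = x$organism,
    sensitivity = div(x$TP, x$TP + x$FN, "sensitivity"),
    specificity = div(x$TN, x$TN + x$FP, "specificity"),
    accuracy = div(x$TP + x$TN, x$TP + x$TN + x$FP + x$FN, "accuracy"),
    precision = div(x$TP, x$TP + x$FP, "precision")),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metrics>", x$organism, "\n")
  for (m in c("sensitivity", "specificity", "accuracy", "precision"))
    cat(sprintf("  %-11s %s\n", m,
                formatC(round_half_up(x[[m]], 4), format = "f",
                        digits = 4)))
  invisible(x)
}

#' Count cross-mapping reads of a library on a foreign genome
#'
#' A cross-mapping is a read from one organism's library that attains at
#' least one admissible placement on the *other* organism's genome.
#'
#' @param reads a `read_library` originating from the other organism.
#' @param foreign the foreign [genome].
#' @param params a [mapping_params()].
#' @return Number of cross-mapping reads.
#' @export
crossmap_assay <- function(reads, foreign, params = mapping_params()) {
  stopifnot(inherits(foreign, "genome"))
  reads <- as_read_library(reads)
  if (nrow(reads) == 0) return(0L)
  idx <- build_index(foreign, params$kmer_size)
  ms <- map_reads(reads, idx, params)
  sum(ms$status != "unmapped")
}

#' Run and benchmark all three partitioning strategies
#'
#' Partitions a truth-tagged library with both sequential orders and the
#' combined strategy, cross-tabulates each result against the truth
#' tags, computes the four benchmark metrics per organism, and (when
#' annotations are given) counts each organism's extracted reads per
#' feature category.
#'
#' @param reads a truth-tagged `read_library`.
#' @param genome_a,genome_b the two [genome]s.
#' @param features_a,features_b optional feature tables; when supplied, a
#'   per-strategy count summary is produced for each organism.
#' @param params a [mapping_params()].
#' @param tie_margin ambiguity margin for the combined strategy.
#' @param cparams a [count_params()] for the counting stage.
#' @return Object of class `strategy_comparison` with elements `tables`
#'   (attribution tables), `totals` (strategy x organism matrix),
#'   `confusion`, `metrics` (data.frame), `counts` (nested list or
#'   `NULL`).
#' @export
compare_strategies <- function(reads, genome_a, genome_b,
                               features_a = NULL, features_b = NULL,
                               params = mapping_params(),
                               tie_margin = 0,
                               cparams = count_params()) {
  reads <- as_read_library(reads)
  combined <- combine_references(genome_a, genome_b)
  tables <- list(
    sequential_A_first = sequential_partition(reads, genome_a, genome_b,
                                              params),
    sequential_B_first = sequential_partition(reads, genome_b, genome_a,
                                              params),
    combined = combined_partition(reads, combined, params, tie_margin))
  orgs <- c(genome_a$organism, genome_b$organism)
  totals <- t(vapply(tables, function(tab)
    attribution_totals(tab)[c(orgs, "unmapped")],
    numeric(length(orgs) + 1)))
  have_truth <- !any(is.na(tables$combined$truth))
  confusion <- metrics <- NULL
  if (have_truth) {
    confusion <- lapply(tables, cross_tabulate)
    metrics <- do.call(rbind, lapply(names(confusion), function(s) {
      do.call(rbind, lapply(confusion[[s]], function(cc) {
        m <- compute_metrics(cc)
        data.frame(strategy = s, organism = cc$organism,
                   sensitivity = m$sensitivity,
                   specificity = m$specificity,
                   accuracy = m$accuracy, precision = m$precision,
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(metrics) <- NULL
  }
  counts <- NULL
  if (!is.null(features_a) && !is.null(features_b)) {
    counts <- lapply(tables, function(tab) {
      list(
        a = count_reads(extract_reads(tab, reads, genome_a$organism),
                        genome_a, features_a, cparams),
        b = count_reads(extract_reads(tab, reads, genome_b$organism),
                        genome_b, features_b, cparams))
    })
  }
  structure(list(tables = tables, totals = totals,
                 confusion = confusion, metrics = metrics,
                 counts = counts, organisms = orgs),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy comparison>", paste(x$organisms, collapse = " vs "),
      "\n\nattributed reads:\n")
  print(x$totals)
  if (!is.null(x$metrics)) {
    cat("\nbenchmark metrics (rounded half-up to 4 decimals):\n")
    m <- x$metrics
    for (col in c("sensitivity", "specificity", "accuracy", "precision"))
      m[[col]] <- round_half_up(m[[col]], 4)
    print(m)
  }
  invisible(x)
}

#' @export
#' @method summary strategy_comparison
summary.strategy_comparison <- function(object, ...) {
  out <- list(totals = object$totals, metrics = object$metrics)
  if (!is.null(object$counts))
    out$counts <- do.call(rbind, lapply(names(object$counts),
      function(s) {
        rbind(cbind(strategy = s, summary(object$counts[[s]]$a)),
              cbind(strategy = s, summary(object$counts[[s]]$b)))
      }))
  out
}

#' Bundled example: maize / H. seropedicae chimera benchmark counts
#'
#' Library sizes, cross-mapping counts and combined-reference attribution
#' counts for a chimera library built from pre-filtered *Herbaspirillum
#' seropedicae* and *Zea mays* RNA-Seq libraries (mapping thresholds
#' 0.8/0.8). These printed counts are the inputs from which the
#' closed-form attribution totals and all benchmark metrics can be
#' recomputed; see [sequential_attribution_counts()],
#' [sequential_confusion()] and [combined_confusion()].
#'
#' @return Named list of counts: `n_hs`, `n_zm` (filtered library
#'   sizes), `cross_hs_to_zm`, `cross_zm_to_hs` (cross-mappings),
#'   `hs_to_hs`, `hs_to_zm`, `zm_to_hs`, `zm_to_zm` (per-library
#'   combined-reference attributions), `combined_unmapped`, and the
#'   organism labels.
#' @export
example_chimera_counts <- function() {
  list(organisms = c(hs = "H. seropedicae", zm = "Z. mays"),
       n_hs = 44469308, n_zm = 22200875,
       cross_hs_to_zm = 13847693, cross_zm_to_hs = 7659,
       hs_to_hs = 43661668, hs_to_zm = 779556,
       zm_to_hs = 394, zm_to_zm = 22200465,
       combined_unmapped = 28100)
}

#' Recompute the chimera benchmark from its printed counts
#'
#' Applies the closed-form attribution rule and the confusion-matrix
#' metrics to a set of benchmark counts (by default
#' [example_chimera_counts()]): both sequential orders and the combined
#' strategy, each with sensitivity/specificity/accuracy/precision per
#' organism rounded half-up to 4 decimals.
#'
#' @param counts a list shaped like [example_chimera_counts()].
#' @return list with `totals` (attributed reads per strategy) and
#'   `metrics` (data.frame of rounded metric cells).
#' @export
chimera_benchmark <- function(counts = example_chimera_counts()) {
  orgs <- unname(counts$organisms)
  tot_euk <- sequential_attribution_counts(
    counts$n_zm, counts$n_hs, counts$cross_zm_to_hs,
    counts$cross_hs_to_zm, order = "A_first", organisms = rev(orgs))
  tot_prok <- sequential_attribution_counts(
    counts$n_hs, counts$n_zm, counts$cross_hs_to_zm,
    counts$cross_zm_to_hs, order = "A_first", organisms = orgs)
  conf <- list(
    eukaryote_first = sequential_confusion(
      counts$n_zm, counts$n_hs, counts$cross_zm_to_hs,
      counts$cross_hs_to_zm, order = "A_first", organisms = rev(orgs)),
    prokaryote_first = sequential_confusion(
      counts$n_hs, counts$n_zm, counts$cross_hs_to_zm,
      counts$cross_zm_to_hs, order = "A_first", organisms = orgs),
    combined = combined_confusion(
      counts$hs_to_hs, counts$hs_to_zm, counts$zm_to_hs,
      counts$zm_to_zm, counts$combined_unmapped, organisms = orgs))
  metrics <- do.call(rbind, lapply(names(conf), function(s) {
    do.call(rbind, lapply(conf[[s]], function(cc) {
      m <- compute_metrics(cc)
      data.frame(strategy = s, organism = cc$organism,
                 sensitivity = round_half_up(m$sensitivity, 4),
                 specificity = round_half_up(m$specificity, 4),
                 accuracy = round_half_up(m$accuracy, 4),
                 precision = round_half_up(m$precision, 4),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(metrics) <- NULL
  list(totals = list(eukaryote_first = tot_euk,
                     prokaryote_first = tot_prok),
       confusion = conf, metrics = metrics)
}
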