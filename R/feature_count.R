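#' Counting parameter set
#'
#' Defaults follow common practice for dual RNA-Seq counting: reads with
#' more than 5 admissible placements are excluded, as are reads mapping
#' only to intergenic regions; admissibility uses the 0.8/0.8 mapping
#' fractions.
#'
#' @param max_hits a read with more admissible placements than this is
#'   excluded from counting (default 5).
#' @param exclude_intergenic drop reads whose placements overlap no
#'   annotated feature (default `TRUE`; when `FALSE` such reads are
#'   reported in a separate `intergenic` tally).
#' @param min_length_fraction,min_similarity_fraction mapping
#'   admissibility thresholds, as [mapping_params()].
#' @param kmer_size seed length used for the counting alignment.
#' @return list of class `count_params`.
#' @export
count_params <- function(max_hits = 5, exclude_intergenic = TRUE,
                         min_length_fraction = 0.8,
                         min_similarity_fraction = 0.8,
                         kmer_size = 15) {
  stopifnot(max_hits >= 1)
  structure(list(max_hits = as.integer(max_hits),
                 exclude_intergenic = isTRUE(exclude_intergenic),
                 min_length_fraction = min_length_fraction,
                 min_similarity_fraction = min_similarity_fraction,
                 kmer_size = as.integer(kmer_size)),
            class = "count_params")
}

CATEGORY_PRIORITY <- c(rRNA = 1, tRNA = 2, CDS = 3)

#' Count reads per annotation category
#'
#' Each read (already attributed to this organism) is mapped against the
#' genome; reads with more than `max_hits` admissible placements, or
#' whose placements overlap no feature, are excluded. A surviving read is
#' assigned to exactly one feature: placements are visited best-score
#' first and, at the first placement overlapping any feature, the feature
#' with maximal overlap wins (ties: category priority rRNA > tRNA > CDS,
#' then lowest start). Reads with a single admissible placement are
#' "unique", all others "multi"; only the CDS tally is split by
#' uniqueness.
#'
#' @param reads a `read_library`.
#' @param genome a [genome].
#' @param features feature data.frame ([read_gff3()] output).
#' @param params a [count_params()].
#' @return Object of class `count_summary`: per-category read counts
#'   (`tRNA`, `rRNA`, `cds_unique`, `cds_multi`, `intergenic`,
#'   `unmapped`), a per-feature count table (`feature_id`, `unique`,
#'   `multi`), the multi-read proportion of the input (fraction), and an
#'   exclusion breakdown.
#' @export
count_reads <- function(reads, genome, features,
                        params = count_params()) {
  stopifnot(inherits(genome, "genome"))
  reads <- as_read_library(reads)
  validate_features(features, genome)
  n <- nrow(reads)
  mp <- mapping_params(min_length_fraction = params$min_length_fraction,
                       min_similarity_fraction =
                         params$min_similarity_fraction,
                       max_hits = params$max_hits,
                       kmer_size = params$kmer_size)
  category <- rep(NA_character_, n)   # per-read assigned category
  feature_of <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  is_multi <- rep(FALSE, n)
  if (n > 0) {
    idx <- build_index(genome, params$kmer_size)
    ms <- map_reads(reads, idx, mp)
    reason[ms$status == "unmapped"] <- "no_placement"
    over_cap <- ms$n_admissible > params$max_hits
    reason[over_cap] <- "too_many_hits"
    eligible <- ms$status != "unmapped" & !over_cap
    is_multi <- ms$n_admissible > 1
    pl <- ms$placements
    pl <- pl[eligible[pl$read], , drop = FALSE]
    if (nrow(pl) && nrow(features)) {
      pl$rank <- stats::ave(pl$score, pl$read,
                            FUN = function(x) seq_along(x))
      pgr <- GenomicRanges::GRanges(
        pl$contig, IRanges::IRanges(pl$start, pl$end))
      fgr <- GenomicRanges::GRanges(
        features$contig, IRanges::IRanges(features$start, features$end))
      ov <- GenomicRanges::findOverlaps(pgr, fgr, ignore.strand = TRUE)
      if (length(ov)) {
        qh <- S4Vectors::queryHits(ov)
        sh <- S4Vectors::subjectHits(ov)
        width <- IRanges::width(IRanges::pintersect(
          IRanges::ranges(pgr)[qh], IRanges::ranges(fgr)[sh]))
        hits <- data.frame(read = pl$read[qh], rank = pl$rank[qh],
                           feature = sh, width = width)
        for (sub in split(hits, hits$read)) {
          r <- sub$read[1]
          sub <- sub[sub$rank == min(sub$rank), , drop = FALSE]
          ord <- order(-sub$width,
                       CATEGORY_PRIORITY[features$category[sub$feature]],
                       features$start[sub$feature])
          f <- sub$feature[ord[1]]
          feature_of[r] <- features$feature_id[f]
          category[r] <- features$category[f]
        }
      }
    }
    intergenic <- eligible & is.na(category)
    reason[intergenic] <- "intergenic"
  }
  counted <- !is.na(category)
  tally <- function(cat, multi = NULL) {
    keep <- counted & category == cat
    if (!is.null(multi)) keep <- keep & (is_multi == multi)
    sum(keep)
  }
  intergenic_n <- sum(reason == "intergenic", na.rm = TRUE)
  counts <- c(tRNA = tally("tRNA"), rRNA = tally("rRNA"),
              cds_unique = tally("CDS", FALSE),
              cds_multi = tally("CDS", TRUE),
              intergenic = if (params$exclude_intergenic) 0L
                           else intergenic_n,
              unmapped = sum(!counted) -
                if (params$exclude_intergenic) 0L else intergenic_n)
  per_feature <- data.frame(feature_id = features$feature_id,
                            category = features$category,
                            unique = 0L, multi = 0L,
                            stringsAsFactors = FALSE)
  if (any(counted)) {
    tu <- table(feature_of[counted & !is_multi])
    tm <- table(feature_of[counted & is_multi])
    per_feature$unique <- as.integer(tu[per_feature$feature_id])
    per_feature$multi <- as.integer(tm[per_feature$feature_id])
    per_feature$unique[is.na(per_feature$unique)] <- 0L
    per_feature$multi[is.na(per_feature$multi)] <- 0L
  }
  breakdown <- table(factor(reason[!counted],
                            levels = c("no_placement", "too_many_hits",
                                       "intergenic")))
  structure(list(counts = counts,
                 per_feature = per_feature,
                 n_reads = n,
                 multiread_fraction =
                   if (n > 0) unname(counts["cds_multi"]) / n else 0,
                 exclusion_breakdown = as.list(breakdown),
                 params = params,
                 organism = genome$organism),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat("<count summary>", x$organism, "-", x$n_reads, "read(s)\n")
  print(x$counts)
  cat(sprintf("proportion of multi-reads from total: %.2f%%\n",
              100 * x$multiread_fraction))
  invisible(x)
}

#' @export
#' @method summary count_summary
summary.count_summary <- function(object, ...) {
  data.frame(organism = object$organism,
             tRNA = object$counts[["tRNA"]],
             rRNA = object$counts[["rRNA"]],
             cds_unique = object$counts[["cds_unique"]],
             cds_multi = object$counts[["cds_multi"]],
             unmapped = object$counts[["unmapped"]] +
               object$counts[["intergenic"]],
             multiread_percent = 100 * object$multiread_fraction,
             stringsAsFactors = FALSE)
}

#' Proportion of multi-reads in a counted library
#'
#' @param summary a `count_summary`.
#' @return The CDS multi-read share of the *input* reads, as a
#'   percentage.
#' @export
multiread_proportion <- function(summary) {
  stopifnot(inherits(summary, "count_summary"))
  if (summary$n_reads == 0) {
    warning("zero input reads; multi-read proportion undefined, ",
            "returning 0")
    return(0)
  }
  100 * summary$counts[["cds_multi"]] / summary$n_reads
}
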