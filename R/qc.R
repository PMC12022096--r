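#' Control-calibrated depletion (or enrichment) threshold
#'
#' The threshold below which a guide is called depleted is the 5th
#' percentile (linear interpolation, type-7 quantile) of the
#' negative-control LFC distribution. For enrichment calls use
#' `percentile = 95` and direction `"above"` in [category_rates()].
#'
#' @param lfc_table An `lfc_table` with a `category` column.
#' @param percentile Percentile of the NEG distribution; default 5.
#' @param use_replicates If `TRUE`, pool per-replicate LFCs instead of
#'   replicate means (some analyses pool replicates for distributional
#'   summaries); default `FALSE`.
#' @return The threshold, in LFC units.
#' @export
depletion_threshold <- function(lfc_table, percentile = 5,
                                use_replicates = FALSE) {
  vals <- category_values(lfc_table, "NEG", use_replicates)
  if (length(vals) < 5L)
    stop("need at least 5 NEG-control LFC values to calibrate a threshold",
         call. = FALSE)
  unname(stats::quantile(vals, percentile / 100, type = 7))
}

category_values <- function(lfc_table, cat, use_replicates = FALSE) {
  rows <- lfc_table$category %in% cat & !lfc_table$filtered
  if (use_replicates) {
    cols <- grep("^lfc_rep", names(lfc_table), value = TRUE)
    unlist(lfc_table[rows, cols], use.names = FALSE)
  } else {
    lfc_table$lfc_mean[rows]
  }
}

#' Per-category fraction of guides beyond a threshold
#'
#' Fraction of unfiltered guides in each category with LFC strictly below
#' (`direction = "below"`, depletion) or strictly above
#' (`direction = "above"`, enrichment) the threshold. Boundary values are
#' not called.
#'
#' @param lfc_table An `lfc_table`.
#' @param threshold LFC threshold, e.g. from [depletion_threshold()].
#' @param direction `"below"` or `"above"`.
#' @param use_replicates Pool per-replicate LFCs instead of means.
#' @return Named numeric vector, one rate per category present (empty
#'   categories give `NA`).
#' @export
category_rates <- function(lfc_table, threshold, direction = c("below", "above"),
                           use_replicates = FALSE) {
  direction <- match.arg(direction)
  cats <- c("NEG", "POS", "CDS", "NT")
  rates <- vapply(cats, function(cat) {
    vals <- category_values(lfc_table, cat, use_replicates)
    if (length(vals) == 0L) return(NA_real_)
    if (direction == "below") mean(vals < threshold)
    else mean(vals > threshold)
  }, numeric(1))
  rates[!is.na(rates) | cats %in% lfc_table$category]
}

#' ROC AUC separating positive from negative controls
#'
#' The AUC is computed as the normalised Mann-Whitney U statistic of the
#' scores (default score = -LFC, so more depleted means higher score): the
#' fraction of (POS, NEG) pairs in which the positive control outranks the
#' negative, ties counting one half. This equals the area under the
#' empirical ROC curve.
#'
#' @param lfc_table An `lfc_table`.
#' @param positives,negatives Category labels of the two control sets.
#' @param score Function mapping LFC to score; default `function(x) -x`.
#' @param use_replicates Pool per-replicate LFCs instead of means.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(lfc_table, positives = "POS", negatives = "NEG",
                    score = function(x) -x, use_replicates = FALSE) {
  pos <- score(category_values(lfc_table, positives, use_replicates))
  neg <- score(category_values(lfc_table, negatives, use_replicates))
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both control sets must be non-empty", call. = FALSE)
  auc_rank(pos, neg)
}

# Rank-based AUC: P(pos > neg) + 0.5 * P(pos == neg).
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

#' Rank-sum comparison of two groups
#'
#' Unpaired two-tailed Wilcoxon rank-sum (Mann-Whitney) test with the
#' tie-corrected normal approximation and continuity correction.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 3).
#' @return List with `U` (the Mann-Whitney statistic for `values_a` vs
#'   `values_b`), `p` (two-sided) and the group medians.
#' @export
rank_sum_compare <- function(values_a, values_b) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("both groups need at least 3 values", call. = FALSE)
  ht <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       median_a = stats::median(values_a),
       median_b = stats::median(values_b))
}

#' Full screen QC report
#'
#' Calibrates the depletion (or enrichment) threshold on negative controls,
#' reports per-category rates, the POS-vs-NEG ROC AUC and rank-sum
#' comparisons of each category against the negative controls.
#'
#' @param lfc_table An `lfc_table`.
#' @param percentile NEG percentile for the threshold (5 for depletion
#'   screens, 95 for enrichment screens).
#' @param direction `"below"` or `"above"`.
#' @return Object of class `qc_report`: list with `threshold`,
#'   `category_rates`, `auc`, `group_tests`.
#' @export
qc_report <- function(lfc_table, percentile = 5,
                      direction = c("below", "above")) {
  direction <- match.arg(direction)
  thr <- depletion_threshold(lfc_table, percentile)
  rates <- category_rates(lfc_table, thr, direction)
  auc <- roc_auc(lfc_table)
  neg <- category_values(lfc_table, "NEG")
  tests <- list()
  for (cat in setdiff(intersect(c("POS", "CDS", "NT"),
                                unique(lfc_table$category)), "NEG")) {
    vals <- category_values(lfc_table, cat)
    if (length(vals) >= 3L && length(neg) >= 3L)
      tests[[paste0(cat, "_vs_NEG")]] <- rank_sum_compare(vals, neg)
  }
  structure(list(threshold = thr, category_rates = rates, auc = auc,
                 group_tests = tests, direction = direction),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("screen QC (%s threshold %.3f):\n", x$direction, x$threshold))
  for (cat_ in names(x$category_rates))
    cat(sprintf("  %-3s rate %s: %s\n", cat_, x$direction,
                ifelse(is.na(x$category_rates[[cat_]]), "NA",
                       sprintf("%.1f%%", 100 * x$category_rates[[cat_]]))))
  cat(sprintf("  POS vs NEG AUC: %.3f\n", x$auc))
  for (nm in names(x$group_tests))
    cat(sprintf("  %s: U = %g, p = %.3g\n", nm, x$group_tests[[nm]]$U,
                x$group_tests[[nm]]$p))
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @export
write_qc <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
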