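#' Reads-per-million normalisation
#'
#' `RPM = counts / column total * 1e6`, per sample. Depth normalisation only;
#' no pseudocount is applied here (the pseudocount enters on the RPM scale in
#' [compute_lfc()]).
#'
#' @param count_matrix A `count_matrix`.
#' @return Numeric matrix of the same shape; every column sums to 1e6.
#' @export
rpm <- function(count_matrix) {
  cts <- count_matrix$counts
  totals <- colSums(cts)
  zero <- totals == 0
  if (any(zero))
    stop("zero total counts in sample(s): ",
         paste(colnames(cts)[zero], collapse = ", "), call. = FALSE)
  sweep(cts, 2L, totals, "/") * 1e6
}

#' Define a screen contrast
#'
#' A contrast names a numerator and a denominator sample selector. Each
#' selector is a list of sample-sheet fields (`cell_line`, `day`,
#' `treatment`); a field left `NULL` matches anything. Replicates are paired
#' by replicate index (`pairwise_then_mean`): LFC is computed per replicate
#' pair and then averaged.
#'
#' @param name Contrast label, e.g. `"PAR/Cas9-D14"` for Cas9 line day 14
#'   over parental line day 0.
#' @param numerator,denominator Selector lists, e.g.
#'   `list(cell_line = "CAS9", day = 14)`.
#' @param replicate_policy Only `"pairwise_then_mean"` is implemented.
#' @return An object of class `contrast`.
#' @export
contrast <- function(name, numerator, denominator,
                     replicate_policy = "pairwise_then_mean") {
  replicate_policy <- match.arg(replicate_policy, "pairwise_then_mean")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator,
                 replicate_policy = replicate_policy),
            class = "contrast")
}

#' Read contrasts from a YAML config
#'
#' The file holds a top-level `contrasts:` list; each entry has `name`,
#' `numerator` and `denominator` keys whose sub-keys are selector fields.
#'
#' @param path Path to a YAML file.
#' @return List of [contrast()] objects.
#' @export
read_contrasts <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading contrast configs requires the 'yaml' package",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  lapply(cfg$contrasts, function(x)
    contrast(x$name, x$numerator, x$denominator))
}

select_samples <- function(samples, selector) {
  keep <- rep(TRUE, nrow(samples))
  for (field in intersect(names(selector), names(samples))) {
    if (!is.null(selector[[field]]))
      keep <- keep & samples[[field]] %in% selector[[field]]
  }
  samples[keep, , drop = FALSE]
}

#' Per-sgRNA log2 fold changes for a contrast
#'
#' Per replicate pair `r`:
#' `lfc_r = log2(RPM_num,r + 1) - log2(RPM_den,r + 1)`, then
#' `lfc_mean = mean(lfc_r)`. The +1 pseudocount is applied on the RPM scale.
#'
#' @param count_matrix A `count_matrix` (RPM is computed internally).
#' @param contrast A [contrast()].
#' @param library Optional `sg_library`; when given, guide `category` and
#'   `residues` are attached to the output.
#' @return An `lfc_table` data.frame with columns `sgrna_id`, `category`,
#'   `residues` (list column), `lfc_rep<k>`, `lfc_mean`, `filtered`,
#'   `filter_reason`, `corrected_lfc`.
#' @export
compute_lfc <- function(count_matrix, contrast, library = NULL) {
  mat <- rpm(count_matrix)
  samples <- count_matrix$samples
  num <- select_samples(samples, contrast$numerator)
  den <- select_samples(samples, contrast$denominator)
  if (nrow(num) == 0L || nrow(den) == 0L)
    stop("contrast '", contrast$name, "' selects no ",
         if (nrow(num) == 0L) "numerator" else "denominator", " samples",
         call. = FALSE)
  reps <- sort(intersect(num$replicate, den$replicate))
  if (length(reps) == 0L ||
      !setequal(num$replicate, den$replicate))
    stop("contrast '", contrast$name,
         "': replicate indices do not pair up (numerator: ",
         paste(sort(num$replicate), collapse = ","), "; denominator: ",
         paste(sort(den$replicate), collapse = ","), ")", call. = FALSE)
  lfc_rep <- sapply(reps, function(r) {
    ni <- num$sample_id[num$replicate == r]
    di <- den$sample_id[den$replicate == r]
    if (length(ni) != 1L || length(di) != 1L)
      stop("contrast '", contrast$name, "' replicate ", r,
           " selects more than one sample per side", call. = FALSE)
    log2(mat[, ni] + 1) - log2(mat[, di] + 1)
  })
  lfc_rep <- matrix(lfc_rep, nrow = nrow(mat),
                    dimnames = list(rownames(mat),
                                    paste0("lfc_rep", reps)))
  out <- data.frame(sgrna_id = rownames(mat), stringsAsFactors = FALSE)
  if (!is.null(library)) {
    idx <- match(out$sgrna_id, library$sgrnas$sgrna_id)
    out$category <- library$sgrnas$category[idx]
    out$residues <- library$sgrnas$residues[idx]
  } else {
    out$category <- NA_character_
    out$residues <- replicate(nrow(out), integer(0), simplify = FALSE)
  }
  out <- cbind(out, as.data.frame(lfc_rep))
  out$lfc_mean <- rowMeans(lfc_rep)
  out$filtered <- FALSE
  out$filter_reason <- NA_character_
  out$corrected_lfc <- NA_real_
  attr(out, "contrast") <- contrast$name
  class(out) <- c("lfc_table", "data.frame")
  out
}

#' Flag guides with too few reads in a reference sample
#'
#' Guides whose raw count in `reference_sample` is strictly below
#' `min_count` are flagged `filtered` with reason `"low_count"`; they remain
#' in the table but are excluded from residue mapping and binning.
#'
#' @param lfc_table An `lfc_table`.
#' @param count_matrix The `count_matrix` the table came from.
#' @param reference_sample Sample id of the reference (typically the
#'   parental line at day 0).
#' @param min_count Threshold; default 300 reads.
#' @return The `lfc_table` with updated `filtered`/`filter_reason`.
#' @export
filter_low_counts <- function(lfc_table, count_matrix, reference_sample,
                              min_count = 300L) {
  if (!(reference_sample %in% colnames(count_matrix$counts)))
    stop("reference sample not in count matrix: ", reference_sample,
         call. = FALSE)
  ref <- count_matrix$counts[lfc_table$sgrna_id, reference_sample]
  low <- ref < min_count
  lfc_table$filtered[low] <- TRUE
  lfc_table$filter_reason[low] <- "low_count"
  lfc_table
}

#' Correct LFCs for predicted on-target activity
#'
#' Deep-learning on-target scores (e.g. CRISPRon output) are consumed as a
#' plain numeric vector. Scores on a 0-100 scale are rescaled to (0, 1].
#' The corrected value is `lfc_mean / max(activity, floor)`; dividing by a
#' number in (0, 1] scales weakly-cutting guides up without ever flipping
#' the sign, and the floor caps the amplification for near-dead guides.
#'
#' @param lfc_table An `lfc_table`.
#' @param activity_scores Named numeric vector (names = sgrna_id) of
#'   on-target activities in (0, 1] or (0, 100].
#' @param floor Minimum activity used as divisor; default 0.2.
#' @return The `lfc_table` with `corrected_lfc` set for scored guides;
#'   unscored unfiltered CDS guides keep `NA` with a warning.
#' @export
activity_correct <- function(lfc_table, activity_scores, floor = 0.2) {
  if (any(activity_scores <= 0, na.rm = TRUE))
    stop("activity scores must be positive", call. = FALSE)
  if (any(activity_scores > 1, na.rm = TRUE))
    activity_scores <- activity_scores / 100
  if (any(activity_scores > 1, na.rm = TRUE))
    stop("activity scores must lie in (0, 1] or (0, 100]", call. = FALSE)
  act <- activity_scores[lfc_table$sgrna_id]
  has <- !is.na(act)
  lfc_table$corrected_lfc[has] <-
    lfc_table$lfc_mean[has] / pmax(act[has], floor)
  need <- lfc_table$category %in% "CDS" & !lfc_table$filtered & !has
  if (any(need))
    warning(sum(need), " unfiltered CDS guide(s) lack activity scores; ",
            "corrected_lfc left NA")
  lfc_table
}

#' Write an LFC table as TSV
#'
#' The list column `residues` is serialised as comma-joined positions.
#'
#' @param lfc_table An `lfc_table`.
#' @param path Output path.
#' @export
write_lfc <- function(lfc_table, path) {
  df <- lfc_table
  df$residues <- vapply(df$residues, paste, character(1), collapse = ",")
  class(df) <- "data.frame"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
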