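#' Rank sgRNAs into quantile bins
#'
#' Unfiltered CDS guides are sorted by `lfc_mean` in decreasing order (most
#' enriched first) and split into `n_bins` contiguous rank groups as equal
#' in size as possible; with `N = k * n_bins + r`, the first `r` bins get
#' one extra guide. Bin 1 holds the most enriched guides, bin `n_bins` the
#' most depleted. Ties in LFC are broken by `sgrna_id` (lexicographic) for
#' determinism.
#'
#' @param lfc_table An `lfc_table`.
#' @param n_bins Number of bins; default 17.
#' @param categories Categories entering the ranking; default `"CDS"` only.
#' @return Named integer vector of bin indices over the binned guides.
#' @export
bin_sgrnas <- function(lfc_table, n_bins = 17L, categories = "CDS") {
  rows <- lfc_table$category %in% categories & !lfc_table$filtered
  ids <- lfc_table$sgrna_id[rows]
  lfc <- lfc_table$lfc_mean[rows]
  n <- length(ids)
  if (n < n_bins)
    stop("need at least ", n_bins, " scored guides to form ", n_bins,
         " bins (have ", n, ")", call. = FALSE)
  ord <- order(-lfc, ids)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- rep(seq_len(n_bins), times = sizes)
  out <- integer(n)
  out[ord] <- bins
  names(out) <- ids
  out
}

#' Project guide scores onto protein residues
#'
#' For every residue 1..n_residues: `mean_lfc` is the mean `lfc_mean` of the
#' unfiltered CDS guides assigned to it, `best_bin` the extreme bin among
#' them (maximum bin index for drop-out tracks, where bin 17 is most
#' depleted; minimum for enrichment tracks, where bin 1 is most enriched),
#' `n_guides` the number of assigned guides.
#'
#' @param lfc_table An `lfc_table` with `residues` resolved.
#' @param bins Bin assignment from [bin_sgrnas()].
#' @param gene_model A [gene_model()].
#' @param direction `"depleted"` (drop-out) or `"enriched"`.
#' @param use_corrected Use `corrected_lfc` instead of `lfc_mean` for the
#'   residue means (bins are whatever was passed in).
#' @return A `residue_track` data.frame with columns `residue`, `aa`,
#'   `n_guides`, `mean_lfc`, `best_bin`, `covered`, plus a `sgrnas` list
#'   column of supporting guide ids.
#' @export
residue_track <- function(lfc_table, bins, gene_model,
                          direction = c("depleted", "enriched"),
                          use_corrected = FALSE) {
  direction <- match.arg(direction)
  n <- gene_model$n_residues
  aa <- strsplit(gene_model$protein_seq, "")[[1L]]
  track <- data.frame(residue = seq_len(n), aa = aa, n_guides = 0L,
                      mean_lfc = NA_real_, best_bin = NA_integer_,
                      covered = FALSE, stringsAsFactors = FALSE)
  track$sgrnas <- replicate(n, character(0), simplify = FALSE)
  rows <- which(lfc_table$sgrna_id %in% names(bins))
  score <- if (use_corrected) lfc_table$corrected_lfc else lfc_table$lfc_mean
  acc <- vector("list", n)
  for (i in rows) {
    for (r in lfc_table$residues[[i]]) {
      if (r < 1L || r > n) next
      acc[[r]] <- c(acc[[r]], i)
    }
  }
  pick <- if (direction == "depleted") max else min
  for (r in seq_len(n)) {
    if (is.null(acc[[r]])) next
    idx <- acc[[r]]
    track$n_guides[r] <- length(idx)
    track$mean_lfc[r] <- mean(score[idx])
    track$best_bin[r] <- pick(bins[lfc_table$sgrna_id[idx]])
    track$covered[r] <- TRUE
    track$sgrnas[[r]] <- lfc_table$sgrna_id[idx]
  }
  attr(track, "direction") <- direction
  class(track) <- c("residue_track", "data.frame")
  track
}

#' Call depleted or enriched regions from a residue track
#'
#' Residues whose `best_bin` falls in `qualifying_bins` (and, when
#' `lfc_cutoff` is given, whose `mean_lfc` is beyond it: below for depleted
#' tracks, above for enriched) seed regions; seeds separated by at most
#' `max_gap` non-qualifying or uncovered residues merge into one region.
#' Labels follow the residue-pair convention: a span of two residues is
#' written `"R234/L235"`-style, longer spans `"R234_G237"`-style, single
#' residues `"A372"`.
#'
#' @param track A `residue_track`.
#' @param qualifying_bins Integer bins that qualify a residue (e.g. `16:17`
#'   for drop-out, `1:2` for enrichment).
#' @param direction `"depleted"` or `"enriched"`; defaults to the track's.
#' @param max_gap Maximum run of non-qualifying residues bridged when
#'   merging; default 1.
#' @param lfc_cutoff Optional absolute effect-size floor in LFC units (a
#'   seed must also pass it); `NULL` disables it.
#' @return A `region_calls` data.frame with `start_res`, `end_res`,
#'   `direction`, `label`, `extreme_lfc`, `n_sgrnas` and a
#'   `supporting_sgrnas` list column.
#' @export
call_regions <- function(track, qualifying_bins, direction = NULL,
                         max_gap = 1L, lfc_cutoff = NULL) {
  if (length(qualifying_bins) == 0L)
    stop("qualifying_bins must be non-empty", call. = FALSE)
  if (is.null(direction)) direction <- attr(track, "direction")
  if (is.null(direction))
    stop("direction not set on track and not supplied", call. = FALSE)
  direction <- match.arg(direction, c("depleted", "enriched"))
  qual <- !is.na(track$best_bin) & track$best_bin %in% qualifying_bins
  if (!is.null(lfc_cutoff)) {
    qual <- qual & !is.na(track$mean_lfc) &
      (if (direction == "depleted") track$mean_lfc < lfc_cutoff
       else track$mean_lfc > lfc_cutoff)
  }
  seeds <- which(qual)
  if (length(seeds) == 0L) return(empty_regions())
  # merge seeds separated by <= max_gap non-qualifying residues
  brk <- c(TRUE, diff(seeds) > max_gap + 1L)
  grp <- cumsum(brk)
  calls <- lapply(split(seeds, grp), function(s) {
    span <- min(s):max(s)
    guides <- sort(unique(unlist(track$sgrnas[s])))
    ext <- if (direction == "depleted") min(track$mean_lfc[s])
           else max(track$mean_lfc[s])
    data.frame(start_res = min(s), end_res = max(s), direction = direction,
               label = region_label(track$aa, min(s), max(s)),
               extreme_lfc = ext, n_sgrnas = length(guides),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out$supporting_sgrnas <- lapply(split(seeds, grp), function(s)
    sort(unique(unlist(track$sgrnas[s]))))
  class(out) <- c("region_calls", "data.frame")
  out
}

empty_regions <- function() {
  out <- data.frame(start_res = integer(0), end_res = integer(0),
                    direction = character(0), label = character(0),
                    extreme_lfc = numeric(0), n_sgrnas = integer(0),
                    stringsAsFactors = FALSE)
  out$supporting_sgrnas <- list()
  class(out) <- c("region_calls", "data.frame")
  out
}

region_label <- function(aa, start, end) {
  if (start == end) paste0(aa[start], start)
  else if (end == start + 1L) paste0(aa[start], start, "/", aa[end], end)
  else paste0(aa[start], start, "_", aa[end], end)
}

#' Write a residue track / region calls as TSV
#'
#' @param x A `residue_track` or `region_calls`.
#' @param path Output path.
#' @export
write_track <- function(x, path) {
  df <- as.data.frame(x)
  for (col in c("sgrnas", "supporting_sgrnas"))
    if (col %in% names(df))
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate a PDB structure with per-residue scores in the B-factor column
#'
#' Rewrites columns 61-66 (the B-factor field) of every `ATOM`/`HETATM`
#' record of the matching chain whose residue number appears in the track;
#' residues without a score get 0.00 (noted in a message). All other bytes
#' of the file are preserved, so the output remains a valid PDB that
#' structure viewers can colour as a heat map.
#'
#' @param pdb_path Input PDB file.
#' @param track A `residue_track`.
#' @param out_path Output PDB file.
#' @param chain_id Chain to annotate; default `"A"`.
#' @param field Which track column to write: `"mean_lfc"` or `"best_bin"`.
#' @return `out_path`, invisibly.
#' @export
export_bfactor <- function(pdb_path, track, out_path, chain_id = "A",
                           field = c("mean_lfc", "best_bin")) {
  field <- match.arg(field)
  lines <- readLines(pdb_path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", pdb_path,
                          call. = FALSE)
  values <- track[[field]]
  n_na <- 0L
  matched <- FALSE
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 66L) ln <- formatC(ln, width = -66L)
    if (substr(ln, 22L, 22L) != chain_id) next
    resno <- suppressWarnings(as.integer(substr(ln, 23L, 26L)))
    if (is.na(resno) || resno < 1L || resno > nrow(track)) next
    matched <- TRUE
    v <- values[resno]
    if (is.na(v)) { v <- 0; n_na <- n_na + 1L }
    substr(ln, 61L, 66L) <- sprintf("%6.2f", v)
    lines[i] <- ln
  }
  if (!matched)
    stop("no residue-number overlap between chain ", chain_id, " of ",
         pdb_path, " and the track", call. = FALSE)
  if (n_na > 0L)
    message(n_na, " atom record(s) at unscored residues set to B = 0.00")
  writeLines(lines, out_path)
  invisible(out_path)
}
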