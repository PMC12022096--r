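#' Sample metadata constructor
#'
#' @param sample_id Unique sample name.
#' @param cell_line `"CAS9"` (nuclease-expressing) or `"PAR"` (parental,
#'   Cas9-negative).
#' @param day Integer day of sampling (>= 0).
#' @param treatment Treatment label, e.g. `"none"`, `"DMSO"`,
#'   `"selumetinib"`.
#' @param replicate Integer replicate index (>= 1).
#' @return One-row data.frame of sample metadata.
#' @export
sample_meta <- function(sample_id, cell_line, day, treatment = "none",
                        replicate = 1L) {
  cell_line <- match.arg(cell_line, c("CAS9", "PAR"))
  data.frame(sample_id = sample_id, cell_line = cell_line,
             day = as.integer(day), treatment = treatment,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

validate_samples <- function(samples) {
  need <- c("sample_id", "cell_line", "day", "treatment", "replicate")
  missing <- setdiff(need, names(samples))
  if (length(missing) > 0L)
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  key <- with(samples, paste(cell_line, day, treatment, replicate))
  if (anyDuplicated(key))
    stop("duplicate (cell_line, day, treatment, replicate) combination",
         call. = FALSE)
  invisible(samples)
}

#' Count sgRNA cassette reads for one sample
#'
#' A read increments exactly one guide when exactly one distinct library
#' protospacer occurs within it, in either orientation (the protospacer
#' itself or its reverse complement as a substring of the read). Reads
#' matching zero or more than one distinct guide are tallied as
#' `unassigned`. Matching is exact; multiple occurrences of the same guide
#' in one read count once.
#'
#' @param fastq_path Path to a FASTQ file (optionally gzipped), or a
#'   character vector of read sequences.
#' @param library An `sg_library`.
#' @return List with `counts` (named integer vector over `sgrna_id`),
#'   `unassigned` (integer) and `n_reads`.
#' @export
count_fastq <- function(fastq_path, library) {
  if (nrow(library$sgrnas) == 0L)
    stop("empty sgRNA library", call. = FALSE)
  reads <- if (is.character(fastq_path) && length(fastq_path) == 1L &&
               file.exists(fastq_path)) {
    Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  } else {
    Biostrings::DNAStringSet(toupper(fastq_path))
  }
  guides <- Biostrings::DNAStringSet(library$sgrnas$protospacer)
  names(guides) <- library$sgrnas$sgrna_id
  counts <- integer(length(guides))
  names(counts) <- names(guides)
  if (length(reads) == 0L)
    return(list(counts = counts, unassigned = 0L, n_reads = 0L))

  pd_fwd <- Biostrings::PDict(guides)
  pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(guides))
  hits_fwd <- Biostrings::vwhichPDict(pd_fwd, reads)
  hits_rev <- Biostrings::vwhichPDict(pd_rev, reads)
  n <- length(reads)
  unassigned <- 0L
  for (i in seq_len(n)) {
    g <- unique(c(hits_fwd[[i]], hits_rev[[i]]))
    if (length(g) == 1L) counts[g] <- counts[g] + 1L
    else unassigned <- unassigned + 1L
  }
  list(counts = counts, unassigned = unassigned, n_reads = n)
}

#' Assemble per-sample count vectors into a count matrix
#'
#' @param vectors Named list (by sample_id) of outputs of [count_fastq()],
#'   or of bare named count vectors.
#' @param samples Sample-sheet data.frame (see [sample_meta()]); row order
#'   fixes column order.
#' @return An object of class `count_matrix`: list with `counts` (integer
#'   matrix, rows = sgRNA, columns = samples), `samples` and `unassigned`
#'   (named integer vector).
#' @export
assemble_matrix <- function(vectors, samples) {
  validate_samples(samples)
  if (!setequal(names(vectors), samples$sample_id))
    stop("vector names and sample sheet sample_ids differ", call. = FALSE)
  vectors <- vectors[samples$sample_id]
  get_counts <- function(v) if (is.list(v)) v$counts else v
  ids <- names(get_counts(vectors[[1L]]))
  counts <- matrix(0L, nrow = length(ids), ncol = length(vectors),
                   dimnames = list(ids, samples$sample_id))
  unassigned <- integer(length(vectors))
  names(unassigned) <- samples$sample_id
  for (j in seq_along(vectors)) {
    v <- get_counts(vectors[[j]])
    missing <- setdiff(ids, names(v))
    extra <- setdiff(names(v), ids)
    if (length(missing) > 0L || length(extra) > 0L)
      stop("sample ", samples$sample_id[j], " has mismatched guide set",
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    counts[, j] <- as.integer(v[ids])
    if (is.list(vectors[[j]]) && !is.null(vectors[[j]]$unassigned))
      unassigned[j] <- vectors[[j]]$unassigned
  }
  count_matrix(counts, samples, unassigned)
}

#' Count matrix constructor
#'
#' @param counts Integer matrix, rows named by sgRNA id, columns by
#'   sample_id.
#' @param samples Sample sheet data.frame.
#' @param unassigned Optional named integer vector of unassigned reads.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, samples, unassigned = NULL) {
  validate_samples(samples)
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id))
    stop("count matrix columns do not match sample sheet order",
         call. = FALSE)
  if (any(counts < 0L)) stop("negative counts", call. = FALSE)
  if (is.null(unassigned)) {
    unassigned <- integer(ncol(counts))
    names(unassigned) <- samples$sample_id
  }
  structure(list(counts = counts, samples = samples,
                 unassigned = unassigned),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sgRNAs x %d samples, median depth %s\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(colSums(x$counts)), big.mark = ",")))
  invisible(x)
}

#' Write / read a count matrix as TSV plus a JSON sidecar
#'
#' `write_counts()` writes the integer matrix as TSV (first column
#' `sgrna_id`) and the sample metadata with unassigned totals as
#' `<path>.json`; `read_counts()` inverts it. Round-tripping is exact.
#'
#' @param matrix A `count_matrix`.
#' @param path Output TSV path.
#' @export
write_counts <- function(matrix, path) {
  df <- data.frame(sgrna_id = rownames(matrix$counts), matrix$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(samples = matrix$samples,
                  unassigned = as.list(matrix$unassigned))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_counts
#' @return `read_counts()` returns a `count_matrix`.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$sgrna_id
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- as.data.frame(side$samples, stringsAsFactors = FALSE)
  unassigned <- as.integer(unlist(side$unassigned))
  names(unassigned) <- names(side$unassigned)
  count_matrix(counts[, samples$sample_id, drop = FALSE], samples,
               unassigned[samples$sample_id])
}
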