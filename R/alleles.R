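#' Define an amplicon around an edited locus
#'
#' The amplicon carries the coordinate bridge between read space and the
#' CDS: `cds_offset` is the 0-based position in the amplicon where CDS
#' coordinate `frame_anchor` (0-based) begins. For amplicons lying entirely
#' within the CDS, `cds_offset = 0` and `frame_anchor` is the CDS start of
#' the amplicon.
#'
#' @param seq Amplicon nucleotide sequence (reference).
#' @param cut_pos_amplicon 0-based cut position within the amplicon.
#' @param cds_offset 0-based amplicon position where the CDS anchor lies.
#' @param frame_anchor 0-based CDS coordinate at `cds_offset`.
#' @return An object of class `amplicon`.
#' @export
amplicon <- function(seq, cut_pos_amplicon, cds_offset = 0L,
                     frame_anchor = 0L) {
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGT]+$", seq)) stop("amplicon must be A/C/G/T",
                                     call. = FALSE)
  if (cut_pos_amplicon < 0L || cut_pos_amplicon > nchar(seq))
    stop("cut position outside the amplicon", call. = FALSE)
  structure(list(seq = seq, cut_pos_amplicon = as.integer(cut_pos_amplicon),
                 cds_offset = as.integer(cds_offset),
                 frame_anchor = as.integer(frame_anchor)),
            class = "amplicon")
}

#' Globally align one read to the amplicon reference
#'
#' Needleman-Wunsch with match +2, mismatch -4, gap open -12, gap extend
#' -1, followed by left-normalisation of gap placement (each gap run is
#' shifted left through repeat context while the alignment score is
#' unchanged). Reads scoring below `0.4 * 2 * nchar(read)` are rejected as
#' unalignable.
#'
#' @param amplicon An [amplicon()].
#' @param read Read sequence (character).
#' @return List with `ref_aln`, `read_aln`, `score`, `aligned` (logical).
#' @export
align_read <- function(amplicon, read) {
  read <- toupper(as.character(read))
  la <- nchar(amplicon$seq)
  lr <- nchar(read)
  if (lr < 0.5 * la || lr > 1.5 * la)
    return(list(ref_aln = NA_character_, read_aln = NA_character_,
                score = -Inf, aligned = FALSE))
  al <- .nw_align_cpp(amplicon$seq, read)
  if (al$score < 0.4 * 2 * lr)
    return(list(ref_aln = NA_character_, read_aln = NA_character_,
                score = al$score, aligned = FALSE))
  norm <- left_normalize(al$ref_aln, al$read_aln)
  list(ref_aln = norm$ref_aln, read_aln = norm$read_aln, score = al$score,
       aligned = TRUE)
}

# Shift every gap run as far left as score-equivalence allows: a gap in row
# s at columns [a, b] moves one column left when the preceding column is a
# match and the shifted pairing stays a match (repeat context).
left_normalize <- function(ref_aln, read_aln) {
  r <- strsplit(ref_aln, "")[[1L]]
  q <- strsplit(read_aln, "")[[1L]]
  shift_gaps <- function(s, t) {
    # s holds the gaps being shifted; t is the partner row
    repeat {
      moved <- FALSE
      i <- 2L
      n <- length(s)
      while (i <= n) {
        if (s[i] == "-" && s[i - 1L] != "-" && t[i - 1L] != "-") {
          b <- i
          while (b < n && s[b + 1L] == "-") b <- b + 1L
          if (s[i - 1L] == t[i - 1L] && s[i - 1L] == t[b]) {
            s[b] <- s[i - 1L]
            s[i - 1L] <- "-"
            moved <- TRUE
          }
          i <- b + 1L
        } else i <- i + 1L
      }
      if (!moved) break
    }
    s
  }
  q <- shift_gaps(q, r)
  r <- shift_gaps(r, q)
  list(ref_aln = paste(r, collapse = ""),
       read_aln = paste(q, collapse = ""))
}

#' Call the editing outcome near the cut site
#'
#' Scans the alignment for runs of non-matching columns (mismatches and
#' gaps), keeps those overlapping the editing window
#' `[cut - w, cut + w]` (events wholly outside are treated as sequencing
#' noise) and merges the kept events into one descriptor: the reference
#' span from the first to the last event and the read bases aligned across
#' it. More than one disjoint event inside the window sets `compound`.
#'
#' @param alignment Output of [align_read()].
#' @param amplicon The [amplicon()] aligned against.
#' @param window_halfwidth Editing window half-width in nt; default 20.
#' @return `NULL` when nothing overlaps the window (wild-type read),
#'   otherwise a list `descriptor` with `start` (0-based amplicon),
#'   `ref_len`, `alt`, `compound`.
#' @export
call_indel <- function(alignment, amplicon, window_halfwidth = 20L) {
  if (!isTRUE(alignment$aligned))
    stop("read was not aligned; cannot call an indel", call. = FALSE)
  r <- strsplit(alignment$ref_aln, "")[[1L]]
  q <- strsplit(alignment$read_aln, "")[[1L]]
  ncol <- length(r)
  # 0-based ref coordinate at the *start* of each column
  ref_pos <- cumsum(c(0L, utils::head(r != "-", -1L)))
  is_event <- (r == "-") | (q == "-") | (r != q)
  if (!any(is_event)) return(NULL)
  runs <- rle(is_event)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  win_lo <- amplicon$cut_pos_amplicon - window_halfwidth
  win_hi <- amplicon$cut_pos_amplicon + window_halfwidth
  in_win <- logical(length(keep))
  for (k in seq_along(keep)) {
    cols <- starts[keep[k]]:ends[keep[k]]
    ev_lo <- ref_pos[cols[1L]]
    ev_hi <- ref_pos[cols[length(cols)]] +
      as.integer(r[cols[length(cols)]] != "-")
    # event ref interval [ev_lo, ev_hi); insertions have ev_hi == ev_lo
    in_win[k] <- ev_hi >= win_lo && ev_lo <= win_hi
  }
  keep <- keep[in_win]
  if (length(keep) == 0L) return(NULL)
  col_lo <- starts[keep[1L]]
  col_hi <- ends[keep[length(keep)]]
  ref_start <- ref_pos[col_lo]
  ref_end <- ref_pos[col_hi] + as.integer(r[col_hi] != "-")
  alt <- paste(q[col_lo:col_hi][q[col_lo:col_hi] != "-"], collapse = "")
  list(start = as.integer(ref_start),
       ref_len = as.integer(ref_end - ref_start),
       alt = alt, compound = length(keep) > 1L)
}

# Apply a descriptor to a sequence (0-based start).
apply_descriptor <- function(seq, descriptor) {
  paste0(substr(seq, 1L, descriptor$start),
         descriptor$alt,
         substr(seq, descriptor$start + descriptor$ref_len + 1L,
                nchar(seq)))
}

#' Protein-level consequence of an amplicon edit
#'
#' Maps the descriptor into CDS coordinates through the amplicon frame
#' anchor, rebuilds the alternate CDS and compares translations. Emits
#' HGVS-like protein strings: `"A372del"` (single-codon deletion),
#' `"I141_C142delinsEI"` (in-frame replacement), `"K59_E62del"`
#' (multi-codon deletion), `"G237V"` (substitution), `"L235="`
#' (synonymous), `"T238_H239insQ"` (in-frame insertion), `"R234fs"`
#' (frameshift, first affected residue), `"WT"`. Affected spans are
#' left-aligned: the common protein prefix is trimmed maximally first.
#'
#' @param gene_model A [gene_model()].
#' @param amplicon The [amplicon()].
#' @param descriptor Descriptor from [call_indel()], or `NULL` for WT.
#' @return List with `hgvs_p` and `frame_class` (one of `"WT"`,
#'   `"synonymous"`, `"in_frame"`, `"frameshift"`).
#' @export
protein_consequence <- function(gene_model, amplicon, descriptor) {
  if (is.null(descriptor))
    return(list(hgvs_p = "WT", frame_class = "WT"))
  cds <- gene_model$cds_seq
  cds_start <- amplicon$frame_anchor + (descriptor$start - amplicon$cds_offset)
  cds_end <- cds_start + descriptor$ref_len
  if (cds_end <= 0L || cds_start >= nchar(cds))
    return(list(hgvs_p = "noncoding", frame_class = "WT"))
  if (cds_start < 0L || cds_end > nchar(cds))
    stop("edit extends beyond the CDS segment covered by the amplicon",
         call. = FALSE)
  alt_cds <- paste0(substr(cds, 1L, cds_start), descriptor$alt,
                    substr(cds, cds_end + 1L, nchar(cds)))
  if (identical(alt_cds, cds))
    return(list(hgvs_p = "WT", frame_class = "WT"))
  net <- nchar(descriptor$alt) - descriptor$ref_len
  ref_prot <- gene_model$protein_seq
  aa <- strsplit(ref_prot, "")[[1L]]
  if (net %% 3L != 0L) {
    # frameshift: first affected residue by protein comparison
    alt_prot <- translate_prefix(alt_cds)
    p <- first_difference(ref_prot, alt_prot)
    pos <- min(p, gene_model$n_residues)
    return(list(hgvs_p = paste0(aa[pos], pos, "fs"),
                frame_class = "frameshift"))
  }
  alt_prot_full <- translate_cds(trim_to_codons(alt_cds))
  alt_prot <- sub("\\*.*$", "", alt_prot_full) # stop truncates
  if (identical(alt_prot, ref_prot)) {
    pos <- (first_nt_difference(cds, alt_cds) - 1L) %/% 3L + 1L
    pos <- min(pos, gene_model$n_residues)
    return(list(hgvs_p = paste0(aa[pos], pos, "="),
                frame_class = "synonymous"))
  }
  # trim common prefix (maximally, left alignment), then common suffix
  np <- common_prefix(ref_prot, alt_prot)
  ns <- common_suffix(substring(ref_prot, np + 1L),
                      substring(alt_prot, np + 1L))
  ref_seg <- substr(ref_prot, np + 1L, nchar(ref_prot) - ns)
  alt_seg <- substr(alt_prot, np + 1L, nchar(alt_prot) - ns)
  p1 <- np + 1L
  p2 <- nchar(ref_prot) - ns
  hgvs <-
    if (nchar(ref_seg) == 0L) {
      # pure insertion between p1-1 and p1
      lo <- max(p1 - 1L, 1L)
      paste0(aa[lo], lo, "_", aa[lo + 1L], lo + 1L, "ins", alt_seg)
    } else if (nchar(alt_seg) == 0L) {
      if (p1 == p2) paste0(aa[p1], p1, "del")
      else paste0(aa[p1], p1, "_", aa[p2], p2, "del")
    } else if (nchar(ref_seg) == 1L && nchar(alt_seg) == 1L) {
      paste0(aa[p1], p1, alt_seg)
    } else if (p1 == p2) {
      paste0(aa[p1], p1, "delins", alt_seg)
    } else {
      paste0(aa[p1], p1, "_", aa[p2], p2, "delins", alt_seg)
    }
  list(hgvs_p = hgvs, frame_class = "in_frame")
}

trim_to_codons <- function(nt) substr(nt, 1L, (nchar(nt) %/% 3L) * 3L)

translate_prefix <- function(nt) {
  p <- translate_cds(trim_to_codons(nt))
  sub("\\*.*$", "", p)
}

first_difference <- function(a, b) {
  n <- common_prefix(a, b)
  n + 1L
}

common_prefix <- function(a, b) {
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  n <- min(length(av), length(bv))
  if (n == 0L) return(0L)
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

common_suffix <- function(a, b) {
  av <- rev(utf8ToInt(a)); bv <- rev(utf8ToInt(b))
  n <- min(length(av), length(bv))
  if (n == 0L) return(0L)
  d <- which(av[seq_len(n)] != bv[seq_len(n)])
  if (length(d) == 0L) n else d[1L] - 1L
}

first_nt_difference <- function(a, b) {
  n <- common_prefix(a, b)
  if (n >= min(nchar(a), nchar(b))) n else n + 1L
}

#' Reconstruct the protein implied by an HGVS-like consequence string
#'
#' Applies a `del` / `delins` / `ins` / substitution / `=` / `WT` string to
#' the reference protein. Used as a self-consistency check: the result must
#' equal the translation of the alternate CDS the edit produces.
#'
#' @param ref_protein Reference protein string.
#' @param hgvs_p Consequence string as produced by
#'   [protein_consequence()] (frameshifts are not reconstructible).
#' @return The implied protein string.
#' @export
apply_protein_hgvs <- function(ref_protein, hgvs_p) {
  if (hgvs_p %in% c("WT", "noncoding") || grepl("=$", hgvs_p))
    return(ref_protein)
  if (grepl("fs$", hgvs_p))
    stop("frameshift consequences are not reconstructible", call. = FALSE)
  m <- regmatches(hgvs_p,
                  regexec("^([A-Z])(\\d+)(?:_([A-Z])(\\d+))?(.*)$", hgvs_p))[[1L]]
  p1 <- as.integer(m[3L])
  p2 <- if (m[5L] == "") p1 else as.integer(m[5L])
  tail <- m[6L]
  aa <- strsplit(ref_protein, "")[[1L]]
  stopifnot(aa[p1] == m[2L])
  if (tail == "del") {
    paste(c(utils::head(aa, p1 - 1L),
            if (p2 < length(aa)) aa[(p2 + 1L):length(aa)]),
          collapse = "")
  } else if (startsWith(tail, "delins")) {
    ins <- substring(tail, nchar("delins") + 1L)
    paste(c(utils::head(aa, p1 - 1L), strsplit(ins, "")[[1L]],
            if (p2 < length(aa)) aa[(p2 + 1L):length(aa)]), collapse = "")
  } else if (startsWith(tail, "ins")) {
    ins <- substring(tail, 4L)
    paste(c(utils::head(aa, p1), strsplit(ins, "")[[1L]],
            if (p1 < length(aa)) aa[(p1 + 1L):length(aa)]), collapse = "")
  } else if (nchar(tail) == 1L) { # substitution (possibly to *)
    aa[p1] <- tail
    sub("\\*.*$", "", paste(aa, collapse = ""))
  } else stop("unrecognised consequence string: ", hgvs_p, call. = FALSE)
}

#' Build a per-allele outcome table across timepoints
#'
#' Aligns every read of every timepoint, calls the editing outcome, keys
#' alleles by protein consequence, and reports per-timepoint abundance as
#' reads per million aligned reads plus log2 fold change versus the
#' reference day: `lfc_d = log2(RPM_d + 1) - log2(RPM_ref + 1)`.
#'
#' @param reads_by_day Named list (names = day numbers) of read sets: each
#'   a character vector of sequences or a FASTQ path.
#' @param amplicon An [amplicon()].
#' @param gene_model A [gene_model()].
#' @param ref_day Reference day (default 1); must be present.
#' @param window_halfwidth Editing window half-width passed to
#'   [call_indel()].
#' @param min_reads Minimum total reads (across days) for an allele to be
#'   reported; default 1.
#' @return An `allele_table` data.frame with `consequence`, `frame_class`,
#'   `compound`, `rpm_d<day>` and `lfc_d<day>` columns, sorted by
#'   reference-day abundance.
#' @export
allele_table <- function(reads_by_day, amplicon, gene_model, ref_day = 1L,
                         window_halfwidth = 20L, min_reads = 1L) {
  days <- as.integer(names(reads_by_day))
  if (anyNA(days)) stop("reads_by_day must be named by day numbers",
                        call. = FALSE)
  if (!(ref_day %in% days))
    stop("reference day ", ref_day, " absent from reads_by_day",
         call. = FALSE)
  tallies <- list()
  aligned_per_day <- integer(length(days))
  names(aligned_per_day) <- as.character(days)
  classes <- character(0)
  compound <- logical(0)
  for (d in as.character(days)) {
    reads <- reads_by_day[[d]]
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
      reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                         format = "fastq"))
    reads <- as.character(reads)
    keys <- character(length(reads))
    ok <- logical(length(reads))
    for (i in seq_along(reads)) {
      al <- align_read(amplicon, reads[i])
      if (!al$aligned) next
      desc <- call_indel(al, amplicon, window_halfwidth)
      cons <- protein_consequence(gene_model, amplicon, desc)
      keys[i] <- cons$hgvs_p
      ok[i] <- TRUE
      if (!(cons$hgvs_p %in% names(classes))) {
        classes[cons$hgvs_p] <- cons$frame_class
        compound[cons$hgvs_p] <- !is.null(desc) && isTRUE(desc$compound)
      }
    }
    aligned_per_day[d] <- sum(ok)
    tallies[[d]] <- table(keys[ok])
  }
  alleles <- unique(unlist(lapply(tallies, names)))
  counts <- sapply(as.character(days), function(d) {
    v <- as.integer(tallies[[d]][alleles])
    v[is.na(v)] <- 0L
    v
  })
  counts <- matrix(counts, nrow = length(alleles),
                   dimnames = list(alleles, as.character(days)))
  keep <- rowSums(counts) >= min_reads
  counts <- counts[keep, , drop = FALSE]
  alleles <- alleles[keep]
  rpm_mat <- sweep(counts, 2L, pmax(aligned_per_day, 1L), "/") * 1e6
  lfc_mat <- log2(rpm_mat + 1) - log2(rpm_mat[, as.character(ref_day)] + 1)
  out <- data.frame(consequence = alleles,
                    frame_class = unname(classes[alleles]),
                    compound = unname(compound[alleles]),
                    stringsAsFactors = FALSE)
  colnames(rpm_mat) <- paste0("rpm_d", days)
  colnames(lfc_mat) <- paste0("lfc_d", days)
  out <- cbind(out, as.data.frame(rpm_mat), as.data.frame(lfc_mat))
  out <- out[order(-out[[paste0("rpm_d", ref_day)]]), ]
  rownames(out) <- NULL
  attr(out, "ref_day") <- ref_day
  attr(out, "aligned_per_day") <- aligned_per_day
  class(out) <- c("allele_table", "data.frame")
  out
}

#' Compare depletion of frameshift versus in-frame alleles
#'
#' Rank-sum comparison (see [rank_sum_compare()]) of `lfc_d<day>` between
#' alleles classified `frameshift` and `in_frame`. At a functional region
#' both classes are expected to deplete similarly, so a non-significant
#' result is the interesting outcome.
#'
#' @param allele_table An [allele_table()].
#' @param day Day whose LFC values are compared; defaults to the last day.
#' @return List with `U`, `p`, `median_frameshift`, `median_in_frame`,
#'   `n_frameshift`, `n_in_frame`.
#' @export
frame_group_compare <- function(allele_table, day = NULL) {
  lfc_cols <- grep("^lfc_d", names(allele_table), value = TRUE)
  if (is.null(day)) {
    day <- max(as.integer(sub("^lfc_d", "", lfc_cols)))
  }
  col <- paste0("lfc_d", day)
  if (!(col %in% names(allele_table)))
    stop("no LFC column for day ", day, call. = FALSE)
  fs <- allele_table[[col]][allele_table$frame_class == "frameshift"]
  inf_ <- allele_table[[col]][allele_table$frame_class == "in_frame"]
  if (length(fs) < 3L || length(inf_) < 3L)
    stop("need at least 3 alleles in each frame class (frameshift: ",
         length(fs), ", in_frame: ", length(inf_), ")", call. = FALSE)
  res <- rank_sum_compare(fs, inf_)
  list(U = res$U, p = res$p, median_frameshift = res$median_a,
       median_in_frame = res$median_b, n_frameshift = length(fs),
       n_in_frame = length(inf_), day = day)
}
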