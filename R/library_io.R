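#' Locate a protospacer on the coding sequence and place the Cas9 cut
#'
#' Searches for an exact match of the 20-nt protospacer on the coding strand
#' and for its reverse complement (a guide reading off the template strand).
#' The blunt SpCas9 cut is placed between protospacer positions 17 and 18,
#' i.e. 3 nt 5' of the NGG PAM. `cut_pos` is reported as the number of CDS
#' nucleotides 5' of the cut (0-based CDS coordinate of the cut):
#' for a plus-strand guide starting at 0-based `s` this is `s + 17`; for a
#' minus-strand guide whose 20-mer occupies `[s, s + 20)` on the coding
#' strand it is `s + 3`.
#'
#' @param gene_model A [gene_model()].
#' @param protospacer 20-nt guide sequence (5'→3' as synthesised).
#' @return A list with `strand` (`"+"` or `"-"`) and `cut_pos` (integer).
#' @seealso [assign_residues()] for the codons flanking the cut.
#' @export
map_protospacer <- function(gene_model, protospacer) {
  protospacer <- toupper(as.character(protospacer))
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 nt", call. = FALSE)
  if (!grepl("^[ACGT]+$", protospacer))
    stop("protospacer contains non-ACGT characters: ", protospacer,
         call. = FALSE)
  cds <- gene_model$cds_seq
  fwd <- substr_positions(cds, protospacer)
  rev <- substr_positions(cds, revcomp(protospacer))
  n_hits <- length(fwd) + length(rev)
  if (n_hits == 0L)
    stop("protospacer not found in CDS (unmapped guide): ", protospacer,
         call. = FALSE)
  if (n_hits > 1L)
    stop("protospacer maps to ", n_hits,
         " CDS locations (ambiguous guide): ", protospacer, call. = FALSE)
  if (length(fwd) == 1L) {
    list(strand = "+", cut_pos = fwd - 1L + 17L)
  } else {
    list(strand = "-", cut_pos = rev - 1L + 3L)
  }
}

# All 1-based start positions of exact occurrences of `pattern` in `x`.
substr_positions <- function(x, pattern) {
  m <- gregexpr(pattern, x, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Codons flanking a Cas9 cut site
#'
#' Returns the 1-based indices of the residues whose codons contain the two
#' nucleotides flanking the blunt cut: positions `cut_pos - 1` and `cut_pos`
#' in 0-based CDS coordinates, i.e. codons `floor((cut_pos - 1) / 3) + 1`
#' and `floor(cut_pos / 3) + 1`, clipped to `[1, n_residues]` (cuts in the
#' stop codon contribute nothing), deduplicated and sorted. A cut on a codon
#' boundary therefore names two consecutive residues ("sgX/Y"-style), a cut
#' inside a codon names one.
#'
#' @param gene_model A [gene_model()].
#' @param cut_pos 0-based CDS coordinate of the cut, in `[0, nchar(cds)]`.
#' @return Integer vector of length 0, 1 or 2.
#' @export
assign_residues <- function(gene_model, cut_pos) {
  cut_pos <- as.integer(cut_pos)
  if (cut_pos < 0L || cut_pos > nchar(gene_model$cds_seq))
    stop("cut_pos outside the CDS: ", cut_pos, call. = FALSE)
  cand <- c((cut_pos - 1L) %/% 3L + 1L, cut_pos %/% 3L + 1L)
  res <- sort(unique(cand[cand >= 1L & cand <= gene_model$n_residues]))
  if (length(res) == 0L)
    warning("cut at CDS position ", cut_pos,
            " touches no coding residue (stop-codon region)")
  res
}

# "sgQ58/K59"-style label for a CDS guide.
sgrna_label <- function(gene_model, residues) {
  aa <- strsplit(gene_model$protein_seq, "")[[1L]]
  paste0("sg", paste0(aa[residues], residues, collapse = "/"))
}

#' Parse an sgRNA library table and resolve guide placement
#'
#' Reads a delimited text file with columns `sgrna_id`, `protospacer` and
#' `category` (one of `CDS`, `NEG`, `POS`, `NT`; an optional `label` column
#' is carried through). Every `CDS` guide is located on the CDS via
#' [map_protospacer()] and its targeted residues resolved via
#' [assign_residues()]; control guides pass through with `NA` placement.
#'
#' @param path Path to a TSV/CSV file (delimiter sniffed from the header).
#' @param gene_model A [gene_model()].
#' @return An object of class `sg_library`: a list with `sgrnas` (data.frame
#'   with columns `sgrna_id`, `protospacer`, `category`, `strand`, `cut_pos`,
#'   `residues` (list column), `label`) and `gene` (the gene model).
#' @export
parse_library <- function(path, gene_model) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  required <- c("sgrna_id", "protospacer", "category")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("library file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!("label" %in% names(df))) df$label <- NA_character_
  build_library(df, gene_model)
}

# Shared constructor/validator used by parse_library() and design_library().
build_library <- function(df, gene_model) {
  df$protospacer <- toupper(df$protospacer)
  bad <- !grepl("^[ACGT]{20}$", df$protospacer)
  if (any(bad))
    stop("invalid protospacer (must be 20 nt of A/C/G/T) for: ",
         paste(df$sgrna_id[bad], collapse = ", "), call. = FALSE)
  dup_id <- df$sgrna_id[duplicated(df$sgrna_id)]
  if (length(dup_id) > 0L)
    stop("duplicate sgrna_id: ", paste(unique(dup_id), collapse = ", "),
         call. = FALSE)
  dup <- duplicated(df$protospacer) | duplicated(df$protospacer, fromLast = TRUE)
  if (any(dup))
    stop("duplicate protospacer shared by: ",
         paste(df$sgrna_id[dup], collapse = ", "), call. = FALSE)
  if (!all(df$category %in% c("CDS", "NEG", "POS", "NT")))
    stop("category must be one of CDS, NEG, POS, NT", call. = FALSE)

  df$strand <- NA_character_
  df$cut_pos <- NA_integer_
  df$residues <- vector("list", nrow(df))
  for (i in which(df$category == "CDS")) {
    hit <- map_protospacer(gene_model, df$protospacer[i])
    df$strand[i] <- hit$strand
    df$cut_pos[i] <- hit$cut_pos
    res <- assign_residues(gene_model, hit$cut_pos)
    df$residues[[i]] <- res
    if (is.na(df$label[i]) && length(res) > 0L)
      df$label[i] <- sgrna_label(gene_model, res)
  }
  for (i in which(df$category != "CDS")) df$residues[[i]] <- integer(0)
  rownames(df) <- NULL
  lib <- structure(list(sgrnas = df, gene = gene_model), class = "sg_library")
  lib
}

#' @export
print.sg_library <- function(x, ...) {
  tab <- table(x$sgrnas$category)
  cat(sprintf("sg_library on %s: %d sgRNAs (%s)\n", x$gene$gene_id,
              nrow(x$sgrnas),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  cat(sprintf("residue coverage: %.1f%%\n",
              100 * residue_coverage(x)))
  invisible(x)
}

#' Fraction of protein residues covered by at least one CDS guide
#'
#' @param library An `sg_library`.
#' @param gene_model Gene model; defaults to the one stored in the library.
#' @return Fraction in `[0, 1]` of positions `1..n_residues` assigned to at
#'   least one CDS sgRNA.
#' @export
residue_coverage <- function(library, gene_model = library$gene) {
  res <- unlist(library$sgrnas$residues[library$sgrnas$category == "CDS"])
  length(unique(res[res >= 1 & res <= gene_model$n_residues])) /
    gene_model$n_residues
}

#' Write an sgRNA library table
#'
#' Inverse of [parse_library()] (placement columns are recomputed on read).
#'
#' @param library An `sg_library`.
#' @param path Output TSV path.
#' @export
write_library <- function(library, path) {
  df <- library$sgrnas[, c("sgrna_id", "protospacer", "category", "label")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
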