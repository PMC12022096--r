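#' Construct a gene model from a coding sequence
#'
#' A gene model anchors every downstream residue-level computation: the CDS
#' (coding strand, 5'→3', including the stop codon) and its translation.
#' If `protein_seq` is omitted it is derived by translating the CDS with the
#' standard genetic code.
#'
#' @param gene_id Gene identifier, e.g. `"MAP2K1"`.
#' @param cds_seq Nucleotide string (A/C/G/T only) whose length is a multiple
#'   of 3, ending in a stop codon, with no internal stop.
#' @param protein_seq Optional amino-acid string (no stop character). When
#'   supplied it is checked against the translation of `cds_seq`.
#' @return An object of class `gene_model`: a list with `gene_id`, `cds_seq`,
#'   `protein_seq` and `n_residues`.
#' @examples
#' gm <- gene_model("toy", "ATGGCTGAAAAACGTTGGTAA")
#' gm$n_residues  # 6
#' @export
gene_model <- function(gene_id, cds_seq, protein_seq = NULL) {
  cds_seq <- toupper(as.character(cds_seq))
  if (!grepl("^[ACGT]+$", cds_seq))
    stop("cds_seq must contain only A/C/G/T", call. = FALSE)
  if (nchar(cds_seq) %% 3L != 0L)
    stop("cds_seq length must be a multiple of 3", call. = FALSE)
  aa_full <- translate_cds(cds_seq)
  n_aa <- nchar(aa_full)
  if (substr(aa_full, n_aa, n_aa) != "*")
    stop("cds_seq must end in a stop codon", call. = FALSE)
  aa <- substr(aa_full, 1L, n_aa - 1L)
  if (grepl("\\*", aa))
    stop("cds_seq contains an internal stop codon", call. = FALSE)
  if (!is.null(protein_seq)) {
    protein_seq <- toupper(as.character(protein_seq))
    if (!identical(protein_seq, aa))
      stop("protein_seq does not match the translation of cds_seq",
           call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, cds_seq = cds_seq, protein_seq = aa,
         n_residues = nchar(aa)),
    class = "gene_model"
  )
}

#' Read a gene model from FASTA
#'
#' Accepts either a single-record FASTA holding the CDS (translated
#' internally) or a two-record FASTA holding the CDS and the protein, in
#' which case the record whose alphabet is nucleotide-only is taken as the
#' CDS and the other as the protein.
#'
#' @param path Path to a FASTA file.
#' @param gene_id Optional identifier; defaults to the CDS record name.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, gene_id = NULL) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) < 1L || length(recs) > 2L)
    stop("gene model FASTA must contain 1 (CDS) or 2 (CDS + protein) records",
         call. = FALSE)
  seqs <- toupper(as.character(recs))
  is_nt <- grepl("^[ACGTN]+$", seqs)
  if (!any(is_nt))
    stop("no nucleotide (CDS) record found in ", path, call. = FALSE)
  cds_i <- which(is_nt)[1L]
  prot <- if (length(recs) == 2L) seqs[-cds_i] else NULL
  if (is.null(gene_id)) gene_id <- sub("\\s.*$", "", names(recs)[cds_i])
  gene_model(gene_id, seqs[cds_i], prot)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %d residues, CDS %d nt (incl. stop)\n",
              x$gene_id, x$n_residues, nchar(x$cds_seq)))
  invisible(x)
}

# Translate a coding-strand nucleotide string with the standard code.
# Returns an amino-acid string; stop codons are '*'.
translate_cds <- function(nt) {
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     no.init.codon = TRUE))
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}
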