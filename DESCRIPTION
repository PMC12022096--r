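Package: tilescreen
Title: Analysis of CRISPR Tiling Screens with Paired-Line Contrasts and
    Residue-Level Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for single-gene CRISPR tiling screens. Counts sgRNA
    cassette reads from FASTQ into a sample-annotated matrix, computes
    reads-per-million normalised log2 fold changes for arbitrary contrasts
    (including a paired Cas9-negative parental-line design), calibrates
    depletion and enrichment calls against negative-control guides
    (percentile thresholds, category depletion rates, ROC/AUC), maps each
    protospacer to the codons flanking its predicted Cas9 cut site, ranks
    guides into quantile bins, projects scores onto protein residues, calls
    depleted or enriched regions and exports them as PDB B-factor
    annotations. A single-locus amplicon module aligns reads, calls indels
    near the cut, derives HGVS-like protein consequences with frame
    classification and tracks per-allele depletion over time. A synthetic
    screen generator with negative-binomial count noise provides known-truth
    data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    yaml,
    optparse
Config/testthat/edition: 3
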