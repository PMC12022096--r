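gm <- simulate_gene(120, seed = 61)
cut <- 3 * 60  # boundary between codons 60 and 61
amp_fx <- function(flank = 60) {
  start <- cut - flank
  amplicon(substr(gm$cds_seq, start + 1, cut + flank),
           cut_pos_amplicon = flank, cds_offset = 0, frame_anchor = start)
}

# translation of the alternate CDS implied by a descriptor (independent of
# the naming code path)
translate_alt <- function(gm, amp, d) {
  cds_start <- amp$frame_anchor + d$start - amp$cds_offset
  alt_cds <- paste0(substr(gm$cds_seq, 1, cds_start), d$alt,
                    substr(gm$cds_seq, cds_start + d$ref_len + 1,
                           nchar(gm$cds_seq)))
  alt_cds <- substr(alt_cds, 1, (nchar(alt_cds) %/% 3) * 3)
  p <- as.character(Biostrings::translate(Biostrings::DNAString(alt_cds),
                                          no.init.codon = TRUE))
  sub("\\*.*$", "", p)
}

synonymous_codon <- function(codon) {
  tr <- function(x) as.character(
    Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE))
  target <- tr(codon)
  for (b in c("A", "C", "G", "T")) {
    alt <- paste0(substr(codon, 1, 2), b)
    if (alt != codon && tr(alt) == target) return(alt)
  }
  NA_character_
}

apply_descr <- function(seq, d)
  paste0(substr(seq, 1, d$start), d$alt,
         substr(seq, d$start + d$ref_len + 1, nchar(seq)))

test_that("a perfect read aligns gap-free with full score", {
  amp <- amp_fx()
  al <- align_read(amp, amp$seq)
  expect_true(al$aligned)
  expect_equal(al$ref_aln, amp$seq)
  expect_equal(al$read_aln, amp$seq)
  expect_equal(al$score, 2 * nchar(amp$seq))
})

test_that("a 3-nt deletion yields one leftmost-placed gap", {
  amp <- amp_fx()
  # delete a codon right of the cut
  read <- paste0(substr(amp$seq, 1, 60), substr(amp$seq, 64, nchar(amp$seq)))
  al <- align_read(amp, read)
  expect_true(al$aligned)
  gaps <- gregexpr("-+", al$read_aln)[[1]]
  expect_equal(length(gaps), 1)
  expect_equal(attr(gaps, "match.length"), 3)
  # leftmost among equivalent placements: oracle by direct trimming
  desc <- call_indel(al, amp)
  oracle <- canonical_descriptor(amp$seq, read)
  expect_equal(desc$start, oracle$start)
  expect_equal(desc$ref_len, oracle$ref_len)
  expect_equal(desc$alt, oracle$alt)
})

test_that("reads far from the reference are rejected as unalignable", {
  amp <- amp_fx()
  set.seed(62)
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(amp$seq), TRUE),
                collapse = "")
  al <- align_read(amp, junk)
  expect_false(al$aligned)
  expect_false(align_read(amp, substr(amp$seq, 1, 20))$aligned)
  expect_error(call_indel(al, amp), "not aligned")
})

test_that("mismatches outside the editing window are sequencing noise", {
  amp <- amp_fx()
  ch <- strsplit(amp$seq, "")[[1]]
  far <- 10  # 50 nt from the cut, outside the +/-20 window
  ch[far] <- setdiff(c("A", "C", "G", "T"), ch[far])[1]
  al <- align_read(amp, paste(ch, collapse = ""))
  expect_null(call_indel(al, amp))
  # the same event inside the window is called as a substitution
  ch2 <- strsplit(amp$seq, "")[[1]]
  ch2[61] <- setdiff(c("A", "C", "G", "T"), ch2[61])[1]
  desc <- call_indel(align_read(amp, paste(ch2, collapse = "")), amp)
  expect_equal(desc$ref_len, 1)
  expect_equal(nchar(desc$alt), 1)
})

test_that("disjoint events in the window merge into a compound descriptor", {
  amp <- amp_fx()
  # 2-nt deletion left of the cut plus a mismatch right of it
  ch <- strsplit(amp$seq, "")[[1]]
  ch[70] <- setdiff(c("A", "C", "G", "T"), ch[70])[1]
  read <- paste(c(ch[1:54], ch[57:length(ch)]), collapse = "")
  desc <- call_indel(align_read(amp, read), amp)
  expect_true(desc$compound)
  expect_equal(desc$start + desc$ref_len, 70)
})

test_that("simulated indel spectra are recovered exactly after left-normalisation", {
  spec <- data.frame(
    start = c(0, 59, 60, 57, 59),
    ref_len = c(0, 3, 1, 6, 2),
    alt = c("", "", "", "", "TT"),
    frac_day1 = c(0.3, 0.2, 0.2, 0.15, 0.15),
    mult_per_day = 1)
  sim <- simulate_amplicon_reads(gm, cut, spec, days = 1,
                                 reads_per_day = 200, flank = 60, seed = 63)
  amp <- sim$amplicon
  allele_seqs <- vapply(seq_len(nrow(spec)), function(i) {
    if (spec$ref_len[i] == 0 && spec$alt[i] == "") amp$seq
    else paste0(substr(amp$seq, 1, spec$start[i]), spec$alt[i],
                substr(amp$seq, spec$start[i] + spec$ref_len[i] + 1,
                       nchar(amp$seq)))
  }, character(1))
  for (i in seq_len(nrow(spec))) {
    al <- align_read(amp, allele_seqs[i])
    desc <- call_indel(al, amp)
    oracle <- canonical_descriptor(amp$seq, allele_seqs[i])
    if (oracle$ref_len == 0 && nchar(oracle$alt) == 0) {
      expect_null(desc)
    } else {
      expect_equal(desc$start, oracle$start)
      expect_equal(desc$ref_len, oracle$ref_len)
      expect_equal(desc$alt, oracle$alt)
    }
  }
})

test_that("protein consequences cover del, delins, substitution, synonymous, fs", {
  amp <- amp_fx()
  aa <- strsplit(gm$protein_seq, "")[[1]]
  # whole-codon deletion: codon 61 occupies amplicon nt 60..62 (0-based)
  d <- list(start = 60L, ref_len = 3L, alt = "", compound = FALSE)
  cons <- protein_consequence(gm, amp, d)
  expect_equal(cons$frame_class, "in_frame")
  expect_match(cons$hgvs_p, "^[A-Z]\\d+del$")
  # the deleted residue index is recoverable and consistent
  expect_equal(apply_protein_hgvs(gm$protein_seq, cons$hgvs_p),
               translate_alt(gm, amp, d))

  # two-codon replacement by EI (delins or substitution after trimming)
  d2 <- list(start = 60L, ref_len = 6L, alt = "GAAATC", compound = FALSE)
  cons2 <- protein_consequence(gm, amp, d2)
  expect_equal(cons2$frame_class, "in_frame")
  expect_equal(apply_protein_hgvs(gm$protein_seq, cons2$hgvs_p),
               translate_alt(gm, amp, d2))

  # 1-nt deletion is always a frameshift
  d3 <- list(start = 61L, ref_len = 1L, alt = "", compound = FALSE)
  cons3 <- protein_consequence(gm, amp, d3)
  expect_equal(cons3$frame_class, "frameshift")
  expect_match(cons3$hgvs_p, "fs$")

  # synonymous wobble change at codon 61
  codon <- substr(gm$cds_seq, 181, 183)
  syn <- synonymous_codon(codon)
  skip_if(is.na(syn), "codon has no synonymous alternative")
  d4 <- list(start = 60L, ref_len = 3L, alt = syn, compound = FALSE)
  cons4 <- protein_consequence(gm, amp, d4)
  expect_equal(cons4$frame_class, "synonymous")
  expect_equal(cons4$hgvs_p, paste0(aa[61], "61="))

  # in-frame insertion
  d5 <- list(start = 60L, ref_len = 0L, alt = "GAAGAA", compound = FALSE)
  cons5 <- protein_consequence(gm, amp, d5)
  expect_equal(cons5$frame_class, "in_frame")
  expect_equal(apply_protein_hgvs(gm$protein_seq, cons5$hgvs_p),
               translate_alt(gm, amp, d5))
})



test_that("re-translation self-consistency holds for random in-frame edits", {
  amp <- amp_fx()
  set.seed(64)
  for (k in 1:40) {
    len <- sample(c(0L, 3L, 6L, 9L), 1)
    ins <- sample(c(0L, 3L, 6L), 1)
    if (len == 0 && ins == 0) next
    start <- as.integer(sample(40:75, 1))
    alt <- paste(sample(c("A", "C", "G", "T"), ins, TRUE), collapse = "")
    d <- list(start = start, ref_len = len, alt = alt, compound = FALSE)
    cons <- protein_consequence(gm, amp, d)
    if (cons$frame_class %in% c("in_frame", "synonymous")) {
      expect_equal(apply_protein_hgvs(gm$protein_seq, cons$hgvs_p),
                   translate_alt(gm, amp, d),
                   info = paste("descriptor", start, len, alt))
    }
  }
})

test_that("left-normalised descriptor equivalents give the same consequence", {
  amp <- amp_fx()
  # deletion inside a repeat: build a descriptor and its right-shifted twin
  ch <- strsplit(amp$seq, "")[[1]]
  rep_pos <- which(ch[-length(ch)] == ch[-1])[1]  # a dinucleotide repeat
  skip_if(is.na(rep_pos), "no repeat context in fixture")
  d_left <- list(start = rep_pos - 1L, ref_len = 1L, alt = "",
                 compound = FALSE)
  d_right <- list(start = rep_pos, ref_len = 1L, alt = "", compound = FALSE)
  same_seq <- identical(apply_descr(amp$seq, d_left),
                        apply_descr(amp$seq, d_right))
  skip_if(!same_seq)
  expect_equal(protein_consequence(gm, amp, d_left)$hgvs_p,
               protein_consequence(gm, amp, d_right)$hgvs_p)
})


test_that("allele tables track RPM and LFC across timepoints", {
  spec <- data.frame(
    start = c(0, 59, 60),
    ref_len = c(0, 3, 1),
    alt = c("", "", ""),
    frac_day1 = c(0.5, 0.25, 0.25),
    mult_per_day = c(1, 1, 0.5))
  sim <- simulate_amplicon_reads(gm, cut, spec, days = c(1, 9),
                                 reads_per_day = 300, flank = 60, seed = 65)
  at <- allele_table(sim$reads, sim$amplicon, gm, ref_day = 1)
  # RPM conservation over aligned reads
  expect_equal(sum(at$rpm_d1), 1e6)
  expect_equal(sum(at$rpm_d9), 1e6)
  expect_true(all(at$lfc_d1 == 0))
  # the stable allele's day-9 LFC is near 0 only if composition is stable;
  # here the depleting allele shifts composition, so just check ordering
  dep <- at$consequence[at$frame_class == "frameshift"]
  expect_lt(at$lfc_d9[at$consequence == dep],
            max(at$lfc_d9[at$consequence != dep]))
  expect_error(allele_table(sim$reads, sim$amplicon, gm, ref_day = 3),
               "absent")
})

test_that("allele LFC has the closed form under planted abundances", {
  # allele at RPM 15 on day 1 and 0 on day 9: log2(1/16) = -4
  rpm1 <- c(a = 15, b = 999985)
  rpm9 <- c(a = 0, b = 1e6)
  lfc <- log2(rpm9 + 1) - log2(rpm1 + 1)
  expect_equal(unname(lfc["a"]), -4)
})

test_that("frame-group comparison is symmetric and needs both classes", {
  at <- data.frame(
    consequence = sprintf("c%d", 1:8),
    frame_class = rep(c("frameshift", "in_frame"), each = 4),
    lfc_d9 = c(-3, -2.5, -2.8, -3.2, -0.1, 0, 0.1, -0.2))
  res <- frame_group_compare(at, day = 9)
  expect_lt(res$p, 0.05)
  expect_equal(res$n_frameshift, 4)
  at2 <- at[at$frame_class == "frameshift", ]
  expect_error(frame_group_compare(at2, day = 9), "at least 3")
  # identical distributions: p near 1
  at$lfc_d9 <- rep(c(-1, -2, -3, -4), 2)
  expect_gt(frame_group_compare(at, day = 9)$p, 0.9)
})
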