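# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

toy_gene <- function(seed = 1, n = 40) simulate_gene(n, seed = seed)

# Reads embedding library protospacers at random offsets in random context.
make_reads <- function(library, n_reads, seed, read_len = 60L,
                       frac_junk = 0.05) {
  set.seed(seed)
  protos <- library$sgrnas$protospacer
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(k) paste(sample(bases, k, replace = TRUE),
                                collapse = "")
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (stats::runif(1) < frac_junk) {
      reads[i] <- rand_seq(read_len)
    } else {
      g <- sample(protos, 1L)
      if (stats::runif(1) < 0.5)
        g <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(g)))
      off <- sample.int(read_len - 20L, 1L)
      reads[i] <- paste0(rand_seq(off - 1L), g,
                         rand_seq(read_len - 19L - off))
    }
  }
  reads
}

# Brute-force O(reads x guides) substring-scan counting oracle.
naive_count_oracle <- function(reads, library) {
  protos <- library$sgrnas$protospacer
  rcs <- vapply(protos, function(p)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(p))),
    character(1))
  hit <- sapply(seq_along(protos), function(k)
    grepl(protos[k], reads, fixed = TRUE) |
      grepl(rcs[k], reads, fixed = TRUE))
  hit <- matrix(hit, nrow = length(reads))
  n_hits <- rowSums(hit)
  counts <- integer(length(protos))
  names(counts) <- library$sgrnas$sgrna_id
  one <- which(n_hits == 1L)
  for (i in one) counts[which(hit[i, ])] <- counts[which(hit[i, ])] + 1L
  list(counts = counts, unassigned = sum(n_hits != 1L))
}

# Exhaustive pairwise-comparison AUC oracle.
auc_pair_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exact permutation two-sided p for the Mann-Whitney U statistic.
perm_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  u_of <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  mu <- na * length(b) / 2
  us <- apply(idx, 2L, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Equal-size rank partition oracle for binning.
bin_oracle <- function(lfc, ids, n_bins) {
  ord <- order(-lfc, ids)
  n <- length(lfc)
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(n)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  names(bins) <- ids
  bins
}

# Minimal leftmost descriptor turning `ref` into `alt_seq`: maximal common
# suffix first, then maximal common prefix (leftmost placement in repeats).
canonical_descriptor <- function(ref, alt_seq) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt_seq, "")[[1]]
  n <- min(length(r), length(a))
  s <- 0L
  while (s < n && r[length(r) - s] == a[length(a) - s]) s <- s + 1L
  p <- 0L
  while (p < n - s && r[p + 1L] == a[p + 1L]) p <- p + 1L
  list(start = p, ref_len = length(r) - p - s,
       alt = if (length(a) - s >= p + 1L)
     paste(a[(p + 1L):(length(a) - s)], collapse = "") else "")
}

# Hand-rolled fixed-column toy PDB (CA-only) for annotation tests.
write_toy_pdb <- function(path, n_res = 3L, chain = "A") {
  fmt <- paste0("ATOM  %5d  CA  ALA %1s%4d    ",
                "%8.3f%8.3f%8.3f%6.2f%6.2f          %2s")
  lines <- vapply(seq_len(n_res), function(i)
    sprintf(fmt, i, chain, i, i * 1.5, 0, 0, 1, 0, "C"), character(1))
  writeLines(c(lines, "END"), path)
  path
}

# Convenience: run the drop-out pipeline on a simulated screen.
run_dropout_pipeline <- function(sim, library, gene_model,
                                 qualifying_bins = 16:17,
                                 lfc_cutoff = -1) {
  ct <- contrast("PAR/Cas9-D14",
                 numerator = list(cell_line = "CAS9", day = 14,
                                  treatment = "none"),
                 denominator = list(cell_line = "PAR", day = 0,
                                    treatment = "none"))
  tab <- compute_lfc(sim$counts, ct, library)
  ref <- sim$counts$samples$sample_id[
    sim$counts$samples$cell_line == "PAR" & sim$counts$samples$day == 0 &
      sim$counts$samples$replicate == 1][1]
  tab <- filter_low_counts(tab, sim$counts, ref)
  bins <- bin_sgrnas(tab)
  track <- residue_track(tab, bins, gene_model, "depleted")
  regions <- call_regions(track, qualifying_bins, max_gap = 1,
                          lfc_cutoff = lfc_cutoff)
  list(tab = tab, bins = bins, track = track, regions = regions,
       ref_sample = ref)
}
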