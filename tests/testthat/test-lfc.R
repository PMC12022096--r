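make_cm <- function(counts, days, cell_lines, reps,
                    treatments = "none") {
  n <- ncol(counts)
  samples <- do.call(rbind, lapply(seq_len(n), function(j)
    sample_meta(paste0("s", j), cell_lines[j], days[j],
                rep(treatments, length.out = n)[j], reps[j])))
  colnames(counts) <- samples$sample_id
  count_matrix(counts, samples)
}

test_that("rpm implements the per-million formula and conserves columns", {
  cm <- make_cm(cbind(c(1L, 1L), c(500L, 999500L)),
                days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  m <- rpm(cm)
  expect_equal(unname(m[, 1]), c(5e5, 5e5))   # symmetry
  expect_equal(unname(m[1, 2]), 500)           # 500 of 1e6 reads
  expect_true(all(abs(colSums(m) - 1e6) < 1e-6 * 1e6))
})

test_that("zero-depth samples are reported by name", {
  cm <- make_cm(cbind(c(1L, 1L), c(0L, 0L)), days = c(0, 14),
                cell_lines = c("PAR", "CAS9"), reps = c(1, 1))
  expect_error(rpm(cm), "s2")
})

test_that("LFC is zero for identical columns and matches the closed form", {
  counts <- cbind(rep(1000L, 4), rep(1000L, 4))
  rownames(counts) <- paste0("g", 1:4)
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  ct <- contrast("null", list(day = 14), list(day = 0))
  expect_true(all(compute_lfc(cm, ct)$lfc_mean == 0))

  # rpm 3 -> 15 in a single replicate: log2(16/4) = 2
  counts <- rbind(c(3L, 15L), c(999997L, 999985L))
  rownames(counts) <- c("a", "b")
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("CAS9", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, ct)
  expect_equal(tab$lfc_mean[tab$sgrna_id == "a"], 2)
})

test_that("LFC is antisymmetric under contrast reversal", {
  set.seed(31)
  counts <- matrix(rpois(200, 800), ncol = 4)
  rownames(counts) <- paste0("g", 1:50)
  cm <- make_cm(counts, days = c(0, 0, 14, 14),
                cell_lines = c("PAR", "PAR", "CAS9", "CAS9"),
                reps = c(1, 2, 1, 2))
  fwd <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  bwd <- compute_lfc(cm, contrast("b", list(day = 0), list(day = 14)))
  expect_equal(bwd$lfc_mean, -fwd$lfc_mean)
  expect_equal(bwd$lfc_rep1, -fwd$lfc_rep1)
})

test_that("LFC is invariant to a sample depth factor", {
  set.seed(32)
  counts <- matrix(rpois(100, 500), ncol = 2)
  rownames(counts) <- paste0("g", 1:50)
  cm1 <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                 reps = c(1, 1))
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 7L
  cm2 <- make_cm(counts2, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                 reps = c(1, 1))
  ct <- contrast("f", list(day = 14), list(day = 0))
  expect_equal(compute_lfc(cm1, ct)$lfc_mean, compute_lfc(cm2, ct)$lfc_mean)
})

test_that("mismatched replicate indices raise a contrast error", {
  counts <- matrix(1000L, nrow = 3, ncol = 2,
                   dimnames = list(paste0("g", 1:3), NULL))
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 2))
  expect_error(compute_lfc(cm, contrast("f", list(day = 14), list(day = 0))),
               "replicate")
})

test_that("paired parental contrast equals within-line contrast on noiseless data", {
  gm <- simulate_gene(100, seed = 33)
  lib <- design_library(gm, seed = 34)
  sim <- simulate_screen(lib, nb_dispersion = 0, depth = 5e7,
                         initial_sdlog = 0.3, seed = 35)
  par_ct <- contrast("PAR/Cas9-D14",
                     list(cell_line = "CAS9", day = 14),
                     list(cell_line = "PAR", day = 0))
  cas_ct <- contrast("Cas9/Cas9-D14",
                     list(cell_line = "CAS9", day = 14),
                     list(cell_line = "CAS9", day = 0))
  a <- compute_lfc(sim$counts, par_ct)$lfc_mean
  b <- compute_lfc(sim$counts, cas_ct)$lfc_mean
  # shared initial pool: the two contrasts agree up to sampling noise,
  # which is tiny at this depth
  expect_lt(max(abs(a - b)), 0.1)
  expect_lt(abs(mean(a - b)), 0.02)
})

test_that("low-count filter uses a strict below-threshold rule", {
  counts <- cbind(c(299L, 300L, 301L), c(10L, 10L, 10L))
  rownames(counts) <- c("low", "edge", "high")
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  tab <- filter_low_counts(tab, cm, "s1")
  expect_true(tab$filtered[tab$sgrna_id == "low"])
  expect_false(tab$filtered[tab$sgrna_id == "edge"])
  expect_false(tab$filtered[tab$sgrna_id == "high"])
  expect_equal(tab$filter_reason[tab$sgrna_id == "low"], "low_count")
  expect_error(filter_low_counts(tab, cm, "nope"), "reference sample")
})

test_that("planted low-count guides are exactly the filtered set", {
  set.seed(36)
  counts <- matrix(rpois(120, 2000), ncol = 2)
  rownames(counts) <- paste0("g", 1:60)
  low <- sample(60, 7)
  counts[low, 1] <- sample(0:299, 7)
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  tab <- filter_low_counts(tab, cm, "s1")
  expect_setequal(tab$sgrna_id[tab$filtered], paste0("g", low))
})

test_that("activity correction divides by floored activity, preserving sign", {
  counts <- matrix(1000L, nrow = 3, ncol = 2,
                   dimnames = list(c("a", "b", "c"), NULL))
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  tab$lfc_mean <- c(-2, -2, 3)
  scores <- c(a = 1.0, b = 0.5, c = 0.05)
  out <- activity_correct(tab, scores)
  expect_equal(out$corrected_lfc, c(-2, -4, 15))  # 0.05 floored to 0.2
  expect_true(all(sign(out$corrected_lfc) == sign(tab$lfc_mean)))

  # 0-100 scale auto-rescales
  out2 <- activity_correct(tab, c(a = 100, b = 50, c = 5))
  expect_equal(out2$corrected_lfc, out$corrected_lfc)
  expect_error(activity_correct(tab, c(a = -1, b = 1, c = 1)), "positive")
})

test_that("unscored CDS guides warn and keep NA corrected values", {
  counts <- matrix(1000L, nrow = 2, ncol = 2,
                   dimnames = list(c("a", "b"), NULL))
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  tab$category <- c("CDS", "CDS")
  expect_warning(out <- activity_correct(tab, c(a = 0.8)), "lack activity")
  expect_true(is.na(out$corrected_lfc[out$sgrna_id == "b"]))
})

test_that("correction improves essentiality ranking when effects scale with activity", {
  # screen-like mixture: a minority of guides with real effects on top of a
  # large null background, effect = activity x essentiality
  set.seed(37)
  n_eff <- 60; n_null <- 240; n <- n_eff + n_null
  activity <- rbeta(n, 2, 2) * 0.8 + 0.2
  essentiality <- c(runif(n_eff, 0.3, 1), rep(0, n_null))
  true_lfc_val <- -4 * activity * essentiality
  counts <- matrix(0L, nrow = n, ncol = 2,
                   dimnames = list(paste0("g", 1:n), NULL))
  counts[, 1] <- rpois(n, 5000)
  counts[, 2] <- rpois(n, 5000 * 2^true_lfc_val)
  cm <- make_cm(counts, days = c(0, 14), cell_lines = c("PAR", "CAS9"),
                reps = c(1, 1))
  tab <- compute_lfc(cm, contrast("f", list(day = 14), list(day = 0)))
  names(activity) <- tab$sgrna_id
  out <- activity_correct(tab, activity)
  eff <- essentiality > 0
  raw_cor <- cor(-out$lfc_mean[eff], essentiality[eff], method = "spearman")
  cor_cor <- cor(-out$corrected_lfc[eff], essentiality[eff],
                 method = "spearman")
  expect_gt(cor_cor, raw_cor)
})

test_that("LFC tables serialise residues and survive a write", {
  gm <- simulate_gene(90, seed = 1)
  lib <- design_library(gm, n_controls = c(NEG = 4, POS = 3, NT = 2),
                        seed = 38)
  sim <- simulate_screen(lib, seed = 39, depth = 1e5)
  tab <- compute_lfc(sim$counts,
                     contrast("f", list(cell_line = "CAS9", day = 14),
                              list(cell_line = "PAR", day = 0)), lib)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lfc(tab, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(tab))
  expect_true(all(c("sgrna_id", "lfc_mean", "filtered") %in% names(back)))
})
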