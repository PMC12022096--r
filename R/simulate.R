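#' Simulate a single-gene coding sequence
#'
#' Random CDS with an ATG start, no internal stop and a single terminal
#' stop codon; reproducible under a fixed seed. Base composition is
#' GC-biased (default 56% GC, typical of human kinase coding sequences),
#' which sets a realistic density of NGG PAM sites for library design.
#'
#' @param n_residues Protein length (>= 30); default 393, the size of a
#'   typical kinase target.
#' @param seed Optional RNG seed.
#' @param gene_id Identifier for the model.
#' @param gc GC fraction of the simulated CDS; default 0.56.
#' @return A [gene_model()] whose CDS has `3 * (n_residues + 1)` nt.
#' @export
simulate_gene <- function(n_residues = 393L, seed = NULL,
                          gene_id = "simgene", gc = 0.56) {
  if (n_residues < 30L) stop("n_residues must be >= 30", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- all_codons()
  sense <- codons[!(codons %in% c("TAA", "TAG", "TGA"))]
  # codon probabilities from independent base draws, stops excluded
  w <- vapply(strsplit(sense, ""), function(b) prod(p[b]), numeric(1))
  body <- sample(sense, n_residues - 1L, replace = TRUE, prob = w)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  gene_model(gene_id, paste(c("ATG", body, stop_codon), collapse = ""))
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Design a tiling library over a simulated gene
#'
#' Every 20-mer with an NGG PAM immediately 3' on either strand of the CDS
#' becomes a candidate guide; duplicated and multi-mapping protospacers are
#' dropped. Control guides (negative, positive, non-targeting) are random
#' 20-mers absent from the CDS. Each guide receives an on-target activity
#' drawn from a Beta distribution.
#'
#' @param gene_model A [gene_model()].
#' @param n_controls Named integer vector, e.g. `c(NEG = 24, POS = 18,
#'   NT = 10)` (six guides against each of four non-essential and three
#'   essential genes, plus non-targeting guides).
#' @param activity_shape `c(alpha, beta)` of the Beta activity
#'   distribution; the default `c(5, 2)` gives mean 0.71, matching
#'   libraries pre-filtered for reasonable predicted activity.
#' @param seed Optional RNG seed.
#' @return An `sg_library` whose `sgrnas` carries an extra `activity`
#'   column.
#' @export
design_library <- function(gene_model, n_controls = c(NEG = 24L, POS = 18L,
                                                      NT = 10L),
                           activity_shape = c(5, 2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cds <- gene_model$cds_seq
  L <- nchar(cds)
  chars <- strsplit(cds, "")[[1L]]
  protos <- character(0)
  # plus strand: protospacer [s, s+20), PAM at [s+20, s+23), N G G
  for (s in 0:(L - 23L)) {
    if (chars[s + 22L] == "G" && chars[s + 23L] == "G")
      protos <- c(protos, substr(cds, s + 1L, s + 20L))
  }
  # minus strand: CCN on the coding strand immediately 5' of the 20-mer
  for (s in 3:(L - 20L)) {
    if (chars[s - 2L] == "C" && chars[s - 1L] == "C")
      protos <- c(protos, revcomp(substr(cds, s + 1L, s + 20L)))
  }
  protos <- unique(protos)
  # drop multi-mappers (either orientation matches more than one place)
  n_hits <- vapply(protos, function(p)
    length(substr_positions(cds, p)) + length(substr_positions(cds, revcomp(p))),
    integer(1))
  protos <- protos[n_hits == 1L]
  if (length(protos) < 30L)
    stop("gene too short for a tiling library: only ", length(protos),
         " usable PAM sites", call. = FALSE)
  ctrl <- random_controls(cds, sum(n_controls))
  cats <- c(rep("CDS", length(protos)),
            rep(names(n_controls), times = n_controls))
  all_protos <- c(protos, ctrl)
  df <- data.frame(
    sgrna_id = sprintf("sg%03d", seq_along(all_protos)),
    protospacer = all_protos, category = cats, label = NA_character_,
    stringsAsFactors = FALSE)
  lib <- build_library(df, gene_model)
  lib$sgrnas$activity <- stats::rbeta(nrow(lib$sgrnas), activity_shape[1L],
                                      activity_shape[2L])
  lib
}

# Random 20-mers not occurring (either orientation) in the CDS.
random_controls <- function(cds, n) {
  out <- character(0)
  while (length(out) < n) {
    p <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
               collapse = "")
    if (length(substr_positions(cds, p)) == 0L &&
        length(substr_positions(cds, revcomp(p))) == 0L &&
        !(p %in% out))
      out <- c(out, p)
  }
  out
}

#' Default screen arms
#'
#' Parental (Cas9-negative) and Cas9 arms sampled at days 0, 7 and 14 —
#' the paired-line drop-out design.
#' @return List of arm descriptors.
#' @export
default_arms <- function() {
  list(list(cell_line = "PAR", treatment = "none", days = c(0L, 7L, 14L)),
       list(cell_line = "CAS9", treatment = "none", days = c(0L, 7L, 14L)))
}

#' Default planted essential regions
#'
#' Three windows sized like kinase functional elements (P-loop, catalytic
#' segment, activation-loop neighbourhood) with a per-doubling log2
#' depletion of 0.5 for fully active guides.
#' @return data.frame with `start`, `end`, `effect`.
#' @export
default_essential_regions <- function() {
  data.frame(start = c(68L, 140L, 190L), end = c(82L, 155L, 205L),
             effect = 0.5)
}

#' Simulate a multi-arm tiling screen count matrix with known truth
#'
#' Initial guide abundances are lognormal and shared across arms (one
#' library pool). In Cas9 arms a guide's expected abundance is multiplied
#' per sampling day by `2^(-doublings * activity * effect)`, where `effect`
#' is the planted per-doubling log2 depletion of the residues it targets
#' (positive controls use `pos_effect`, negative/non-targeting guides 0);
#' parental-arm guides are never edited, so their effect is 0. Arms whose
#' `treatment` is neither `"none"` nor `"DMSO"` additionally multiply
#' guides in resistance regions by
#' `2^(+doublings * enrich_effect * in_frame_prob * activity)`. Counts are
#' negative-binomial around `depth * relative abundance`.
#'
#' @param library An `sg_library` from [design_library()] (needs the
#'   `activity` column).
#' @param arms List of arm descriptors (`cell_line`, `treatment`, `days`);
#'   default [default_arms()].
#' @param essential_regions data.frame `start`, `end`, `effect`; default
#'   [default_essential_regions()].
#' @param resistance_regions Optional data.frame `start`, `end`,
#'   `enrich_effect`, `in_frame_prob`.
#' @param pos_effect Per-doubling log2 depletion of positive-control
#'   guides; default 0.5.
#' @param n_replicates Replicates per arm; default 2.
#' @param depth Reads per sample; default 1e6.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); default 0.01. Zero gives Poisson noise.
#' @param initial_sdlog sdlog of the lognormal initial abundances; default
#'   0.5.
#' @param doublings_per_day Cell doublings per day; default 1 (a two-week
#'   screen then spans ~14 doublings).
#' @param seed Optional RNG seed.
#' @return List with `counts` (a `count_matrix`) and `truth` (list with
#'   `expected_rpm` matrix, per-guide `activity` and `effect`, and the
#'   planted region tables).
#' @export
simulate_screen <- function(library, arms = default_arms(),
                            essential_regions = default_essential_regions(),
                            resistance_regions = NULL,
                            pos_effect = 0.5, n_replicates = 2L,
                            depth = 1e6, nb_dispersion = 0.01,
                            initial_sdlog = 0.5, doublings_per_day = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sg <- library$sgrnas
  if (is.null(sg$activity))
    stop("library lacks per-guide activity scores; use design_library()",
         call. = FALSE)
  n <- nrow(sg)
  effect <- numeric(n)
  enrich <- numeric(n)
  for (i in seq_len(n)) {
    if (sg$category[i] == "POS") {
      effect[i] <- pos_effect
    } else if (sg$category[i] == "CDS") {
      res <- sg$residues[[i]]
      if (length(res) > 0L && nrow(essential_regions) > 0L) {
        hit <- essential_regions$start <= max(res) &
          essential_regions$end >= min(res)
        if (any(hit)) effect[i] <- max(essential_regions$effect[hit])
      }
      if (!is.null(resistance_regions) && length(res) > 0L) {
        hit <- resistance_regions$start <= max(res) &
          resistance_regions$end >= min(res)
        if (any(hit))
          enrich[i] <- max(resistance_regions$enrich_effect[hit] *
                             resistance_regions$in_frame_prob[hit])
      }
    }
  }
  init <- stats::rlnorm(n, meanlog = 0, sdlog = initial_sdlog)

  samples <- list()
  expected_rpm <- NULL
  counts <- NULL
  has_day0 <- vapply(arms, function(a) 0L %in% a$days, logical(1))
  if (!all(has_day0))
    stop("every arm needs a day-0 reference sample", call. = FALSE)
  for (arm in arms) {
    edited <- arm$cell_line == "CAS9"
    drugged <- edited && !(arm$treatment %in% c("none", "DMSO"))
    for (day in arm$days) {
      doublings <- doublings_per_day * day
      log2mult <- if (edited) {
        -doublings * sg$activity * effect +
          (if (drugged) doublings * sg$activity * enrich else 0)
      } else rep(0, n)
      w <- init * 2^log2mult
      p <- w / sum(w)
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_%s_d%d_r%d", arm$cell_line, arm$treatment,
                       day, r)
        mu <- depth * p
        cnt <- if (nb_dispersion > 0) {
          stats::rnbinom(n, mu = mu, size = 1 / nb_dispersion)
        } else {
          stats::rpois(n, lambda = mu)
        }
        counts <- cbind(counts, cnt)
        expected_rpm <- cbind(expected_rpm, p * 1e6)
        samples[[sid]] <- sample_meta(sid, arm$cell_line, day,
                                      arm$treatment, r)
      }
    }
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  dimnames(counts) <- list(sg$sgrna_id, samples$sample_id)
  dimnames(expected_rpm) <- dimnames(counts)
  cm <- count_matrix(counts, samples)
  list(counts = cm,
       truth = list(expected_rpm = expected_rpm, activity = sg$activity,
                    effect = effect, enrich = enrich,
                    essential_regions = essential_regions,
                    resistance_regions = resistance_regions))
}

#' Expected log2 fold change implied by a simulation truth table
#'
#' Computed on expected RPM with the same +1 pseudocount as
#' [compute_lfc()], so pipeline estimates converge to these values as
#' depth grows.
#'
#' @param truth The `truth` element of [simulate_screen()] output.
#' @param numerator_sample,denominator_sample Sample ids.
#' @return Named numeric vector of expected LFCs.
#' @export
true_lfc <- function(truth, numerator_sample, denominator_sample) {
  e <- truth$expected_rpm
  log2(e[, numerator_sample] + 1) - log2(e[, denominator_sample] + 1)
}

#' Simulate amplicon reads from an evolving allele mixture
#'
#' Builds an amplicon around `cut_pos` (clipped to the CDS), applies each
#' allele descriptor to the reference, and samples reads per day from the
#' mixture `frac_day1 * mult_per_day^(day - day_1)`, renormalised, with an
#' optional uniform substitution error. A WT allele is a row with
#' `ref_len = 0` and empty `alt`.
#'
#' @param gene_model A [gene_model()].
#' @param cut_pos 0-based CDS cut coordinate (see [map_protospacer()]).
#' @param allele_spec data.frame with columns `start` (0-based amplicon
#'   coordinate), `ref_len`, `alt`, `frac_day1`, `mult_per_day`.
#' @param days Sampling days; default `c(1, 2, 5, 9)`.
#' @param reads_per_day Reads per timepoint; default 500.
#' @param flank Amplicon half-width around the cut; default 80 nt.
#' @param error_rate Per-base substitution error; default 0.
#' @param seed Optional RNG seed.
#' @return List with `amplicon`, `reads` (named list day -> character
#'   vector), and `truth` (allele_spec plus left-normalised descriptors,
#'   consequence strings and per-day expected fractions).
#' @export
simulate_amplicon_reads <- function(gene_model, cut_pos, allele_spec,
                                    days = c(1L, 2L, 5L, 9L),
                                    reads_per_day = 500L, flank = 80L,
                                    error_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(sum(allele_spec$frac_day1) - 1) > 1e-8)
    stop("allele day-1 fractions must sum to 1", call. = FALSE)
  cds <- gene_model$cds_seq
  amp_start <- max(0L, cut_pos - flank)
  amp_end <- min(nchar(cds), cut_pos + flank)
  amp <- amplicon(substr(cds, amp_start + 1L, amp_end),
                  cut_pos_amplicon = cut_pos - amp_start,
                  cds_offset = 0L, frame_anchor = amp_start)
  n_alleles <- nrow(allele_spec)
  seqs <- character(n_alleles)
  consequence <- character(n_alleles)
  frame_class <- character(n_alleles)
  for (i in seq_len(n_alleles)) {
    d <- list(start = allele_spec$start[i],
              ref_len = allele_spec$ref_len[i],
              alt = allele_spec$alt[i], compound = FALSE)
    is_wt <- d$ref_len == 0L && nchar(d$alt) == 0L
    seqs[i] <- if (is_wt) amp$seq else apply_descriptor(amp$seq, d)
    cons <- protein_consequence(gene_model, amp, if (is_wt) NULL else d)
    consequence[i] <- cons$hgvs_p
    frame_class[i] <- cons$frame_class
  }
  reads <- list()
  fracs <- matrix(NA_real_, n_alleles, length(days),
                  dimnames = list(NULL, paste0("frac_d", days)))
  day1 <- min(days)
  for (k in seq_along(days)) {
    w <- allele_spec$frac_day1 * allele_spec$mult_per_day^(days[k] - day1)
    p <- w / sum(w)
    fracs[, k] <- p
    cnt <- as.integer(stats::rmultinom(1L, reads_per_day, p))
    rd <- rep(seqs, times = cnt)
    if (error_rate > 0 && length(rd) > 0L) rd <- add_errors(rd, error_rate)
    reads[[as.character(days[k])]] <- sample(rd)
  }
  truth <- cbind(allele_spec,
                 data.frame(consequence = consequence,
                            frame_class = frame_class,
                            stringsAsFactors = FALSE),
                 as.data.frame(fracs))
  list(amplicon = amp, reads = reads, truth = truth)
}

add_errors <- function(reads, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(s) {
    ch <- strsplit(s, "")[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of read sequences.
#' @param path Output FASTQ path (`.gz` for compressed output).
#' @param prefix Read-name prefix.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_%06d", prefix, seq_along(reads))
  q <- Biostrings::PhredQuality(vapply(Biostrings::width(x),
                                       function(w) strrep("I", w),
                                       character(1)))
  xs <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(
    xs, path, compress = grepl("\\.gz$", path))
  invisible(path)
}
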