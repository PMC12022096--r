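---
title: "Analysing single-gene CRISPR tiling screens with tilescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing single-gene CRISPR tiling screens with tilescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescreen)
```

## The experiment this package models

A CRISPR tiling screen disperses sgRNAs densely along the coding sequence
of a single gene so that the fitness consequence of cutting — and of the
in-frame indels left behind at each cut — can be read out position by
position on the protein. Guides whose edits disrupt a functionally
essential region drop out of the population; under drug selection, guides
whose edits confer resistance are enriched. The analysis problem is to turn
raw sequencing of the sgRNA cassette into calibrated per-guide effect
sizes, project those onto protein residues, and call contiguous residue
regions as functional (drop-out) or resistance-associated (enrichment).

`tilescreen` implements that pipeline end to end, together with a
single-locus amplicon module that resolves the individual editing outcomes
behind one guide, and a synthetic-screen generator that plants known truth
at every stage so the whole chain is testable at desk scale.

## Quantification and normalisation

Reads are assigned to guides by exact substring matching of the 20-nt
protospacer (either orientation) within each read; a read matching zero or
more than one distinct guide is left unassigned. Exact matching keeps
counting verifiable against a brute-force scan and is deterministic; there
is no mismatch tolerance. One consequence worth knowing about: tiling
guides overlap heavily on the CDS, so a read context that happens to extend
a protospacer by the right nucleotide can complete a neighbouring guide's
20-mer and force an (honest) ambiguity call. With randomised context this
affects a stable minority of reads; with a fixed vector junction it can be
systematic for specific guide pairs. Counting is the place to look first if
assignment rates seem low in a dense library.

Counts are depth-normalised to reads per million:
\[
\mathrm{RPM}_{ij} = \frac{c_{ij}}{\sum_i c_{ij}} \times 10^6 ,
\]
and per-guide effects are log2 fold changes of RPM with a pseudocount of 1
applied on the RPM scale:
\[
\mathrm{LFC}_{i} = \log_2(\mathrm{RPM}_{i,\mathrm{num}} + 1)
  - \log_2(\mathrm{RPM}_{i,\mathrm{den}} + 1).
\]
Replicates are paired by replicate index; the LFC is computed per pair and
then averaged. The pseudocount bounds the statistic when a guide is absent
from one sample; it also means the LFC of a fully depleted guide saturates
near \(-\log_2(\mathrm{RPM}_{den}+1)\) rather than \(-\infty\).

The package's canonical contrast is the paired-line design: the
nuclease-expressing line at the end of the screen against the parental
(Cas9-negative) line at day 0. Because the parental denominator is never
edited, this contrast retains the full depletion signal instead of
differencing away early drop-out, and the parental arm doubles as a control
for composition drift.

Guides with fewer than 300 reads in the reference (parental day-0) sample
are flagged and excluded from binning and residue mapping; at typical
library coverage these are guides whose measurement is dominated by
sampling noise. The threshold is a parameter (`min_count`), applied as a
strict inequality.

## On-target activity correction

Predicted editing activity varies between guides and biases positional
comparisons: a weak guide in a critical region looks like a weak region.
Scores from an external predictor are consumed as a plain numeric column
(values in (0,1] or (0,100]). The correction divides the mean LFC by the
activity, floored at 0.2:
\[
\mathrm{LFC}^{corr}_i = \mathrm{LFC}_i / \max(a_i, 0.2).
\]
Division is the minimal monotone rescaling that undoes a multiplicative
activity model, never flips the sign, and the floor caps the amplification
applied to near-dead guides, whose LFC is mostly noise. This functional
form is a design choice of this package — activity-aware correction can be
parameterised in several ways — and it is deliberately exposed as a plain,
documented rule rather than a fitted model. Note that the correction also
rescales any additive composition offset shared by all guides, so it is
most meaningful on contrasts where the bulk of the library is
approximately neutral (as in a tiling library with controls).

## Control-calibrated calling and screen QC

Negative-control guides (targeting non-essential genes) define the null
LFC distribution. The depletion threshold is their 5th percentile (linear
interpolation, the default type-7 quantile); a guide is called depleted
when strictly below it. Per-category depletion rates, the
positive-vs-negative ROC AUC, and rank-sum comparisons of each category
against the negative controls make up the QC report. The AUC is computed
as the normalised Mann–Whitney statistic (ties count one half), which
equals the area under the empirical ROC curve and is invariant under
monotone transforms of the score; the rank-sum test is the unpaired
two-tailed Wilcoxon with tie-corrected normal approximation.

## Residue projection, binning and region calling

Each CDS guide is placed by exact protospacer match; the blunt SpCas9 cut
is placed between protospacer positions 17 and 18 (3 nt 5' of the NGG
PAM), and the guide is assigned the one or two consecutive residues whose
codons flank the cut. This two-codon window is intentionally narrow: the
guides' own labels ("sgR234/L235"-style) name at most two consecutive
residues, and wider windows smear effects across motifs at the scale the
screen is trying to resolve. Multi-mapping protospacers are rejected
rather than placed arbitrarily. Multi-exon genes are supported only via a
pre-spliced CDS; the caller is responsible for splicing.

Unfiltered CDS guides are ranked by mean LFC (most enriched first) and
split into 17 contiguous rank groups as equal in size as possible (the
first `N mod 17` bins take one extra guide); ties break lexicographically
by guide id so the partition is deterministic. Bin 17 is the most
depleted, bin 1 the most enriched. Per residue, the track records the mean
LFC of assigned guides and the extreme bin among them (max for drop-out,
min for enrichment).

Regions are called from residues whose extreme bin falls in a qualifying
set (bins 16–17 for drop-out, 1–2 for enrichment by default), merging
seeds separated by at most one non-qualifying residue. Because bin
membership is purely relative, a screen with little signal would still
populate the extreme bins with noise-level guides; `call_regions()`
therefore accepts an optional absolute effect-size floor (`lfc_cutoff`),
and the recommended drop-out configuration uses bins 16–17 together with
`lfc_cutoff = -1` (at least a two-fold abundance change). One log2 unit is
far outside the null spread at typical depth (the negative-control 5th
percentile in the simulated studies sits near −0.1) yet well inside the
depletion of a genuinely essential region over a two-week screen, so the
floor removes relative-rank noise without costing sensitivity. Setting
`lfc_cutoff = NULL` recovers pure bin-based behaviour; enrichment calls
may equivalently use an absolute LFC threshold.

Per-residue scores (mean LFC or best bin) can be written into the
B-factor column of a PDB file for heat-map rendering in any structure
viewer. The export rewrites only columns 61–66 of `ATOM`/`HETATM` records
of the chosen chain and leaves every other byte of the file untouched;
unscored residues get 0.00 with a note.

## Single-locus allele analysis

For one guide of interest, amplicon sequencing across the cut site
resolves which alleles drive the population-level signal. Reads are
globally aligned to the amplicon (match +2, mismatch −4, gap open −12,
gap extend −1; a gap of length L costs 12 + (L−1)); alignments scoring
below 0.4 × 2 × read length are rejected. Gap placement is
left-normalised — every gap run is shifted left through repeat context
while the score is unchanged — so equivalent indels always receive one
canonical description. Events (gap or mismatch runs) overlapping a ±20 nt
window around the cut are merged into a single descriptor; events wholly
outside the window are treated as sequencing noise. The window reflects
where Cas9 repair outcomes concentrate; widen it for amplicons with known
distal edits.

Descriptors are lifted through the amplicon's frame anchor into CDS
coordinates and translated. Consequences are reported in an HGVS-like
protein notation — `A372del`, `I141_C142delinsEI`, `G237V`, `L235=`
(synonymous), `K59_E62del`, `R234fs` — with a frame class (`WT`,
`synonymous`, `in_frame`, `frameshift`; frameshift if and only if the net
indel length is not a multiple of 3). Affected spans are named after
trimming the maximal common protein prefix first, which pairs with
left-normalised alignments to keep naming deterministic in repeats. An
in-frame consequence string can be applied back to the reference protein
(`apply_protein_hgvs()`) and must reproduce the translation of the
alternate CDS; the test suite asserts this self-consistency on randomised
edits.

Alleles are keyed by protein consequence (not nucleotide string), matching
how editing outcomes are usually reported; abundances are reads per
million aligned reads per timepoint, and per-allele LFC is taken against
the day-1 reference with the same +1 pseudocount. The frameshift versus
in-frame comparison is a rank-sum test on per-allele LFCs at a chosen day;
at a genuinely functional region the two classes deplete similarly, so a
non-significant result is the expected, informative outcome, and the test
is validated for type-I control on null simulations rather than for power.

## The synthetic study

`simulate_gene()` draws a random CDS (ATG start, single terminal stop, no
internal stops) with 56% GC, typical of human kinase coding sequence; GC
content sets the NGG PAM density and hence the achievable guide density.
`design_library()` takes every 20-mer with an NGG immediately 3' on either
strand, drops duplicates and multi-mappers, and appends 24 negative, 18
positive and 10 non-targeting control guides (six guides for each of four
non-essential and three essential control genes). On a 393-residue gene
this yields roughly 180–200 CDS guides covering 40–46% of residues — the
sparse-PAM regime in which a real NGG tiling library operates. Each guide
receives an on-target activity drawn from Beta(5, 2) (mean 0.71),
emulating a library pre-filtered for usable guides.

`simulate_screen()` models the pooled dynamics: lognormal initial
abundances (sdlog 0.5) shared across arms, exponential per-doubling
depletion `2^(−doublings × activity × effect)` in nuclease arms (zero in
the parental arm), optional per-doubling enrichment for guides in
resistance regions under drug treatment, and negative-binomial counts
(variance μ + 0.01 μ²; dispersion 0 falls back to Poisson, the count-noise
floor) at 10⁶ reads per sample, two replicates, one doubling per day with
sampling at days 0, 7 and 14. Positive controls and planted essential
windows use a per-doubling effect of 0.5, i.e. strong but not total
depletion over ~14 doublings once multiplied by per-guide activity. The
default planted windows (residues 68–82, 140–155, 190–205) are sized like
kinase functional elements. The truth table records expected RPM per
sample, from which the expected LFC of any contrast follows with the same
pseudocount as the pipeline.

What the generator does **not** emulate: sequencing error inside the
cassette read, guide-specific repair-outcome spectra (each guide's effect
is a single scalar rather than a mixture over frameshift and in-frame
alleles), off-target cutting, fitness interactions between cells, and
PCR/jackpot artefacts beyond the NB dispersion. Passing tests therefore
demonstrate correctness of the analysis on the stated statistical model,
not robustness to every artefact of real data.

`simulate_amplicon_reads()` plants an allele spectrum at one locus: each
allele is a descriptor with a day-1 fraction and a per-day multiplier;
reads are drawn multinomially per day with optional uniform substitution
error. It returns the amplicon, per-day reads and a truth table of
descriptors, consequences and expected fractions.

## Numerical and edge-case choices

* Quantiles are type 7 (linear interpolation); "depleted" is a strict
  inequality, so boundary values are never called.
* Binning requires at least as many scored guides as bins; ties are broken
  by guide id.
* `rpm()` refuses zero-depth samples by name; `compute_lfc()` refuses
  contrasts whose replicate indices do not pair.
* Cuts in the stop codon region clip to the last residue or, when wholly
  in the stop codon, yield no residue with a warning.
* Alignment tie-breaking is fixed in the traceback and then canonicalised
  by left-normalisation, so indel descriptors are reproducible across
  equivalent optimal alignments.
* All generators are bit-reproducible under a fixed seed; every stochastic
  test fixes one.

## Problem sizes used in the shipped checks

The package's own test suite and the acceptance script run entirely on
simulated data: screens of ~230–250 guides × 12 samples at depth 10⁶,
counting checks on 10³ reads against ~300 guides, region-recovery studies
of 10–20 independent simulated screens, and allele studies of a few
hundred amplicon reads per timepoint over four timepoints with 50-seed
null replications. These sizes were chosen so every planted effect is
comfortably detectable at the stated tolerances while each check stays
close to instantaneous; they are stated here so readers know what the
reported rates were measured on.

One calibration note: planted-LFC recovery to ±0.3 is asserted on screens
whose expected LFCs lie in [−2.1, 0]. Recovery of far stronger depletion
(expected LFC near −7) is intrinsically noisier — the numerator counts
shrink toward the NB noise floor — and is exercised instead through the
rank-based checks (AUC, binning, region recovery), which are insensitive
to that saturation.

## Limitations

* The CDS must be supplied pre-spliced; genomic coordinates, introns and
  alternative isoforms are out of scope.
* Exact-match counting understates abundance when cassette reads carry
  sequencing errors inside the protospacer; there is no mismatch recovery.
* The activity correction is a fixed monotone rule, not a fitted model; a
  second divisor column (e.g. a predicted frameshift rate) can be applied
  with the same rule where appropriate.
* The allele module assumes a single edited locus within the amplicon and
  merges co-occurring events into one compound descriptor rather than
  phasing them.
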