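---
title: "Competitive internal-standard quantification: model, QC and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive internal-standard quantification: model, QC and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campseq)
```

# The measurement model

A competitive amplicon panel pairs every native target (NT) with a synthetic
internal standard (IS): a 101-nt template identical to the NT at both priming
sites and differing at exactly six positions inside a 60-nt central window.
Because the pair shares primers, NT and IS amplify with the same efficiency
and their molar ratio is invariant through PCR — including plateau phase.
Sequencing therefore measures the pre-amplification ratio, and with `SC_i`
known IS copies loaded at dilution point `i`, absolute native copies per
library preparation are estimated per replicate as

$$NC_i = \frac{NT_i}{IS_i} \cdot SC_i,$$

where `NT_i` and `IS_i` are the binned read counts. Two structural properties
follow, and both are enforced as tests:

* **scale equivariance**: scaling all `SC` by `k` scales every estimate by `k`;
* **read-depth invariance**: multiplying all counts in a replicate by a
  constant leaves `NC_i` unchanged — sequencing depth cancels out of the
  estimator entirely.

Driving every amplicon toward a common plateau concentration compresses the
between-gene read range (a 10^6-fold copy range collapses to roughly 10^3-fold
in reads) while each within-gene NT:IS ratio is untouched. That compression is
the entire case for the method's read economy, and
`simulate_competitive_pcr()` encodes it literally: plateau totals are set per
gene, the NT fraction is exactly `nt / (nt + sc)`.

# Read parsing and allele calling

Reads strictly longer than 150 nt are split by pure string slicing into the
first and last 14 bases (barcode tags, each containing a 4-nt sample index)
and the central region, from which the 60-nt diagnostic window is extracted.
Base qualities are carried but unused: amplicons are fixed-length and
indel-free by construction, so classification is purely sequence-based.

Demultiplexing matches both 4-nt indices exactly and accepts a read only when
they name the same library; discordant pairs are discarded as conflicts
(dual indexing exists precisely to suppress false indexing). Allele calling
assigns the gene by minimal Hamming distance over the window, capped at
`max_mismatch = 5`; panels are built with pairwise window distances of at
least 15, so at that cap a read can never be attracted to the wrong gene, and
a random 60-mer (expected identity 25%, i.e. ~45 mismatches) can never be
assigned at all. The NT/IS decision then uses only the six diagnostic
positions: a call requires at least 4 of 6 bases matching one allele and a
strict majority over the other; split evidence is `ambiguous` and excluded
from counts, never fractionally assigned. Enumerating all reads within two
errors of an NT window shows the boundary behaves as intended: every such
read is still called NT, and NT-to-IS swaps require at least four errors
hitting diagnostic positions with exactly the other allele's bases —
vanishingly rare at substitution rates of 1% or less.

This Hamming classifier replaces general-purpose read alignment. For
fixed-length, indel-free amplicons an aligner adds no information; the
substitution is deliberate and is the one methodological replacement made in
the data-processing chain (homopolymer indel errors typical of
semiconductor sequencing are correspondingly out of scope).

# Quantification, QC and the pipetting correction

Per (sample, gene), replicates are filtered to those with at least
`min_counts = 15` reads for both NT and IS; survivors must show dispersion of
log10 `NC_i` below `max_cv_log10 = 1.00` (a 10-fold spread), and the default
summary is their median. These defaults are the combination selected by the
grid search that `optimize_summarization()` re-implements: summarizer
(average / median / least squares / weighted least squares) crossed with
count and dispersion filters, scored by the R² of log10 measured vs expected
jointly with the number of genes retained. Because those two objectives
trade off, the grid is reported with a Pareto flag rather than a single
scalarized winner; `best` maximizes R² subject to a retention floor.

Two definitions were genuinely open:

* **"CV on a base-10 logarithm scale"** is implemented as the standard
  deviation of log10 `NC_i`. A mean-normalized CV of logarithms is ill-posed
  when mean log values approach zero; the SD-of-logs reading makes the stated
  threshold of 1.00 a clean 10-fold spread. Both the statistic and the
  threshold are exposed as parameters.
* **The pipetting correction's "expected from surrounding dilution points"**
  is implemented order-free: each replicate's offset is the median over genes
  of (log10 `NC_i` − the gene's cross-replicate median), using genes valid in
  at least three replicates, subtracted on the log scale. A median over genes
  is robust to the handful of genuinely noisy assays, and a cross-replicate
  median avoids privileging neighbors on the dilution ladder, which the
  design does not order physically. Injecting a +0.3 log10 shift into one
  replicate of a clean simulated study recovers the offset to ±0.02.

Zero counts are flags, not zeros: `IS = 0` leaves the estimate undefined, and
`NT = 0` with adequate IS yields a below-detection bound of `SC/IS` copies.

The least-squares summarizers fit the titration model directly: with slope
fixed at −1 (the competitive law), the intercept-implied NC reduces to the
(inverse-variance-weighted) geometric mean of the replicate estimates, with
Poisson counting variance `(1/NT + 1/IS)/ln(10)²` supplying the weights.

# Evaluation statistics

**Titration linearity.** `fit_titration()` regresses log10(NT:IS) on
log10(SC); the competitive model demands slope −1, and on noise-free ratios
the fit returns −1 to machine precision. Prediction intervals use the
standard linear-regression formula, pooled across points; at least three
titration points are required (fewer is a no-fit result, matching the
at-least-three-dilutions reporting rule).

**Poisson variance.** Sampling `n` molecules or reads is Poisson, so the
expected CV is `1/sqrt(n)` — 25.8% at the 15-read QC floor. The simulator's
multinomial sampling reproduces this to Monte-Carlo precision, which is what
justifies using propagated Poisson intervals for parameter-recovery checks.

**Fold-change ROC.** Measured abundance ratios between sample pairs are
scored against the known design ratios. Comparisons with expected ratio
exactly 1 are controls; the rest are binned by expected ratio into fixed
ranges ([1.05–1.174], [1.175–1.374], [1.375–1.74], [1.75–2.49],
[2.5–10.0]). AUC is the rank (Mann–Whitney) statistic — invariant to monotone
transforms of the scores — with a Hanley–McNeil normal 95% CI, a choice made
here because no CI method is prescribed by the design. The comparison
enumeration (which sample pairs, which orientation) is fixed and documented
in `roc_fold_change()`; control/test counts depend on it, so they are treated
as descriptive, not as targets.

**Read budgets.** For traditional preparation, read shares mirror input
copies, so observing the rarest of targets with copies `c` at least `m` times
costs `ceil(m · sum(c)/min(c))` reads — 15,000,015 for two targets a
million-fold apart at `m = 15`. For competitive libraries the budget is set
by the smallest realized read fraction. At study level
(`study_read_budget()`), each target-sample cell's best share is taken over
that sample's dilution libraries and each sample's pool is sized
independently by its own worst target, with the budget the sum over samples.
This reflects pooling libraries at chosen stoichiometry rather than blindly
equal pooling; since the minimum share is a heavy-tailed extreme statistic,
study budgets are best compared as medians over replicate simulations and to
order of magnitude.

**Detection power.** The 15-read benchmark is interpreted as a one-sample
exact two-sided Poisson test of an observed count against a known,
IS-anchored reference mean. The rejection region takes the largest lower and
smallest upper tails, each with at most α/2 null probability; both error
rates are exact tail sums. This is the standard construction under which 15
reads detect a 2-fold change with type I error 0.037 and type II error 0.115
(two-sample constructions only reach power near 0.6 at these counts, so the
one-sample reading is the only one consistent with the stated benchmark).
The exact test is conservative — type I error never exceeds α — and power is
monotone in the mean and in the fold change, both asserted as properties.

**Agreement.** Bland–Altman summaries and the cross-platform correction
operate on log10 values with below-detection values excluded pairwise. The
correction estimates each gene's systematic platform offset as the mean
log10 difference over samples A and B and subtracts it from C and D; genes
whose bias differs between A and B (platforms reading different transcript
isoforms) are exactly the ones left with residual error, which the simulated
check reproduces.

# What the generator emulates — and what it does not

`simulate_*_study()` presets encode the three reference designs as their
defaults, chosen once from the study descriptions and not revisited:

* **gDNA calibration study**: 150 assays against a constant 1e5 genomic
  copies, 10-point 3-fold IS ladder from 2e7 down to ~1e3 copies. Of the 150,
  26 assays have near-zero primer efficiency (too few reads to ever pass the
  count filter) and 1 carries gross analytical variation (per-replicate
  lognormal noise, SD 2.0 log10, far above the 1.00 QC cut), so 123 of 150
  pass QC with the failures attributed to the right causes.
* **Endogenous cDNA study**: 123 working assays in samples A–D, 12-point
  3-fold ladder from 6e7 down to ~3.4e2 copies. Sample-A abundances are
  log-uniform over the observed ~6.2e7-fold range starting at 30 copies
  (log-uniform is the simulator's stated abundance law; real expression is
  more concentrated at low abundance, which is why sum-based traditional
  budgets — dominated by the top of the distribution — are only
  order-of-magnitude comparable). Sample B scales A by a lognormal fold
  (SD 1 log10), emulating an unrelated tissue; C and D are the 3:1 and 1:3
  mixtures.
* **ERCC study**: 28 assays in four subgroups with B:A ratios 0.5 / 0.67 /
  1.0 / 4.0, A log-uniform over the ~2.7e6-fold spike-in range, IS ladder
  1e6 / 1e5 / 1e4 / 1e3 / 300 copies, one low-efficiency and one
  non-titrating assay (26 working).

Noise model, with magnitudes fixed a priori from the study descriptions:
per-replicate lognormal technical noise of 0.08 log10 (~20% CV, the reported
median intra-assay CV) applied to the NT:IS ratio; a per-library pipetting
factor of 0.05 log10 (what the pipetting correction removes); lognormal
plateau jitter of 0.1 log10 (unequal primer efficiency, never touching the
ratio); and a fixed per-assay IS calibration error — 0.45 log10 for ERCC
standards (their mixes are assembled through multi-step chip-based
quantification, and an observed measured-vs-known R² of ~0.94 over a
6.4-decade range implies a per-assay systematic SD near this value) versus
0.05 log10 for endogenous standards, which are cross-calibrated against
genomic DNA. The calibration error is systematic per assay, so it cancels in
mixture cross-validation (C/D predicted from A/B) and in between-sample
ratios, but not against nominal truth — exactly the structure the reference
comparisons show. Reads per library default to 1e5, chosen so the 15-read
QC floor is binding for rare targets; total reads per library are not a
study-prescribed quantity.

What passing tests on this generator do **not** show about real data: no
homopolymer or indel errors, no chimeric or heterodimer artifacts, no
reverse-transcription efficiency variation (fixed at 1), no cross-gene
primer interactions, and a single fixed read orientation (directional
adapters make orientation deterministic, so reverse-complement bookkeeping
is omitted). The generator validates the statistical machinery, not the
chemistry.

# Numerical choices and degenerate inputs

* Coordinates are 0-based with half-open windows; the 60-nt window is
  centered in the 101-nt amplicon (offset 20) — a convention, since only the
  window's length and content are prescribed. With the default read layout
  (11-nt spacers), the window starts at offset 31 of the 123-nt central
  region of a 151-nt read.
* The length filter is strictly `> 150` as stated.
* Allele-call ties across genes resolve to the first assay in panel order —
  deterministic, and unreachable for validated panels (window distances
  ≥ 15 > 2 × the mismatch cap).
* Dispersion is computed only when two or more replicates survive; a single
  survivor reports `cv_log10 = 0` and remains valid (the one-or-more-valid-
  measurements rule).
* Malformed FASTQ records (sequence/quality length mismatch, bad header) are
  skipped and tallied per record, never fatal; too-short central regions map
  to an unclassifiable marker rather than an error.
* All stochastic stages flow from a single integer seed; study presets derive
  stage seeds by fixed offsets, so count tables are byte-reproducible.

Problem sizes used by the test and acceptance suites — full-scale panels
(150 / 123 / 28 assays) with 1e5 reads per library for count-level studies,
and 8–20-gene panels with a few thousand reads per library wherever raw FASTQ
emission and re-binning are exercised — were chosen as the smallest designs
that leave every study-level statistic in its asymptotic regime.

# Known limitations

* Allele calls come from an exact/Hamming classifier, not a general
  aligner; no equivalence between a Hamming threshold and any particular
  alignment stringency is claimed, so counts from alignment-based
  processing of real instrument reads may differ at the margins.
* Per-bin control/test counts in the fold-change ROC depend on the chosen
  pair enumeration; they are reported as descriptive output, not matched
  to any external tally.
* The traditional read budget assumes proportional read shares and Poisson
  sampling; deviations reported for fragmentation-based protocols are not
  modelled.
* Below-detection handling reports bounds, not estimates; downstream
  analyses that need imputation must supply their own.
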