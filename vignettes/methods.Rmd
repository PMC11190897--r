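---
title: "From inflamed-gut transcriptomics to nociceptor physiology: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From inflamed-gut transcriptomics to nociceptor physiology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nocimap)
```

nocimap chains six analysis stages that, together, take a mediator from
"upregulated in inflamed biopsies" to "activates visceral nociceptors":
bulk differential expression, gene-set enrichment, a mediator→receptor
screen against single-neuron expression, Ca²⁺-imaging responder
classification, afferent-nerve spike quantification, and
immunocytochemistry cell counting. This vignette explains each model, the
parameters that matter, and the design decisions taken where the underlying
experimental conventions leave choices open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Differential expression

Counts are modelled per gene as negative binomial with dispersion φ, so the
variance is μ + φμ². The stage runs in four steps.

**Low-count filtering.** A gene is retained if its CPM reaches `min_cpm`
(default 1) in at least `min_samples_per_group` (default 2) samples of some
group. The defaults remove genes expressed in only one sample per group; both
knobs are exposed because the underlying convention is a judgment call, not a
derivation.

**TMM normalization.** For each sample against a reference (the sample whose
upper-quartile CPM is closest to the mean upper quartile), per-gene log
ratios M and average abundances A are computed over genes positive in both
samples, doubly trimmed (30% of M, 5% of A — the field-standard trims,
configurable), and averaged with inverse asymptotic-variance weights
`(N−y)/(Ny)` summed over the two samples. Factors are rescaled to geometric
mean 1; effective library size = raw library size × factor.

One property worth stating precisely: because those weights are functions of
library size, doubling every count in one sample (a pure depth change)
perturbs its factor at the third decimal rather than leaving it bit-identical.
Normalized results are stable to well under |Δp| = 0.01, which is what the
test suite asserts.

**Dispersion.** Counts are equalized onto a common library size (geometric
mean of effective library sizes by default, or a fixed value via
`common_lib_size`) by simple rescaling — deliberately simpler than the
quantile-to-quantile adjustment some implementations use, because it
preserves the exact-test contract transparently at this scale. The common φ
maximizes the summed conditional NB log-likelihood given per-group totals
(groups of ≥ 2 samples), located on a log-spaced grid and refined by
golden-section search. Tagwise values maximize each gene's own conditional
likelihood plus `prior_df` (default 10) times the average per-gene
likelihood curve; as `prior_df → ∞` every tagwise value collapses onto the
common one, which the tests assert at `prior_df = 1e6`.

**Exact test.** Conditional on a gene's total pseudo-count, the split
between the groups is negative-hypergeometric (the NB mean cancels), and in
the φ→0 limit binomial. The two-sided p sums the probabilities of all splits
no more probable than the one observed; BH adjustment runs across retained
genes. Fold changes use group means of pseudo-counts with a 0.125 prior
count so zeros stay finite. The significance gate defaults to adjusted
p ≤ 1e-4 with a flag to gate on raw p instead: the convention underlying
published gene tallies of this kind is usually ambiguous between the two,
so both are provided and neither is privileged.

Calibration is regression-tested at the study's scale: on a null simulation
(φ = 0.2, 5 vs 5, 2000 genes) the fraction of p < 0.05 must land in
[0.03, 0.07], and planted |log₂FC| ≥ 1 at 8 vs 8 must be recovered with
sensitivity ≥ 0.8 at FDR ≤ 0.05. edgeR, which implements the same qCML
family of estimators, serves as an independent cross-check in the suite —
never as the implementation.

## Enrichment

Fisher exact enrichment is one-sided (the upper hypergeometric tail), the
EnrichR convention for gene-set work. The background universe defaults to
the union of all library genes plus whatever extra background the caller
supplies (typically all DE-tested genes), since "background" is otherwise
undefined. The odds ratio uses the Haldane +0.5 correction only when a
denominator cell is zero: correcting every cell whenever any cell is zero
would push zero-overlap terms above OR = 1, which misreports depletion as
enrichment.

The rank z-score is Monte-Carlo: `n_permutations` (default 1000, seeded)
random query sets of the observed size are drawn uniformly from the
universe, terms are ranked by p in each draw, and
`z = (mean_perm_rank − observed_rank)/sd_perm_rank` (sd floored at 1e-6), so
terms ranked earlier than chance score positive. A permutation scheme is
used because precomputed expected-rank tables are a property of specific
reference tools, not of the statistic. The combined score is
`c = −ln(p_adj)·z` with p floored at 1e-300; the sign convention makes
enriched terms positive, resolving the ambiguity that ln p_adj < 0 would
otherwise introduce.

## The receptor screen

Coverage asks: what fraction of profiled sensory neurons express *any*
receptor for the mediator above a TPM threshold? The threshold defaults to
0 (any detected transcript) because single-neuron "expressing" conventions
vary; `coverage_sensitivity()` prints coverage at 0/1/5 TPM so the choice is
visible. Marker coexpression (e.g. *Scn10a*, *Trpv1*) is computed among
receptor-positive cells. The selection rule keeps mediators that are
significantly upregulated with coverage ≥ 0.10 — the boundary is kept-if-≥
because the exclusion being implemented is of receptors reaching only a
small subset (under 10%) of afferents. The mediator→receptor pairs are data,
not code: `inst/extdata/mediator_receptors.tsv` ships a panel of
gut-relevant secreted mediators and their canonical receptors as
configuration, and users supply their own TSV for other screens.

## Ca²⁺ imaging

Traces are normalised per ROI to
`(F − background − F₀)/(F_KClmax − F₀)`, where F₀ is the mean over the 10 s
before drug onset and F_KClmax the maximum during the KCl positive-control
window, so 0 is baseline and 1 the maximal depolarisation-evoked signal.
QC requires a KCl rise strictly above 5% of baseline and a stable baseline.
"Stable" is not defined by the conventions this follows, so it is made
explicit: |linear slope| × window ≤ 5% of F₀ and baseline CV ≤ 10%, both
configurable, with failure reasons logged per ROI. Responders must exceed
0.1 F/F_pos (strict) within a response window after drug onset; the window
defaults to 90 s — applications are tens of seconds and Ca²⁺ transients
decay over tens of seconds, so 90 s covers the transient without bleeding
into the next application — and is configurable because the evaluation span
is a protocol choice. Scale invariance (multiplying trace and background by
any k > 0 changes nothing) and noiseless exact recovery of planted truth are
property-tested.

## Afferent recording

The detector implements "count field potentials greater in magnitude than
twice the background noise". Two readings of that rule collide on raw
20 kHz traces: if "noise" means the RMS, a 2× threshold drowns in false
crossings (hundreds per second on white noise); if it means the visual
peak-to-peak band, small-but-real spikes become undetectable. The package
resolves this the way practical spike detection does: the trace is first
smoothed with a Gaussian kernel matched to the spike-lobe width (sd 0.15 ms
— a matched filter), and the threshold is then 2 × (4 × robust RMS of the
smoothed trace), i.e. twice a peak-to-peak noise proxy on the matched-filter
output. On white noise this yields essentially no false events (< 0.5/s is
asserted), while spikes of ~4.5–5× the raw noise RMS are detected with
F1 ≥ 0.95. Events are grouped with a 2 ms dead time and stamped at the
absolute smoothed peak; `threshold_uv` overrides the rule entirely, and a
noiseless record requires an explicit `noise_floor_uv`.

Rates are binned at 1 s and smoothed with a 60 s centred moving average
(rate-histogram display conventions in this field show smoothed traces
without stating parameters; these are the package's explicit defaults).
The drug effect is Δ = max smoothed rate within 600 s after onset minus the
mean over the 300 s before it. The max of a noisy estimate has a small
positive bias; at 5 Hz and 60 s smoothing it is bounded below 1 spike/s and
regression-tested. Concentration–response tables report n/mean/SEM per
concentration with an optional three-parameter Hill fit (off by default —
six points per concentration is meaningful for a summary, marginal for a
free slope).

Unit matching clusters 3 ms snippets, peak-aligned with parabolic
sub-sample interpolation (without it, sampling-phase jitter splits every
unit in two), by average-linkage agglomeration; clusters merge while the
smallest inter-template distance is below 1.5 × the pooled within-cluster
RMS. This is a deliberate, documented stand-in for proprietary
waveform-matching implementations whose algorithms are not published.
Distension responsiveness requires the supra-threshold (default
> 20 mm Hg) mean rate to exceed the sub-threshold rate by more than 2 SDs
of 1-s binned sub-threshold rates.

## Cell counting

Thresholds minimize the Kittler–Illingworth criterion
`J(t) = 1 + 2[P₁ln σ₁ + P₂ln σ₂] − 2[P₁ln P₁ + P₂ln P₂]` by exhaustive scan
over the 8-bit range, with a small variance floor (0.01) so single-level
classes stay finite, ties broken toward the lower level, and foreground
defined as value > t. Manual threshold adjustment — part of the original
imaging workflow — is inherently non-reproducible, so the automatic
threshold is authoritative and a `--threshold`-style override argument is
the only manual path. Binary masks are split by distance-transform
watershed (EBImage) and components under 30 px (configurable) are discarded
as debris. The neuron fraction is marker⁺ objects over nuclear⁺ objects,
reported per image, with a flag if segmentation error pushes it above 1.

## Assumption-gated comparisons

`compare_groups()` reproduces the test-selection contract used across
stages: Shapiro–Wilk per group and an F-test (two groups) or Bartlett test
(k groups) at a 0.05 gate (the gate level is itself a convention; it is
exposed as `alpha_gate`), then t / Welch / Mann–Whitney or
ANOVA + Bonferroni / Kruskal–Wallis + Dunn. Dunn's post-test is implemented
directly (rank-sum z statistics with tie correction, Bonferroni-adjusted).
Gates are applied per comparison. One-tailed alternatives are available for
the two-group branch.

## Synthetic data: what it emulates and what it does not

Every generator returns its ground truth alongside the data, and identical
arguments give bit-identical output (seeds are handled locally, not via the
caller's RNG state).

* **Bulk counts** — log-normal baseline means (meanlog = log 100, sdlog = 1),
  NB counts, uniform library depths in [0.8, 1.2] × 10⁶, planted log₂ fold
  changes drawn N(0, 2) truncated at |lfc| ≥ 0.5 so "true DE" is
  unambiguous, split half-up/half-down between groups.
* **Neuron matrix** — per-population Bernoulli positivity with log-normal
  TPM for positives; conditional rows give direct control of planted joint
  coexpression.
* **Traces** — difference-of-exponentials transients (rise 1 s, decay 8 s;
  transient shape is a modelling choice, as published traces are shown but
  never parameterised), Gaussian noise on the normalised scale, a planted
  dead fraction failing KCl QC, soma areas and reporter rates defaulting to
  nociceptor-like values (responders ≈ 437 µm² and 87% reporter⁺,
  non-responders ≈ 821 µm² and 77%).
* **Recordings** — biphasic difference-of-Gaussians templates (2 ms,
  dominant positive phase — the asymmetry is what real extracellular spikes
  look like and keeps peak alignment stable), Poisson event times with
  per-window rates, optional pressure channel modulating a distension rate,
  white Gaussian noise.
* **Micrographs** — disk cells with nuclei, well-separated foreground and
  background intensities, rejection-sampled placement (an error if packing
  is infeasible).

The noise models are Gaussian throughout — the simplest models satisfying
the stated detection thresholds. What passing tests therefore show is that
the *computations* are correct and calibrated under known generative
models; they do not show robustness to bleed-through, photobleaching,
electrode drift, movement artefacts, or overdispersion beyond NB, none of
which the generators emulate.

## Numerical choices and degenerate inputs

Dispersion optimisation runs on log φ over [1e-6, 4]; estimates at the grid
floor are reported as 0. Exact-test totals are rounded to integers; a zero
total gives p = 1. Fisher p-values are computed as hypergeometric tails and
verified against direct factorial summation to 1e-10 on all small tables.
The permutation z uses an sd floor of 1e-6 and returns 0 with a warning for
single-term libraries. Trace normalization refuses ROIs whose KCl maximum
does not exceed baseline (they fail QC by construction). Spike detection
errors on zero noise unless a floor is given. The watershed never merges
disjoint components; segmentation of an empty mask returns count 0 rather
than an error. All file interchange is plain text (TSV/CSV/GMT/PNG);
simulation scale in the tests (2000 genes, 500 ROIs, 60 s at 20 kHz) was
chosen so the full suite exercises the study-scale conditions in about half
a minute.

## Known limitations

Single-factor designs only (no covariates or batch terms); no read-level
processing (counts are the input contract); the enrichment z is a
Monte-Carlo approximation to a reference tool's precomputed expectation; no
nucleus–soma matching in cell counting; unit matching is a stand-in for
unpublished proprietary sorters; HDF5 containers are not read — CSV/TSV are
the interchange formats.
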