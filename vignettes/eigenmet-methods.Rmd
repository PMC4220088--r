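---
title: "Methods: simulation, chemometrics and annotation in eigenmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, chemometrics and annotation in eigenmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eigenmet` reconstructs a complete plasma ¹H-NMR fingerprinting analysis
for severe burn injury: a spectrum simulator with known ground truth, the
spectral preprocessing that turns raw traces into the 200-bin feature
matrix, PLS-DA with leave-one-out validation, VIP-based biomarker
selection, kernel-SVM classification of latent scores, and local
hypergeometric enrichment of the mapped enzyme genes. This vignette
documents the models, the tunable parameters, and the design decisions
taken where the analysis left genuine freedom.

## The synthetic cohort

No patient spectra from the original study are publicly available, so the
package treats the *study design* — 21 severe burn cases against 3 healthy
controls, CPMG spectra digitised into 32k points over a ≤ 20 ppm width —
as the reproducible object, and simulates plasma spectra under it.

Each resonance is a pure absorptive Lorentzian; a metabolite is a set of
resonances (`metabolite_signatures()`) with chemical shift (ppm), full
width at half maximum, and a relative area, the areas of one metabolite
summing to 1 so that concentration multiplies total signal linearly.
Signature content follows standard plasma spectral compilations,
restricted to each metabolite's *strongest resolved* resonances: minor
multiplets that sit beneath the glucose/creatinine envelope in real plasma
(e.g. the 3-methylhistidine N-CH₃ near 3.69 ppm or the 2-methoxyestrone
OCH₃ near 3.85 ppm) are deliberately omitted, for the same reason
practitioners identify metabolites on resolved peaks. Linewidths are
natural 600-MHz small-molecule widths (0.004–0.005 ppm ≈ 2.4–3 Hz);
modelling a whole multiplet as one broad Lorentzian envelope was rejected
because the Lorentzian's heavy tails would then spread unphysical signal
mass across neighbouring bins. Fine multiplet structure and J-coupling
are *not* modelled; one consequence is that simulated peaks are cleaner
and more isolated than real ones, so shift matching is somewhat easier
than on real spectra.

Per subject, metabolite concentrations are lognormal around the signature
baseline abundance — multiplied by the design's fold change in cases —
with a between-subject coefficient of variation (`concentration_cv`,
default 0.15, a typical clinical-chemistry spread). Default case effects
elevate α-ketoisovaleric acid, 3-methylhistidine, and the
hydroxybutyric/butyric species two-fold, the direction reported for the
early post-burn phase; magnitudes are free parameters of the design, not
data-derived quantities. On top of the resonances the simulator adds

* a slow baseline drift: a sinusoid of ⅓–⅔ of a cycle across the window
  plus a linear term, scaled by `baseline_amplitude` (default 2 intensity
  units). The drift is deliberately kept slow enough to live in the
  subspace a low-order polynomial correction can remove; a faster wiggle
  would model an artefact the prescribed correction cannot address;
* a residual water line at δ 4.70 (area `water_amplitude`, default 50);
  its width (0.005 ppm) is set so that the conventional excision window
  removes > 99% of the water integral, the property the preprocessing
  contract guarantees;
* a rigid chemical-shift translation per spectrum (`shift_jitter_sd`,
  default 0.01 ppm), emulating referencing error that preprocessing must
  undo;
* white noise (`noise_sd`, default 0.3 intensity units, giving peak
  signal-to-noise of roughly 40–600 across the signature table, in the
  range of 600-MHz CPMG plasma acquisitions).

Everything is drawn under one seed (`withr::local_seed`), making cohorts
bit-reproducible; the planted per-subject concentrations are returned as
ground truth.

What the simulator does **not** emulate: the dense forest of minor plasma
metabolites and lipoprotein humps ("chemical noise"), pH-dependent
per-metabolite shift wobble, phase errors, and multiplet structure.
Passing tests therefore demonstrate the correctness of the pipeline's
machinery under a clean, controlled signal model — not its field
performance on real plasma spectra, where peak overlap and chemical
background make both selection and matching harder.

## Preprocessing

**Baseline.** `correct_baseline()` estimates a slowly varying floor in
two stages. A polynomial of order `order` (default 2) is fitted by
trimmed L1 (median) regression: points more than `trim` (2.5)
floor-noise deviations above the curve — the resonances — are excluded,
and the fit is iterated to convergence, so peak height cannot lever the
drift estimate. The residual floor is then refined locally: the axis is
cut into `n_windows` (320) windows, each contributing a low-quantile
(0.15) support point computed over non-peak points only, and a smoothing
spline through the support points captures broad structure (such as
residual-water skirts) that no order-≤5 polynomial can represent. The
support quantile sits a fixed fraction of the noise scale below the floor
midline; because that offset is uniform along the axis and identical
across samples it is left uncorrected. Peak-insensitivity here is not
cosmetic: a baseline estimator that responds to total peak mass leaks
class information into peak-free regions of a case/control cohort and
corrupts every downstream correlation.

**Referencing.** The axis is translated so the maximum-intensity point in
the search window (default 2.95–3.15 ppm) lands on the creatinine N-CH₃
at δ 3.05. Ties take the lower-ppm point. The translation is recorded in
the `reference_shift` attribute.

**Water excision.** All points in the closed window 4.5–5.1 ppm are
dropped. Window and binned range (0.2–10 ppm) are conventional plasma
choices and both are configuration keys.

**Binning.** 200 uniform-width, half-open bins (last bin closed) are laid
over the *water-collapsed* axis, so the count over the retained range is
exactly 200 and no bin centre falls inside the excluded window; a bin
that straddles the gap is represented by its two ppm segments.
Integration is trapezoidal on the native grid, each inter-point panel
assigned to the bin containing its midpoint; panels bridging the excised
gap are discarded. A 24-sample cohort thus yields the 24 × 200 matrix
**X**, rows in input order.

**Scaling.** Unit-variance (auto) scaling is the default; Pareto
(centring and division by √sd) and centring-only are available, and the
method is refit inside every cross-validation fold to avoid leakage.
Unit variance gives every bin equal a-priori weight, which is the
conventional default when a fixed VIP threshold is interpreted across
studies; Pareto damps low-intensity bins and is preferable when trace
tail signal or noise bins would otherwise be amplified. Constant bins
are centred, divided by 1, and flagged rather than dropped. Spectra are
analysed non-normalised (no total-area or probabilistic-quotient step),
matching the upstream analysis this package reconstructs.

## PLS-DA, cross-validation and VIP

`pls_fit()` implements single-response NIPALS: weights **w**ₐ ∝
**E**ᵀ**f** (unit norm; with one response the fixed point is reached in a
single update, and a guard loop merely re-checks it), scores **t**ₐ =
**E w**ₐ, loadings **p**ₐ = **E**ᵀ**t**ₐ/**t**ₐᵀ**t**ₐ, response loading
bₐ, deflation of both **E** and **f**. Sign indeterminacy is removed by
making each weight vector's largest-magnitude entry positive. The
per-component model is collapsed to the regression vector **β** =
**W**(**P**ᵀ**W**)⁻¹**b**, whose predictions equal the component-wise
ones to numerical precision (a tested invariant), giving the discriminant
equation ŷ = ȳ + Σⱼ βⱼ xⱼ on scaled features. Class calls threshold ŷ at
0.5, the midpoint of the 0/1 coding (1 = burn). The centring/scaling
snapshot travels with the model, so prediction takes unscaled features.

Leave-one-out cross-validation refits scaling and model on every n−1
subset (no randomness): PRESS = Σ(yᵢ − ŷ₍₋ᵢ₎,ᵢ)², SSY the sum of squares
of *y* about its mean — making Q² = 1 − PRESS/SSY zero for the
mean predictor — R² = 1 − RSS/SSY, and SECV = √(PRESS/n) without a
degrees-of-freedom correction. The component count is chosen as the
smallest A whose Q² is within 0.01 of the maximum over 1…A_max (default
A_max = 5); the full per-A table is always reported.

VIP uses the explained-response-variance weighting,
VIPⱼ = √( p · Σₐ SSYₐ (wⱼₐ/‖wₐ‖)² / Σₐ SSYₐ ) with SSYₐ = bₐ²
**t**ₐᵀ**t**ₐ. This variant is stated explicitly because alternatives
differ in the bₐ² factor; it forces Σ VIP² = p, so VIP = 1 is the
all-equal reference and the selection rule VIP > 1.5 (strict) has a fixed
meaning regardless of bin count.

## SVM on latent scores

Classification happens on the first two PLS scores (matching the 2-D
score plots the discriminant analysis produces), with four kernels:
quadratic (u·v + 1)², polynomial (γ u·v + c₀)^d, Gaussian RBF
exp(−γ‖u−v‖²), and multilayer perceptron tanh(γ u·v + c₀). The
soft-margin dual is solved by libsvm (via `e1071`), deterministic for
fixed input, with C = 1 and γ = 1/k defaults; labels are recoded to ±1
internally and reported back as 0/1, with zero decision values mapped to
the burn class. The mlp kernel is indefinite; libsvm's SMO handles the
indefinite Gram directly (it does not require positive semidefiniteness),
so no Gram regularisation path is needed. An independent implementation
(`kernlab`) serves as a cross-check in the test suite, never as the
implementation.

## Annotation and enrichment

Bins with VIP strictly above 1.5 are matched against a packaged reference
peak table by chemical shift: a bin matches a metabolite when any
reference peak lies within 0.03 ppm (about one bin half-width) of the
bin's ppm **interval** — the interval rather than the centre, so peaks
near bin edges still match. One bin may match several metabolites; all
are reported and flagged ambiguous, and unmatched bins are kept visible
rather than dropped. Matched metabolites expand to enzyme-gene symbols
through a packaged metabolite→gene table (shipped verbatim as a versioned
fixture; 102 entries, 98 unique genes, four steroid-pathway genes shared
between deoxycorticosterone and aldosterone). Metabolites missing from
the map warn and are skipped; a metabolite mapped to no enzyme
contributes an empty set silently, which is a statement of the map, not
an error.

Enrichment is a local hypergeometric test: for each term, with N the
category's annotated universe, T the term size, Q the effective query
(query ∩ category universe — recomputed per category, which is why Q
differs between categories), and k the overlap, the upper tail
P[X ≥ k] comes from R's `phyper`. Ratios k/Q and k/T mirror the
conventional report columns; terms with k = 0 are omitted; rows sort by
ascending p with Benjamini–Hochberg adjustment per category reported
alongside the raw p. Published corrected p-values from web services with
unstated backgrounds are not reproducible and are not targets; only the
count arithmetic is. The pipeline's default annotation is a
deterministic synthetic generator (`synthetic_annotation()`, labelled
synthetic) because real GO memberships for the published terms cannot be
reconstructed from printed counts; `read_gmt()` accepts real annotations.

## Numerical choices and degenerate inputs

* Bin assignment is floor-based on the collapsed coordinate; the last bin
  is closed. Permuting input spectra permutes matrix rows identically.
* NIPALS stops with an informative error when no covariance remains
  (constant response, zero-variance deflated matrix); leave-one-out names
  the fold when holding out a sample leaves a constant training response.
* `scale_features("none")` still centres: centring is part of the model
  frame, only variance weighting is optional.
* Referencing requires at least one point in the search window; water
  excision refuses to drop the entire axis; binning refuses spectra
  narrower than the region.
* Seeds: one pipeline seed fans out to stage seeds by hashing the stage
  name (`stage_seed()`), all below 2³¹, so stages re-run in isolation
  reproduce their in-pipeline streams.

## Problem sizes used by the tests

Module tests run on reduced axes (2k–8k points) and small cohorts so the
suite stays fast; the acceptance tests run the full study geometry — 24
spectra at 32k points, 200 bins — once for the predictive-ability check
and ten times (seeds 1–10) for the marker-recovery experiment, which
plants a two-fold change on all twelve marker metabolites and asks
whether VIP selection plus shift matching returns exactly those twelve.

## Known limitations

* With only three controls, any single unlucky lognormal draw can pull a
  marker's class correlation — and hence its VIP — just below the
  selection threshold, and conversely a background metabolite (glucose,
  lactate, creatinine) can acquire a sizeable spurious correlation in a
  given cohort; the recovery experiment's per-seed outcome therefore
  fluctuates by ±1 metabolite around the planted twelve. This is a
  property of the study design being emulated, not of the estimator.
* The Lorentzian tail of a strong resonance carries real class signal
  into neighbouring bins; under unit-variance scaling those bins receive
  full weight, which spreads importance across more bins than the peak
  centres alone. Pareto scaling concentrates importance but promotes
  high-abundance background bins instead; both behaviours are inherent
  to the scaling definitions.
* The enrichment universe defaults to the annotation's own genes; with a
  genome-wide background the p-values would differ (the counts would
  not).
* The simulator's clean signal model overstates how crisp shift matching
  is on real plasma spectra.
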