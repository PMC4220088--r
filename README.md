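# eigenmet

Plasma ¹H-NMR metabolomics fingerprinting of severe burn injury, as a
tested, reproducible R pipeline.

Severe burn triggers massive catabolic rewiring — skeletal-muscle
breakdown, ketogenesis, mitochondrial transport dysfunction — that is
visible in the plasma small-molecule profile long before it is clinically
quantifiable. CPMG ¹H-NMR spectra of patient plasma, reduced to a
samples-by-bins matrix and modelled against case/control status, yield a
compact biomarker panel (an *Eigen-metabolome*) of the metabolites whose
resonances drive the discrimination. `eigenmet` implements that whole
analysis for a 21-case / 3-control burn study design, together with a
ground-truth spectrum simulator so every stage is testable without any
patient data (which were never deposited).

The pipeline:

1. **simulate** — Lorentzian plasma spectra (32k points) for burn cases and
   healthy controls, with per-subject lognormal concentration variation,
   planted case fold changes, baseline drift, chemical-shift jitter,
   additive noise and a residual water line at δ 4.70;
2. **preprocess** — robust low-quantile baseline correction, chemical-shift
   referencing to creatinine at δ 3.05, excision of the water region
   (4.5–5.1 ppm), and uniform integral binning into the 200-bin matrix
   **X** (24 × 200), followed by column scaling;
3. **fit** — PLS-DA by NIPALS: latent components **t**<sub>a</sub> = **X
   w**<sub>a</sub> maximising covariance with the class response *y* ∈
   {0, 1} (1 = burn), collapsed to a discriminant equation ŷ = a₀ + Σ
   aⱼxⱼ;
4. **validate** — leave-one-out cross-validation: PRESS = Σ(yᵢ −
   ŷ₍₋ᵢ₎)², Q² = 1 − PRESS/SSY, R² = 1 − RSS/SSY, SECV = √(PRESS/n),
   with Q² > 0.5 read as good predictive ability;
5. **classify** — soft-margin SVM on the first two latent scores with
   quadratic, polynomial, Gaussian RBF or multilayer-perceptron kernels;
6. **annotate** — VIP scores (Chong–Jun explained-variance weighting,
   Σ VIP² = p), selection of bins with VIP > 1.5, chemical-shift matching
   against a packaged reference peak table, and expansion of matched
   metabolites to their enzyme genes via a packaged metabolite→gene map;
7. **enrich** — local hypergeometric GO-style term enrichment of the gene
   set (T, Q, Q&T counts, Q&T/Q, Q&T/T ratios, upper-tail p,
   Benjamini–Hochberg per category).

## Worked example

```r
library(eigenmet)

run <- run_pipeline(pipeline_config(seed = 1))
run
#> <burn_run>
#>   cohort: 21 cases / 3 controls (seed 1)
#>   PLS-DA: A = 1, R2 = 0.907, Q2 = 0.582, SECV = 0.214
#>   SVM (rbf) training accuracy: 1.00
#>   Eigen-metabolome: 23 bins, 5 metabolites, 36 genes
#>   enrichment: 39 term(s) with overlap
```

Reading the output: with the default design (two-fold elevation of
α-ketoisovaleric acid, 3-methylhistidine, 2-hydroxybutyric acid and
butyric acid in cases), leave-one-out Q² = 0.58 exceeds the 0.5 bound for
a usefully predictive model while training R² = 0.91 shows the usual
optimism gap; the SVM separates the two classes perfectly in latent-score
space; and VIP > 1.5 selection recovers the planted markers (plus
ambiguity-flagged neighbours sharing bins with them) along with their 36
mapped enzyme genes.

Individual stages are ordinary functions over tibbles and compose with the
pipe:

```r
coh <- simulate_cohort(cohort_design(seed = 1))
fm  <- coh$spectra |> preprocess_spectra()
sel <- select_n_components(fm, coh$labels$class, max_components = 5)
fit <- pls_fit(fm, coh$labels$class, ncomp = sel$ncomp)
vip_scores(fit) |> select_eigen_bins(threshold = 1.5) |>
  match_bins_to_metabolites()
```

`autoplot()` methods draw PCA/PLS score plots, `plot_vip()` the VIP
profile, and `plot_decision_boundary()` the SVM separating line.

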