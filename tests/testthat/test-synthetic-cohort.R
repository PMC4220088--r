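test_that("lorentzian peak has the analytic shape and area", {
  ax <- axis_config(0, 10, 32768)
  tpl <- list(ppm = 3.05, fwhm = 0.01, relative_area = 1)

  # zero area -> flat zero
  expect_equal(lorentzian_peak(tpl, 0, ax), rep(0, 32768))

  # symmetry about the centre on a symmetric axis
  ax_sym <- axis_config(3.05 - 1, 3.05 + 1, 2049)
  y <- lorentzian_peak(tpl, 1, ax_sym)
  expect_equal(y, rev(y), tolerance = 1e-12)

  # maximum at the axis point nearest the centre, vector non-negative
  x <- axis_ppm(ax)
  y <- lorentzian_peak(tpl, 2.5, ax)
  expect_equal(which.max(y), which.min(abs(x - 3.05)))
  expect_true(all(y >= 0))

  # trapezoidal integral within 1% of the nominal area; frozen value
  # computed with a 10x-resolution quadrature oracle (327680 points),
  # which gives 0.99936 of the nominal area on [0, 10]
  o <- order(x)
  integral <- sum(0.5 * (y[o][-1] + y[o][-32768]) * diff(x[o]))
  expect_equal(integral, 2.5, tolerance = 0.01)
  ax10 <- axis_config(0, 10, 327680)
  x10 <- axis_ppm(ax10); y10 <- lorentzian_peak(tpl, 2.5, ax10)
  o10 <- order(x10)
  oracle <- sum(0.5 * (y10[o10][-1] + y10[o10][-327680]) * diff(x10[o10]))
  expect_equal(integral, oracle, tolerance = 1e-4)

  # centre outside the axis errors, naming the peak position
  expect_error(lorentzian_peak(list(ppm = 12, fwhm = 0.01, relative_area = 1), 1, ax),
               "12.0000")
})

test_that("render_spectrum is additive, deterministic and validates names", {
  sig <- toy_signatures()
  ax <- small_axis()

  # all-zero concentrations with all noise channels off -> flat zero
  conc0 <- c(Creatinine = 0, MarkerA = 0, MarkerB = 0)
  s0 <- render_spectrum(sig, conc0, ax)
  expect_equal(s0$intensity, rep(0, ax$n_points))
  expect_true(all(diff(s0$ppm) < 0))  # descending axis

  # doubling one metabolite doubles the intensity at its peak maximum
  s1 <- render_spectrum(sig, c(MarkerA = 1), ax)
  s2 <- render_spectrum(sig, c(MarkerA = 2), ax)
  i_max <- which.max(s1$intensity)
  expect_equal(s2$intensity[i_max], 2 * s1$intensity[i_max], tolerance = 1e-12)

  # fixed seed -> identical spectra, including noise and drift channels
  r1 <- render_spectrum(sig, c(MarkerA = 1, Creatinine = 2), ax,
                        noise_sd = 0.3, baseline_amplitude = 1,
                        water_amplitude = 10, seed = 99)
  r2 <- render_spectrum(sig, c(MarkerA = 1, Creatinine = 2), ax,
                        noise_sd = 0.3, baseline_amplitude = 1,
                        water_amplitude = 10, seed = 99)
  expect_identical(r1, r2)

  # unknown metabolite names are reported
  expect_error(render_spectrum(sig, c(Nonexistent = 1), ax), "Nonexistent")
})

test_that("simulate_cohort produces the designed cohort with ground truth", {
  coh <- toy_cohort(seed = 11)
  expect_length(unique(coh$spectra$sample_id), 10L)
  expect_equal(sum(coh$labels$class == 1L), 6L)
  expect_equal(sum(coh$labels$class == 0L), 4L)
  expect_equal(nrow(coh$concentrations), 10L * 3L)  # 3 metabolites

  # bit-reproducibility under an identical design and seed
  expect_identical(toy_cohort(seed = 11), coh)

  # the default design encodes the 21-case / 3-control study
  d <- cohort_design()
  expect_equal(d$n_case, 21L)
  expect_equal(d$n_control, 3L)

  # no cases -> all labels 0
  coh0 <- simulate_cohort(cohort_design(n_case = 0, n_control = 3,
                                        fold_changes = c(MarkerA = 2), seed = 1),
                          signatures = toy_signatures(), axis = small_axis())
  expect_true(all(coh0$labels$class == 0L))
})

test_that("null fold changes leave no class difference in the planted truth", {
  # oracle: two-sample comparison on true concentrations; with all fold
  # changes at 1 the per-metabolite difference should look null
  pvals <- vapply(1:50, function(s) {
    coh <- simulate_cohort(
      cohort_design(n_case = 6, n_control = 6, fold_changes = c(MarkerA = 1),
                    concentration_cv = 0.2, noise_sd = 0,
                    shift_jitter_sd = 0, baseline_amplitude = 0,
                    water_amplitude = 0, seed = s),
      signatures = toy_signatures(), axis = small_axis(1024))
    tr <- coh$concentrations[coh$concentrations$metabolite == "MarkerA", ]
    cls <- coh$labels$class[match(tr$sample_id, coh$labels$sample_id)]
    stats::t.test(log(tr$concentration) ~ cls)$p.value
  }, numeric(1))
  expect_gt(min(pvals), 0.01 / 50)   # no extreme rejection at alpha 0.01
  expect_gt(mean(pvals > 0.05), 0.8) # and mostly unremarkable
})

test_that("planted fold changes separate bin integrals over each marker peak", {
  coh <- toy_cohort(seed = 3, fold = 2, n_case = 8L, n_control = 6L)
  grid <- bin_grid()
  fm <- suppressWarnings(preprocess_spectra(coh$spectra, grid = grid))
  X <- as.matrix(fm[, -1])
  cls <- coh$labels$class
  centers <- attr(fm, "bin_centers")
  j <- which.min(abs(centers - 1.20))  # MarkerA peak bin
  p <- stats::t.test(X[cls == 1, j], X[cls == 0, j])$p.value
  expect_lt(p, 1e-3)
})
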