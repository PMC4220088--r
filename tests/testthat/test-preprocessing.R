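test_that("baseline correction removes drift and preserves clean spectra", {
  sig <- toy_signatures()
  ax <- small_axis(8192)

  # a pure straight line is removed exactly (order >= 1)
  x <- axis_ppm(ax)
  line <- tibble::tibble(sample_id = "l", ppm = x, intensity = 2 + 0.5 * x)
  out <- correct_baseline(line, order = 2)
  expect_lt(max(abs(out$intensity)), 1e-10)

  # baseline-free input (peaks on a zero floor) passes through
  clean <- render_spectrum(sig, c(MarkerA = 1, Creatinine = 2), ax)
  kept <- correct_baseline(clean)
  expect_lt(max(abs(kept$intensity - clean$intensity)), 0.02 * max(clean$intensity))

  # known quadratic drift: the recovered peak integral is within 2% of
  # the drift-free render (simulator oracle)
  drifted <- clean
  drifted$intensity <- drifted$intensity + 0.05 * (drifted$ppm - 5)^2 + 0.4
  corr <- correct_baseline(drifted, order = 2)
  intg <- function(s, lo, hi) {
    m <- s$ppm >= lo & s$ppm <= hi
    o <- order(s$ppm[m])
    sum(0.5 * (s$intensity[m][o][-1] + s$intensity[m][o][-sum(m)]) *
          diff(s$ppm[m][o]))
  }
  expect_equal(intg(corr, 1.1, 1.3), intg(clean, 1.1, 1.3), tolerance = 0.02)

  # peak apex position is unchanged
  expect_equal(which.max(corr$intensity), which.max(clean$intensity))

  # too few points for the requested order
  tiny <- tibble::tibble(sample_id = "t", ppm = c(2, 1), intensity = c(0, 0))
  expect_error(correct_baseline(tiny, order = 2), "fewer than")
})

test_that("creatinine referencing translates the axis onto 3.05 ppm", {
  sig <- toy_signatures()
  ax <- small_axis(8192)

  # already on target -> translation below one grid step
  step <- (ax$ppm_max - ax$ppm_min) / (ax$n_points - 1)
  s <- render_spectrum(sig, c(Creatinine = 2), ax)
  ref <- reference_to_creatinine(s)
  expect_lt(abs(unname(attr(ref, "reference_shift"))), step)

  # a known +0.02 ppm render jitter is undone (simulator oracle)
  j <- render_spectrum(sig, c(Creatinine = 2, MarkerA = 1), ax,
                       shift_jitter = 0.02)
  refj <- reference_to_creatinine(j)
  expect_lt(abs(unname(attr(refj, "reference_shift")) + 0.02), step)
  peak <- refj$ppm[which.max(refj$intensity * (refj$ppm > 2.9 & refj$ppm < 3.2))]
  expect_equal(peak, 3.05, tolerance = step)

  # two equal maxima: the lower-ppm one is the anchor
  flat <- tibble::tibble(sample_id = "f",
                         ppm = seq(3.3, 2.8, by = -0.01),
                         intensity = 0)
  flat$intensity[abs(flat$ppm - 3.10) < 1e-9 | abs(flat$ppm - 3.00) < 1e-9] <- 5
  reff <- reference_to_creatinine(flat)
  expect_equal(unname(attr(reff, "reference_shift")), 3.05 - 3.00)

  # empty search window errors
  expect_error(reference_to_creatinine(flat, window = c(5, 5.1)), "no points")
})

test_that("water excision drops exactly the closed window", {
  coh <- toy_cohort(seed = 5, n = 4096)
  cut <- excise_water(coh$spectra, c(4.5, 5.1))
  expect_false(any(cut$ppm >= 4.5 & cut$ppm <= 5.1))
  expect_equal(nrow(cut), sum(!(coh$spectra$ppm >= 4.5 & coh$spectra$ppm <= 5.1)))

  # empty window at an off-grid value is the identity
  same <- excise_water(coh$spectra, c(4.50001234, 4.50001234))
  expect_equal(same, coh$spectra)

  # excising everything is an error
  one <- coh$spectra[coh$spectra$sample_id == coh$spectra$sample_id[1], ]
  expect_error(excise_water(one, c(-1, 11)), "entire")

  # >= 99% of the rendered water integral is removed (water-free oracle)
  sig <- toy_signatures()
  ax <- small_axis(16384)
  wet <- render_spectrum(sig, c(MarkerA = 1), ax, water_amplitude = 50)
  dry <- render_spectrum(sig, c(MarkerA = 1), ax, water_amplitude = 0)
  intg <- function(s) {
    o <- order(s$ppm)
    dx <- diff(s$ppm[o])
    panel <- 0.5 * (s$intensity[o][-1] + s$intensity[o][-nrow(s)]) * dx
    sum(panel[dx < 3 * stats::median(dx)])  # never bridge the excised gap
  }
  water_total <- intg(wet) - intg(dry)
  water_kept <- intg(excise_water(wet)) - intg(excise_water(dry))
  expect_lt(water_kept / water_total, 0.01)
})

test_that("binning integrates half-open uniform bins over the retained range", {
  grid <- bin_grid()
  expect_equal(nrow(grid$bins), 200L)
  expect_true(all(diff(grid$bins$center) > 0))
  # no bin centre falls in the water window
  expect_false(any(grid$bins$center >= 4.5 & grid$bins$center <= 5.1))

  # constant intensity c -> each bin ~ c * bin width
  ax <- small_axis(16384)
  flat <- tibble::tibble(sample_id = "c", ppm = axis_ppm(ax), intensity = 3)
  v <- bin_spectrum(flat, grid)
  expect_equal(v$value, rep(3 * grid$width_u, 200), tolerance = 0.02)

  # one narrow peak wholly inside a bin: that bin holds the peak area
  # (quadrature oracle = lorentzian area), neighbours are ~ 0
  sig <- tibble::tibble(metabolite = "X", baseline_abundance = 1,
                        ppm = 2.155, fwhm = 0.003, relative_area = 1)
  pk <- render_spectrum(sig, c(X = 2), ax)
  vp <- bin_spectrum(pk, grid)
  j <- which.min(abs(vp$ppm - 2.155))
  expect_equal(vp$value[j], 2, tolerance = 0.05)
  expect_lt(max(vp$value[-j]), 0.05 * vp$value[j])

  # spectrum narrower than the region errors
  narrow <- tibble::tibble(sample_id = "n", ppm = seq(5, 1, length.out = 512),
                           intensity = 0)
  expect_error(bin_spectrum(narrow, grid), "narrower")
})

test_that("feature matrix assembly is shape- and order-stable", {
  coh <- toy_cohort(seed = 2, n_case = 3, n_control = 2, n = 4096)
  grid <- bin_grid()
  fm <- assemble_feature_matrix(coh$spectra, grid)
  expect_tibble(fm)
  expect_equal(dim(fm), c(5L, 201L))  # sample_id + 200 bins
  expect_equal(fm$sample_id, unique(coh$spectra$sample_id))

  one <- coh$spectra[coh$spectra$sample_id == fm$sample_id[1], ]
  fm1 <- assemble_feature_matrix(one, grid)
  expect_equal(dim(fm1), c(1L, 201L))

  # permuting input spectra permutes rows identically
  ids <- rev(unique(coh$spectra$sample_id))
  perm <- dplyr::arrange(coh$spectra, match(sample_id, ids))
  fmp <- assemble_feature_matrix(perm, grid)
  expect_equal(fmp$sample_id, ids)
  expect_equal(as.matrix(fmp[match(fm$sample_id, fmp$sample_id), -1]),
               as.matrix(fm[, -1]))
})

test_that("feature scaling matches its definitions and is idempotent", {
  f <- toy_features(n = 6, p = 3)
  fm <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(f$X)),
                         tibble::as_tibble(f$X))

  sc <- scale_features(fm, "unit-variance")
  M <- as.matrix(sc$features[, -1])
  expect_equal(unname(colMeans(M)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(M, 2, sd)), rep(1, 3), tolerance = 1e-9)

  # scaling an already unit-variance matrix changes nothing
  sc2 <- scale_features(sc$features, "unit-variance")
  expect_equal(as.matrix(sc2$features[, -1]), M, tolerance = 1e-9)

  # hand-computed pareto vs unit-variance on a 3 x 2 matrix
  h <- tibble::tibble(sample_id = c("a", "b", "c"),
                      b1 = c(1, 2, 3), b2 = c(10, 30, 20))
  uv <- as.matrix(scale_features(h, "unit-variance")$features[, -1])
  pa <- as.matrix(scale_features(h, "pareto")$features[, -1])
  expect_equal(unname(uv[, 1]), c(-1, 0, 1))
  expect_equal(unname(pa[, 1]), c(-1, 0, 1) / sqrt(1))
  expect_equal(unname(uv[, 2]), c(-10, 10, 0) / 10)
  expect_equal(unname(pa[, 2]), c(-10, 10, 0) / sqrt(10))

  # constant columns are kept, divided by one, and flagged
  k <- tibble::tibble(sample_id = c("a", "b", "c"), b1 = c(1, 2, 3), b2 = 7)
  sck <- scale_features(k, "unit-variance")
  expect_true(sck$scaling$constant[2])
  expect_equal(sck$scaling$divisor[2], 1)
  expect_equal(sck$features$b2, rep(0, 3))

  # centring-only mode and unknown methods
  n0 <- scale_features(h, "none")
  expect_equal(unname(colMeans(as.matrix(n0$features[, -1]))), c(0, 0))
  expect_error(scale_features(h, "zscore"))
})

test_that("referencing undoes a synthetic translation within one grid step", {
  coh <- toy_cohort(seed = 8, n_case = 2, n_control = 1, n = 8192)
  s <- coh$spectra[coh$spectra$sample_id == "case_01", ]
  step <- (small_axis(8192)$ppm_max - small_axis(8192)$ppm_min) / 8191
  for (t_shift in c(-0.03, 0.015)) {
    moved <- s
    moved$ppm <- moved$ppm + t_shift
    back <- reference_to_creatinine(correct_baseline(moved))
    orig <- reference_to_creatinine(correct_baseline(s))
    expect_equal(back$ppm, orig$ppm, tolerance = 1.5 * step)
  }
})
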