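#' Acquisition axis for simulated spectra
#'
#' Defines the chemical-shift axis spectra are rendered on. The spectral
#' width may not exceed 20 ppm and the default of 32768 points mirrors a
#' typical 32k acquisition. The default bounds extend half a ppm beyond
#' the binned region on each side so that referencing translations never
#' push the binned range off the axis. The axis is stored descending,
#' following NMR plotting convention.
#'
#' @param ppm_min,ppm_max Axis bounds in ppm (width at most 20 ppm).
#' @param n_points Number of points along the axis (at least 1024).
#' @return An `axis_config` object.
#' @export
#' @examples
#' ax <- axis_config()
#' head(axis_ppm(ax))
axis_config <- function(ppm_min = -0.5, ppm_max = 10.5, n_points = 32768L) {
  check_number(ppm_min, "ppm_min")
  check_number(ppm_max, "ppm_max")
  n_points <- check_count(n_points, "n_points", min = 1024L)
  if (ppm_max <= ppm_min) abort("`ppm_max` must exceed `ppm_min`.")
  if (ppm_max - ppm_min > 20) abort("spectral width must not exceed 20 ppm.")
  structure(list(ppm_min = ppm_min, ppm_max = ppm_max, n_points = n_points),
            class = "axis_config")
}

#' @rdname axis_config
#' @param axis An `axis_config`.
#' @export
axis_ppm <- function(axis) {
  stopifnot(inherits(axis, "axis_config"))
  seq(axis$ppm_max, axis$ppm_min, length.out = axis$n_points)
}

#' Evaluate one Lorentzian resonance on an axis
#'
#' The absorptive solution-NMR lineshape: a Lorentzian centred on the
#' template's chemical shift whose integral over an infinite axis equals
#' `area_scale * relative_area`.
#'
#' @param template A one-row data frame or named list with fields `ppm`
#'   (centre), `fwhm` and `relative_area`.
#' @param area_scale Total metabolite signal area (concentration units).
#' @param axis An [axis_config()].
#' @return Intensity vector aligned with `axis_ppm(axis)` (descending).
#' @export
#' @examples
#' ax <- axis_config(0, 10, 2048)
#' y <- lorentzian_peak(list(ppm = 3.05, fwhm = 0.01, relative_area = 1), 1, ax)
lorentzian_peak <- function(template, area_scale, axis) {
  template <- as.list(template)
  center <- check_number(template$ppm, "ppm")
  fwhm <- check_number(template$fwhm, "fwhm", min = 0, strict = TRUE)
  rel <- check_number(template$relative_area, "relative_area", min = 0, strict = TRUE)
  check_number(area_scale, "area_scale", min = 0)
  if (center < axis$ppm_min || center > axis$ppm_max) {
    abort(sprintf("peak at %.4f ppm lies outside the axis [%.4f, %.4f].",
                  center, axis$ppm_min, axis$ppm_max))
  }
  x <- axis_ppm(axis)
  hwhm <- fwhm / 2
  # area-normalised Lorentzian: A / pi * hwhm / ((x - x0)^2 + hwhm^2)
  (area_scale * rel / pi) * hwhm / ((x - center)^2 + hwhm^2)
}

#' Render one plasma spectrum from metabolite concentrations
#'
#' Sums one Lorentzian per signature resonance (area proportional to the
#' metabolite concentration), then adds a slow baseline drift (low-order
#' sinusoid plus linear term), a broad residual water resonance near
#' 4.70 ppm, a whole-spectrum chemical-shift translation emulating a
#' referencing error, and white noise. With a fixed seed the output is
#' bit-reproducible.
#'
#' @param signatures Signature table, see [metabolite_signatures()].
#' @param concentrations Named numeric vector of metabolite concentrations
#'   (arbitrary units); names must exist in `signatures`.
#' @param axis An [axis_config()].
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param baseline_amplitude Scale of the slow baseline drift.
#' @param water_amplitude Integrated area of the residual water signal.
#' @param shift_jitter Whole-spectrum translation in ppm.
#' @param sample_id Sample identifier for the output tibble.
#' @param seed Optional seed; when given the ambient RNG state is restored
#'   afterwards.
#' @return A spectra tibble (`sample_id`, `ppm` descending, `intensity`).
#' @export
render_spectrum <- function(signatures, concentrations, axis = axis_config(),
                            noise_sd = 0, baseline_amplitude = 0,
                            water_amplitude = 0, shift_jitter = 0,
                            sample_id = "s1", seed = NULL) {
  validate_signatures(signatures)
  unknown <- setdiff(names(concentrations), unique(signatures$metabolite))
  if (length(unknown)) {
    abort(paste0("concentrations name metabolites absent from the signatures: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  x <- axis_ppm(axis)
  intensity <- numeric(axis$n_points)
  for (i in seq_len(nrow(signatures))) {
    m <- signatures$metabolite[i]
    conc <- if (m %in% names(concentrations)) concentrations[[m]] else 0
    if (conc == 0) next
    tmpl <- list(ppm = signatures$ppm[i] + shift_jitter,
                 fwhm = signatures$fwhm[i],
                 relative_area = signatures$relative_area[i])
    intensity <- intensity + lorentzian_peak(tmpl, conc, axis)
  }
  if (baseline_amplitude > 0) {
    # slow drift: well under one cycle across the window, so it stays in
    # the subspace a low-order polynomial baseline correction removes
    period <- (axis$ppm_max - axis$ppm_min) * runif(1, 1.5, 3)
    phase <- runif(1, 0, 2 * pi)
    a1 <- runif(1, 0.5, 1)
    a2 <- runif(1, -0.5, 0.5)
    mid <- (axis$ppm_max + axis$ppm_min) / 2
    intensity <- intensity + baseline_amplitude *
      (a1 * sin(2 * pi * (x - mid) / period + phase) +
         a2 * (x - mid) / (axis$ppm_max - axis$ppm_min))
  }
  if (water_amplitude > 0) {
    # suppressed residual line: width chosen so the conventional excision
    # window keeps > 99% of the water integral out of the analysed
    # spectrum (the window is asymmetric about 4.70)
    water <- list(ppm = 4.70 + shift_jitter, fwhm = 0.005, relative_area = 1)
    intensity <- intensity + lorentzian_peak(water, water_amplitude, axis)
  }
  if (noise_sd > 0) intensity <- intensity + rnorm(axis$n_points, 0, noise_sd)
  tibble::tibble(sample_id = sample_id, ppm = x, intensity = intensity)
}

#' Cohort design for the burn-vs-control simulation
#'
#' Captures the study conditions the simulator emulates: 21 severe burn
#' cases against 3 healthy controls, class-dependent multiplicative
#' concentration effects on the burn-marker metabolites, lognormal
#' between-subject variation, additive noise, baseline drift, referencing
#' jitter and a residual water signal.
#'
#' @param n_case,n_control Group sizes (defaults 21 and 3).
#' @param fold_changes Named multiplicative case effects; metabolites not
#'   named keep fold 1. The default elevates alpha-ketoisovalerate,
#'   3-methylhistidine and the hydroxybutyric/butyric species two-fold,
#'   the direction reported for early severe burn.
#' @param concentration_cv Between-subject coefficient of variation.
#' @param noise_sd Additive spectral noise standard deviation.
#' @param shift_jitter_sd Per-spectrum referencing error SD in ppm.
#' @param baseline_amplitude Baseline drift scale.
#' @param water_amplitude Residual water signal area.
#' @param seed Random seed (simulation is bit-reproducible given the seed).
#' @return A `cohort_design` object.
#' @export
cohort_design <- function(n_case = 21L, n_control = 3L,
                          fold_changes = c("Alpha ketoisovaleric acid" = 2,
                                           "3-Methylhistidine" = 2,
                                           "2-Hydroxybutyric acid" = 2,
                                           "Butyric acid" = 2),
                          concentration_cv = 0.15, noise_sd = 0.3,
                          shift_jitter_sd = 0.01, baseline_amplitude = 2,
                          water_amplitude = 50, seed = 1L) {
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  if (length(fold_changes)) {
    if (is.null(names(fold_changes)) || any(names(fold_changes) == "")) {
      abort("`fold_changes` must be a named numeric vector.")
    }
    if (any(fold_changes <= 0)) abort("all `fold_changes` must be > 0.")
  }
  check_number(concentration_cv, "concentration_cv", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(shift_jitter_sd, "shift_jitter_sd", min = 0)
  check_number(baseline_amplitude, "baseline_amplitude", min = 0)
  check_number(water_amplitude, "water_amplitude", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_case = n_case, n_control = n_control,
                 fold_changes = fold_changes,
                 concentration_cv = concentration_cv, noise_sd = noise_sd,
                 shift_jitter_sd = shift_jitter_sd,
                 baseline_amplitude = baseline_amplitude,
                 water_amplitude = water_amplitude, seed = seed),
            class = "cohort_design")
}

#' Simulate a burn/control plasma NMR cohort with known ground truth
#'
#' Draws per-subject metabolite concentrations (lognormal around the
#' signature baseline abundance, multiplied by the design fold change in
#' cases), renders one spectrum per subject and retains the true
#' concentrations so downstream stages can be validated against the
#' planted signal. Class labels follow the convention 1 = burn,
#' 0 = healthy.
#'
#' @param design A [cohort_design()].
#' @param signatures Signature table, see [metabolite_signatures()].
#' @param axis An [axis_config()].
#' @return An `nmr_cohort`: list with `spectra` (long tibble), `labels`
#'   (tibble `sample_id`, `class`) and `concentrations` (long tibble of
#'   the planted per-subject truth).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_design(n_case = 2, n_control = 2, seed = 7),
#'                        axis = axis_config(0, 10, 2048))
#' coh$labels
simulate_cohort <- function(design = cohort_design(),
                            signatures = metabolite_signatures(),
                            axis = axis_config()) {
  stopifnot(inherits(design, "cohort_design"))
  validate_signatures(signatures)
  unknown <- setdiff(names(design$fold_changes), unique(signatures$metabolite))
  if (length(unknown)) {
    abort(paste0("fold_changes name metabolites absent from the signatures: ",
                 paste(unknown, collapse = ", ")))
  }
  withr::local_seed(design$seed)
  meta <- unique(signatures[, c("metabolite", "baseline_abundance")])
  n <- design$n_case + design$n_control
  ids <- c(sprintf("case_%02d", seq_len(design$n_case)),
           sprintf("ctrl_%02d", seq_len(design$n_control)))
  labels <- c(rep(1L, design$n_case), rep(0L, design$n_control))
  cv <- design$concentration_cv
  sdlog <- sqrt(log(1 + cv^2))
  spectra <- vector("list", n)
  conc_rows <- vector("list", n)
  for (i in seq_len(n)) {
    fold <- rep(1, nrow(meta))
    if (labels[i] == 1L && length(design$fold_changes)) {
      idx <- match(names(design$fold_changes), meta$metabolite)
      fold[idx] <- design$fold_changes
    }
    mu <- meta$baseline_abundance * fold
    conc <- if (cv > 0) {
      rlnorm(nrow(meta), meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    } else mu
    names(conc) <- meta$metabolite
    jitter <- if (design$shift_jitter_sd > 0) rnorm(1, 0, design$shift_jitter_sd) else 0
    spectra[[i]] <- render_spectrum(
      signatures, conc, axis,
      noise_sd = design$noise_sd,
      baseline_amplitude = design$baseline_amplitude,
      water_amplitude = design$water_amplitude,
      shift_jitter = jitter, sample_id = ids[i])
    conc_rows[[i]] <- tibble::tibble(sample_id = ids[i],
                                     metabolite = meta$metabolite,
                                     concentration = unname(conc),
                                     shift_jitter = jitter)
  }
  structure(list(spectra = dplyr::bind_rows(spectra),
                 labels = tibble::tibble(sample_id = ids, class = labels),
                 concentrations = dplyr::bind_rows(conc_rows),
                 design = design, axis = axis),
            class = "nmr_cohort")
}

#' @export
print.nmr_cohort <- function(x, ...) {
  cat(sprintf("<nmr_cohort> %d burn cases + %d controls, %d-point axis [%g, %g] ppm\n",
              sum(x$labels$class == 1L), sum(x$labels$class == 0L),
              x$axis$n_points, x$axis$ppm_min, x$axis$ppm_max))
  invisible(x)
}
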