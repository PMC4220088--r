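#' Subtract a slowly varying baseline from spectra
#'
#' Robust polynomial baseline estimation on the signal floor. Points
#' lying more than `trim` floor-noise deviations above the current curve
#' (the resonances) are excluded, and a polynomial of the given order is
#' fitted to the remaining low-quantile support points by iteratively
#' reweighted median (L1) regression; exclusion and fit are alternated
#' until stable. Because the fit sees only floor points, the estimate is
#' unbiased for the baseline and essentially independent of peak
#' content; peak apex positions and integrals are preserved, and a pure
#' straight-line baseline is removed exactly.
#'
#' @param spectra Spectra tibble (`sample_id`, `ppm`, `intensity`).
#' @param order Polynomial order of the parametric drift component,
#'   0 to 5.
#' @param trim Peak-rejection threshold in floor-noise standard
#'   deviations (default 2.5).
#' @param quantile Within-window support quantile for the local floor
#'   refinement (default 0.15).
#' @param n_windows Number of support windows for the local refinement;
#'   set to 0 to disable it and use the pure polynomial fit.
#' @param max_iter Maximum reweighting iterations.
#' @param tol Convergence tolerance relative to the signal spread.
#' @return Spectra tibble with the fitted baseline removed.
#' @export
correct_baseline <- function(spectra, order = 2L, trim = 2.5,
                             quantile = 0.15, n_windows = 320L,
                             max_iter = 50L, tol = 1e-9) {
  order <- check_count(order, "order")
  if (order > 5L) abort("`order` must be between 0 and 5.")
  check_number(trim, "trim", min = 0, strict = TRUE)
  check_number(quantile, "quantile", min = 0, strict = TRUE)
  if (quantile >= 1) abort("`quantile` must be in (0, 1).")
  n_windows <- check_count(n_windows, "n_windows")
  map_samples(spectra, function(s) {
    n <- nrow(s)
    if (n < order + 1L) {
      abort(sprintf("sample %s has %d points, fewer than order + 1 = %d.",
                    s$sample_id[1], n, order + 1L))
    }
    # orthogonal polynomial basis on a normalised axis for stability
    x <- (s$ppm - mean(s$ppm)) / (diff(range(s$ppm)) / 2)
    basis <- cbind(1, if (order > 0L) stats::poly(x, degree = order) else NULL)
    y <- s$intensity
    scale_ref <- max(sd(y), .Machine$double.eps)
    eps <- 1e-6 * scale_ref
    # stage 1: global polynomial drift by trimmed L1 (median) regression
    # on the signal floor, so peaks do not lever the fit
    fit <- drop(basis %*% solve(crossprod(basis), crossprod(basis, y)))
    for (it in seq_len(max_iter)) {
      r <- y - fit
      below <- r[r <= 0]
      sigma <- if (length(below)) max(1.4826 * stats::median(abs(below)), eps) else eps
      keep <- r <= trim * sigma
      w <- as.numeric(keep) / pmax(abs(r), eps)
      bw <- basis * w
      coef <- solve(crossprod(bw, basis), crossprod(bw, y))
      fit_new <- drop(basis %*% coef)
      delta <- max(abs(fit_new - fit))
      fit <- fit_new
      if (delta < tol * scale_ref) break
    }
    r <- y - fit
    # stage 2: local floor refinement - windowed low-quantile support
    # points of the residual, smoothed; follows broad structure (e.g.
    # residual water skirts) a low-order polynomial cannot represent,
    # without touching narrow resonances. Points flagged as resonance by
    # the stage-1 trim are excluded so peak area is not absorbed.
    nw <- min(n_windows, n %/% 8L)
    if (nw >= 8L) {
      o <- order(s$ppm)
      win <- cut(seq_len(n), breaks = nw, labels = FALSE)
      below <- r[r <= 0]
      sigma <- if (length(below)) max(1.4826 * stats::median(abs(below)), eps) else eps
      floor_pt <- r <= trim * sigma
      qfun <- function(v) if (length(v) >= 8L) stats::quantile(v, quantile, names = FALSE) else NA_real_
      sup_y <- as.numeric(tapply(ifelse(floor_pt[o], r[o], NA_real_), win,
                                 function(v) qfun(v[!is.na(v)])))
      sup_x <- tapply(s$ppm[o], win, mean)
      ok_sup <- !is.na(sup_y)
      sup_y <- sup_y[ok_sup]; sup_x <- sup_x[ok_sup]
      nw <- length(sup_y)
      if (nw >= 8L) {
        sm <- stats::smooth.spline(sup_x, sup_y,
                                   df = min(max(8, nw %/% 5L), nw - 1L))
        floor_local <- stats::predict(sm, s$ppm)$y
        # the support quantile sits a fixed fraction of the noise scale
        # below the floor midline; that offset is uniform along the axis
        # and identical across samples, so it is left alone rather than
        # re-estimated from the (peak-containing) signal
        fit <- fit + floor_local
      }
    }
    s$intensity <- y - fit
    s
  })
}

#' Reference chemical shifts to the creatinine peak at 3.05 ppm
#'
#' Translates each spectrum's axis so that the maximum-intensity point
#' inside the search window lands exactly on the target shift. If two
#' points tie, the lower-ppm one is used. The applied translation per
#' sample is recorded in the `reference_shift` attribute of the result.
#'
#' @param spectra Spectra tibble.
#' @param target Target chemical shift in ppm (default 3.05, creatinine).
#' @param window Search window in ppm (default `c(2.95, 3.15)`).
#' @return Spectra tibble with translated axes.
#' @export
reference_to_creatinine <- function(spectra, target = 3.05,
                                    window = c(2.95, 3.15)) {
  check_number(target, "target")
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be an increasing ppm interval of length 2.")
  }
  shifts <- c()
  out <- map_samples(spectra, function(s) {
    inside <- s$ppm >= window[1] & s$ppm <= window[2]
    if (!any(inside)) {
      abort(sprintf("sample %s has no points inside the search window [%g, %g].",
                    s$sample_id[1], window[1], window[2]))
    }
    cand <- s[inside, ]
    top <- cand[cand$intensity == max(cand$intensity), ]
    peak_ppm <- min(top$ppm)  # tie-break: lower ppm
    shift <- target - peak_ppm
    shifts[[s$sample_id[1]]] <<- shift
    s$ppm <- s$ppm + shift
    s
  })
  attr(out, "reference_shift") <- unlist(shifts)
  out
}

#' Remove the suppressed-water spectral region
#'
#' Drops every spectrum point (or feature-matrix column) whose chemical
#' shift lies inside the closed water window. Everything outside the
#' window is untouched.
#'
#' @param data Spectra tibble, or a feature tibble from
#'   [assemble_feature_matrix()].
#' @param window Closed ppm interval to excise (default `c(4.5, 5.1)`).
#' @return The same kind of object with the window removed.
#' @export
excise_water <- function(data, window = c(4.5, 5.1)) {
  if (length(window) != 2L || window[1] > window[2]) {
    abort("`window` must be a ppm interval with min <= max.")
  }
  if ("ppm" %in% names(data)) {
    keep <- !(data$ppm >= window[1] & data$ppm <= window[2])
    if (!any(keep)) abort("water window covers the entire spectral region.")
    tibble::as_tibble(data[keep, ])
  } else {
    centers <- attr(data, "bin_centers")
    if (is.null(centers)) abort("feature input must carry a `bin_centers` attribute.")
    drop <- centers >= window[1] & centers <= window[2]
    if (all(drop)) abort("water window covers the entire binned region.")
    value_cols <- setdiff(names(data), "sample_id")
    out <- data[, c("sample_id", value_cols[!drop])]
    attr(out, "bin_centers") <- centers[!drop]
    attr(out, "bin_grid") <- attr(data, "bin_grid")
    out
  }
}

#' Uniform integral bin grid with water-window exclusion
#'
#' Lays `n_bins` uniform-width, half-open bins over the binned region
#' after collapsing the excluded water window out of the axis, so the bin
#' count over the retained range is exact. Bin centres are reported in
#' ppm, ascending; a bin that straddles the water gap is represented by
#' its two ppm segments.
#'
#' @param region Binned range in ppm (default `c(0.2, 10)`).
#' @param n_bins Number of bins (default 200).
#' @param water_window Closed excluded interval in ppm (default
#'   `c(4.5, 5.1)`), or `NULL` for none.
#' @return A `bin_grid` object; its `bins` element is a tibble with the
#'   ppm segments (`lo1`,`hi1`,`lo2`,`hi2`) and centre of each bin.
#' @export
#' @examples
#' grid <- bin_grid()
#' nrow(grid$bins)
bin_grid <- function(region = c(0.2, 10), n_bins = 200L,
                     water_window = c(4.5, 5.1)) {
  if (length(region) != 2L || region[1] >= region[2]) {
    abort("`region` must be an increasing ppm interval of length 2.")
  }
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  gap <- 0
  if (!is.null(water_window)) {
    if (length(water_window) != 2L || water_window[1] > water_window[2]) {
      abort("`water_window` must be a ppm interval with min <= max.")
    }
    if (water_window[1] < region[1] || water_window[2] > region[2]) {
      abort("`water_window` must lie within `region`.")
    }
    gap <- water_window[2] - water_window[1]
  }
  # collapsed coordinate: u = ppm below the window, ppm - gap above it
  u_min <- region[1]
  u_max <- region[2] - gap
  edges_u <- seq(u_min, u_max, length.out = n_bins + 1L)
  width_u <- (u_max - u_min) / n_bins
  to_ppm <- function(u) {
    if (gap == 0) return(u)
    ifelse(u <= water_window[1], u, u + gap)
  }
  lo_u <- edges_u[-(n_bins + 1L)]
  hi_u <- edges_u[-1L]
  straddle <- gap > 0 & lo_u < water_window[1] & hi_u > water_window[1]
  bins <- tibble::tibble(
    bin = seq_len(n_bins),
    lo1 = to_ppm(lo_u),
    hi1 = ifelse(straddle, water_window[1], to_ppm(hi_u)),
    lo2 = ifelse(straddle, water_window[2], NA_real_),
    hi2 = ifelse(straddle, to_ppm(hi_u), NA_real_),
    center = to_ppm((lo_u + hi_u) / 2)
  )
  structure(list(region = region, n_bins = n_bins,
                 water_window = water_window, gap = gap,
                 edges_u = edges_u, width_u = width_u, bins = bins),
            class = "bin_grid")
}

# map ppm to the grid's collapsed coordinate (NA inside the water window)
grid_collapse <- function(grid, ppm) {
  if (grid$gap == 0) return(ppm)
  ww <- grid$water_window
  u <- ifelse(ppm < ww[1], ppm, ifelse(ppm > ww[2], ppm - grid$gap, NA_real_))
  u
}

#' Integrate one spectrum over a bin grid
#'
#' Trapezoidal integration on the native axis: each panel between
#' consecutive retained points is assigned to the bin containing its
#' midpoint (in the water-collapsed coordinate), so no panel spanning the
#' excised water gap contributes. Bins are half-open `[lo, hi)` with the
#' last bin closed.
#'
#' @param spectrum Single-sample spectra tibble.
#' @param grid A [bin_grid()].
#' @return Tibble with `bin`, `ppm` (bin centre) and `value` (integral).
#' @export
bin_spectrum <- function(spectrum, grid = bin_grid()) {
  stopifnot(inherits(grid, "bin_grid"))
  s <- as_spectra(spectrum)
  if (length(unique(s$sample_id)) != 1L) {
    abort("`bin_spectrum` takes a single spectrum; use `assemble_feature_matrix` for cohorts.")
  }
  eps <- 1e-9
  if (min(s$ppm) > grid$region[1] + eps || max(s$ppm) < grid$region[2] - eps) {
    abort(sprintf("sample %s covers [%.3f, %.3f] ppm, narrower than the binned region [%.3f, %.3f].",
                  s$sample_id[1], min(s$ppm), max(s$ppm),
                  grid$region[1], grid$region[2]))
  }
  o <- order(s$ppm)
  x <- s$ppm[o]
  y <- s$intensity[o]
  u <- grid_collapse(grid, x)
  keep <- !is.na(u)
  x <- x[keep]; y <- y[keep]; u <- u[keep]
  np <- length(x)
  if (np < 2L) abort("too few retained points to integrate.")
  dx <- diff(x)
  panel_area <- 0.5 * (y[-np] + y[-1L]) * dx
  panel_mid_u <- (u[-np] + u[-1L]) / 2
  # drop panels bridging the water gap (their ppm step spans the window)
  gap_panel <- diff(u) < dx - 1e-12
  idx <- floor((panel_mid_u - grid$edges_u[1]) / grid$width_u) + 1
  ok <- !gap_panel & idx >= 1 & idx <= grid$n_bins
  vals <- numeric(grid$n_bins)
  acc <- tapply(panel_area[ok], idx[ok], sum)
  vals[as.integer(names(acc))] <- acc
  tibble::tibble(bin = grid$bins$bin, ppm = grid$bins$center, value = vals)
}

#' Assemble the samples-by-bins feature matrix
#'
#' Bins every spectrum of a cohort on a common grid and stacks the
#' integral vectors into the feature matrix X (rows = samples in input
#' order, columns = bins ascending by ppm centre). With the default grid
#' a 24-sample cohort yields a 24 x 200 matrix.
#'
#' @param spectra Spectra tibble covering several samples (already
#'   referenced and water-excised).
#' @param grid A [bin_grid()].
#' @return A feature tibble: `sample_id` plus one numeric column per bin
#'   (named `ppm_<centre>`), with `bin_centers` and `bin_grid` attributes.
#' @export
assemble_feature_matrix <- function(spectra, grid = bin_grid()) {
  spectra <- as_spectra(spectra)
  ids <- unique(spectra$sample_id)
  rows <- lapply(ids, function(id) {
    s <- spectra[spectra$sample_id == id, ]
    tryCatch(bin_spectrum(s, grid)$value,
             error = function(e) abort(sprintf("sample %s: %s", id, conditionMessage(e))))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- sprintf("ppm_%.4f", grid$bins$center)
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                          tibble::as_tibble(mat))
  attr(out, "bin_centers") <- grid$bins$center
  attr(out, "bin_grid") <- grid
  out
}

# numeric matrix view of a feature tibble (rownames = sample ids)
fm_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  stopifnot(is.data.frame(features))
  cols <- setdiff(names(features), "sample_id")
  m <- as.matrix(features[, cols, drop = FALSE])
  if ("sample_id" %in% names(features)) rownames(m) <- features$sample_id
  storage.mode(m) <- "double"
  m
}

fm_rebuild <- function(mat, template) {
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  out <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                          tibble::as_tibble(mat, .name_repair = "minimal"))
  attr(out, "bin_centers") <- attr(template, "bin_centers")
  attr(out, "bin_grid") <- attr(template, "bin_grid")
  out
}

#' Column scaling of a feature matrix
#'
#' Centres every bin and divides by its standard deviation
#' (`unit-variance`, the default), by the square root of the standard
#' deviation (`pareto`), or centres only (`none`). Scaling keeps small
#' resonances from being overshadowed by large ones in the multivariate
#' models. Constant bins are centred but divided by 1 and flagged rather
#' than dropped.
#'
#' @param features Feature tibble from [assemble_feature_matrix()].
#' @param method One of `"unit-variance"` (alias `"uv"`), `"pareto"`,
#'   `"none"`.
#' @return A list with `features` (scaled tibble) and `scaling` (tibble of
#'   per-bin centres, divisors and constant-column flags).
#' @export
scale_features <- function(features, method = c("unit-variance", "uv", "pareto", "none")) {
  method <- match.arg(method)
  if (method == "uv") method <- "unit-variance"
  X <- fm_matrix(features)
  if (method != "none" && nrow(X) < 2L) {
    abort("variance-based scaling needs at least 2 samples.")
  }
  if (method == "none") {
    # "none" still centres columns: centring is part of the model frame,
    # only the variance weighting is switched off
    centers <- colMeans(X); divisors <- rep(1, ncol(X)); constant <- rep(FALSE, ncol(X))
    Xs <- sweep(X, 2, centers, "-")
  } else {
    centers <- colMeans(X)
    sds <- apply(X, 2, sd)
    constant <- sds < .Machine$double.eps^0.5
    divisors <- ifelse(constant, 1,
                       if (method == "unit-variance") sds else sqrt(sds))
    Xs <- sweep(sweep(X, 2, centers, "-"), 2, divisors, "/")
  }
  scaling <- tibble::tibble(column = colnames(X), center = unname(centers),
                            divisor = unname(divisors), constant = unname(constant),
                            method = method)
  list(features = fm_rebuild(Xs, features), scaling = scaling)
}

apply_scaling <- function(X, scaling) {
  X <- fm_matrix(X)
  if (!is.null(scaling$column) && !is.null(colnames(X))) {
    if (!identical(colnames(X), scaling$column)) {
      abort("feature columns do not match the scaling snapshot.")
    }
  }
  sweep(sweep(X, 2, scaling$center, "-"), 2, scaling$divisor, "/")
}

#' One-call preprocessing of a cohort of raw spectra
#'
#' Baseline correction, creatinine referencing, water excision and
#' binning, in the order the processing pipeline applies them.
#'
#' @param spectra Raw spectra tibble.
#' @param baseline_order Polynomial order for [correct_baseline()].
#' @param reference_window Search window for [reference_to_creatinine()].
#' @param water_window Excised interval, also used by the grid.
#' @param grid A [bin_grid()]; its water window should match.
#' @return A feature tibble (unscaled); referencing shifts are carried in
#'   the `reference_shift` attribute.
#' @export
preprocess_spectra <- function(spectra, baseline_order = 2L,
                               reference_window = c(2.95, 3.15),
                               water_window = c(4.5, 5.1),
                               grid = bin_grid(water_window = water_window)) {
  s <- correct_baseline(spectra, order = baseline_order)
  s <- reference_to_creatinine(s, window = reference_window)
  shifts <- attr(s, "reference_shift")
  s <- excise_water(s, window = water_window)
  features <- assemble_feature_matrix(s, grid)
  attr(features, "reference_shift") <- shifts
  features
}
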