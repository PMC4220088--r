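#' Cross-validation fit statistics
#'
#' The summary statistics of a leave-one-out run: `Q2 = 1 - PRESS/SSY`
#' (SSY is the sum of squares of the response about its mean, so Q2 = 0
#' is the mean-predictor baseline), `R2 = 1 - RSS/SSY` for the training
#' residuals, and `SECV = sqrt(PRESS/n)` with no degrees-of-freedom
#' correction.
#'
#' @param press Predictive residual sum of squares.
#' @param ssy Total sum of squares of y about its mean (must be > 0).
#' @param residual_ss Training residual sum of squares (optional; `r2` is
#'   `NA` when missing).
#' @param n Number of observations.
#' @return One-row tibble with `q2`, `r2`, `secv`.
#' @export
#' @examples
#' fit_statistics(press = 1.2, ssy = 4.8, residual_ss = 0.6, n = 12)
fit_statistics <- function(press, ssy, residual_ss = NULL, n) {
  check_number(press, "press", min = 0)
  check_number(ssy, "ssy")
  if (ssy <= 0) abort("`ssy` must be > 0 (degenerate constant response).")
  n <- check_count(n, "n", min = 1L)
  r2 <- if (is.null(residual_ss)) NA_real_ else {
    check_number(residual_ss, "residual_ss", min = 0)
    1 - residual_ss / ssy
  }
  tibble::tibble(q2 = 1 - press / ssy, r2 = r2, secv = sqrt(press / n))
}

# LOO predictions for components 1..ncomp in one pass per fold.
# Scaling is refit on every n-1 training remainder (no leakage).
loo_predictions <- function(X, y, ncomp, scaling) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, ncomp)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      abort(sprintf("leave-one-out fold %d leaves a constant training response.", i))
    }
    sc <- scale_features(X[-i, , drop = FALSE], scaling)
    Xs <- fm_matrix(sc$features)
    y_mean <- mean(ytr)
    core <- pls_core(Xs, ytr - y_mean, ncomp)
    xs_new <- apply_scaling(X[i, , drop = FALSE], sc$scaling)
    preds[i, ] <- y_mean + drop(xs_new %*% core$coefficients_per_a)
  }
  preds
}

#' Leave-one-out cross-validation of a PLS-DA model
#'
#' Each sample is held out once; scaling and the PLS fit are recomputed
#' on the remaining n - 1 samples and the held-out sample is predicted.
#' PRESS accumulates the squared prediction errors; Q2, R2 and SECV
#' follow [fit_statistics()]. The procedure contains no randomness.
#'
#' @param features Unscaled feature tibble or matrix.
#' @param y 0/1 class response.
#' @param ncomp Number of latent components.
#' @param scaling Scaling method, refit inside every fold.
#' @return A `cv_result` with `press`, `ssy`, `q2`, `r2`, `secv`, `sd_x`
#'   (pooled SD of the scaled training matrix), `n_components`, `n`, and
#'   the per-sample out-of-fold `predictions`.
#' @export
loo_cross_validate <- function(features, y, ncomp = 2L,
                               scaling = "unit-variance") {
  X <- fm_matrix(features)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) abort("leave-one-out needs at least 3 samples.")
  if (length(unique(y)) < 2L) abort("both classes required: `y` is constant.")
  ncomp <- check_count(ncomp, "ncomp", min = 1L)
  preds <- loo_predictions(X, y, ncomp, scaling)[, ncomp]
  press <- sum((y - preds)^2)
  ssy <- sum((y - mean(y))^2)
  full <- pls_fit(features, y, ncomp = ncomp, scaling = scaling)
  rss <- sum((y - full$fitted)^2)
  stats <- fit_statistics(press, ssy, rss, n)
  Xs <- fm_matrix(scale_features(features, scaling)$features)
  structure(list(
    press = press, ssy = ssy, q2 = stats$q2, r2 = stats$r2,
    secv = stats$secv, sd_x = sd(as.vector(Xs)),
    n_components = ncomp, n = n, scaling = scaling,
    predictions = tibble::tibble(
      sample_id = rownames(X) %||% as.character(seq_len(n)),
      y = y, y_cv = preds)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> A = %d: R2 = %.3f, Q2 = %.3f, SECV = %.3f (n = %d)\n",
              x$n_components, x$r2, x$q2, x$secv, x$n))
  invisible(x)
}

#' Choose the number of PLS components by leave-one-out Q2
#'
#' Runs leave-one-out cross-validation for every component count from 1
#' to `max_components` and returns the smallest count whose Q2 comes
#' within 0.01 of the maximum, along with the full per-A table.
#'
#' @param features Unscaled feature tibble or matrix.
#' @param y 0/1 class response.
#' @param max_components Largest component count to consider.
#' @param scaling Scaling method.
#' @return A `component_selection`: list with `ncomp` (chosen) and
#'   `table` (tibble of A, PRESS, Q2, R2, SECV for every A).
#' @export
select_n_components <- function(features, y, max_components = 5L,
                                scaling = "unit-variance") {
  X <- fm_matrix(features)
  y <- as.numeric(y)
  max_components <- check_count(max_components, "max_components", min = 1L)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (max_components > kmax) {
    abort(sprintf("`max_components` = %d exceeds min(n - 1, bins) = %d.",
                  max_components, kmax))
  }
  if (length(unique(y)) < 2L) abort("both classes required: `y` is constant.")
  preds <- loo_predictions(X, y, max_components, scaling)
  ssy <- sum((y - mean(y))^2)
  full <- pls_fit(features, y, ncomp = max_components, scaling = scaling)
  Xs_full <- apply_scaling(X, full$scaling)
  tab <- purrr::map_dfr(seq_len(max_components), function(a) {
    press <- sum((y - preds[, a])^2)
    fit_a <- full$intercept + drop(Xs_full %*% full$coefficients_per_a[, a])
    st <- fit_statistics(press, ssy, sum((y - fit_a)^2), length(y))
    tibble::tibble(A = a, press = press, q2 = st$q2, r2 = st$r2, secv = st$secv)
  })
  best <- max(tab$q2)
  chosen <- min(tab$A[tab$q2 >= best - 0.01])
  structure(list(ncomp = chosen, table = tab), class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> chosen A = %d\n", x$ncomp))
  print(x$table)
  invisible(x)
}
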