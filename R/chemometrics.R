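#' Principal component analysis of a scaled feature matrix
#'
#' Computed by singular value decomposition of the supplied matrix:
#' loadings are right singular vectors, scores are their projections, and
#' explained variance fractions are squared singular values over their
#' total. The input is expected to be centred (and usually scaled); no
#' internal centring is applied so that `scores = X %*% loadings` holds
#' exactly. Each loading's largest-magnitude entry is made positive to
#' remove sign indeterminacy.
#'
#' @param features Scaled feature tibble or numeric matrix.
#' @param k Number of components (at most `min(n - 1, p)`).
#' @return A `pca_model` with `loadings`, `scores` (tibble) and
#'   `explained_variance`.
#' @export
pca_fit <- function(features, k = 2L) {
  X <- fm_matrix(features)
  k <- check_count(k, "k", min = 1L)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax) abort(sprintf("`k` = %d exceeds min(samples - 1, bins) = %d.", k, kmax))
  dec <- svd(X)
  flip <- vapply(seq_len(k), function(a) {
    v <- dec$v[, a]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(dec$v[, seq_len(k), drop = FALSE], 2, flip, "*")
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  scores <- X %*% loadings
  ev <- dec$d^2 / sum(dec$d^2)
  structure(list(
    loadings = loadings,
    scores = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(X) %||% as.character(seq_len(nrow(X)))),
      tibble::as_tibble(scores)),
    explained_variance = ev[seq_len(k)],
    k = k), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d component(s); explained variance: %s\n", x$k,
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}

# NIPALS partial least squares, single response, on a centred/scaled matrix.
# For one response the weight update is closed-form, so each component
# converges in a single pass; the iteration guard is retained for safety.
pls_core <- function(Xs, yc, ncomp, tol = 1e-12, max_iter = 500L) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  b <- numeric(ncomp)
  tt <- numeric(ncomp)
  E <- Xs
  f <- yc
  for (a in seq_len(ncomp)) {
    # with one response the NIPALS fixed point is reached in a single
    # update (w proportional to E'f); the guard loop only re-checks it
    w <- drop(crossprod(E, f))
    for (iter in seq_len(max_iter)) {
      w_new <- drop(crossprod(E, f))
      if (sqrt(sum((w_new - w)^2)) <= tol) break
      w <- w_new
    }
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) {
      abort(sprintf("component %d: no covariance left between X and y.", a))
    }
    w <- w / nw
    if (w[which.max(abs(w))] < 0) w <- -w  # sign convention
    t_a <- drop(E %*% w)
    tt_a <- sum(t_a^2)
    if (tt_a < .Machine$double.eps) {
      abort(sprintf("component %d: degenerate score vector.", a))
    }
    p_a <- drop(crossprod(E, t_a)) / tt_a
    b_a <- sum(f * t_a) / tt_a
    E <- E - tcrossprod(t_a, p_a)
    f <- f - b_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; b[a] <- b_a; tt[a] <- tt_a
  }
  # collapsed regression vector: X W (P'W)^-1 b reproduces sum_a b_a t_a
  R <- W %*% solve(crossprod(P, W))
  coef_per_a <- vapply(seq_len(ncomp), function(a) {
    drop(R[, seq_len(a), drop = FALSE] %*% b[seq_len(a)])
  }, numeric(p))
  coef_per_a <- matrix(coef_per_a, nrow = p, ncol = ncomp)
  list(weights = W, x_loadings = P, x_scores = Tm, y_loadings = b, tt = tt,
       coefficients = coef_per_a[, ncomp], coefficients_per_a = coef_per_a)
}

#' Fit a PLS-DA model by NIPALS
#'
#' Partial least squares regression of a 0/1 class response on a binned
#' spectral matrix, computed component-by-component by NIPALS with
#' deflation. The model keeps the per-component weights, scores and
#' loadings as well as the collapsed coefficient vector of the
#' discriminant equation, plus the centring/scaling snapshot so new
#' samples can be predicted from unscaled features.
#'
#' @param features Unscaled feature tibble (or matrix); the requested
#'   scaling is applied internally and remembered.
#' @param y Numeric response, 1 = burn and 0 = healthy.
#' @param ncomp Number of latent components (at most `min(n - 1, p)`).
#' @param scaling Scaling method passed to [scale_features()].
#' @return A `pls_model`.
#' @export
#' @examples
#' X <- tibble::tibble(sample_id = letters[1:6],
#'                     b1 = c(1, 2, 3, 7, 8, 9) + 0.1 * (1:6),
#'                     b2 = rnorm(6))
#' m <- pls_fit(X, c(0, 0, 0, 1, 1, 1), ncomp = 1)
#' predict(m, X)
pls_fit <- function(features, y, ncomp = 2L, scaling = "unit-variance") {
  X <- fm_matrix(features)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) abort("`y` must have one value per sample.")
  if (length(unique(y)) < 2L) abort("both classes required: `y` is constant.")
  ncomp <- check_count(ncomp, "ncomp", min = 1L)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (ncomp > kmax) abort(sprintf("`ncomp` = %d exceeds min(samples - 1, bins) = %d.", ncomp, kmax))
  sc <- scale_features(features, scaling)
  Xs <- fm_matrix(sc$features)
  y_mean <- mean(y)
  core <- pls_core(Xs, y - y_mean, ncomp)
  fitted <- y_mean + drop(Xs %*% core$coefficients)
  structure(list(
    n_components = ncomp,
    weights = `dimnames<-`(core$weights, list(colnames(X), NULL)),
    x_scores = core$x_scores,
    x_loadings = core$x_loadings,
    y_loadings = core$y_loadings,
    score_ss = core$tt,
    coefficients = setNames(core$coefficients, colnames(X)),
    coefficients_per_a = core$coefficients_per_a,
    intercept = y_mean,
    scaling = sc$scaling,
    y = y,
    fitted = fitted,
    sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    bin_centers = attr(features, "bin_centers")
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  r2 <- 1 - sum((x$y - x$fitted)^2) / sum((x$y - mean(x$y))^2)
  cat(sprintf("<pls_model> %d component(s), %d bins, training R2 = %.3f\n",
              x$n_components, length(x$coefficients), r2))
  invisible(x)
}

#' Predict the class response from a fitted PLS-DA model
#'
#' Applies the model's stored centring/scaling to the supplied unscaled
#' features and evaluates the collapsed discriminant equation
#' `yhat = intercept + sum_j a_j x_j`. Class calls use the 0.5 midpoint of
#' the 0/1 coding: `yhat >= 0.5` is called burn (1).
#'
#' @param object A `pls_model`.
#' @param newdata Feature tibble or matrix with the training columns.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `response` and `class`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- fm_matrix(newdata)
  if (ncol(X) != length(object$coefficients)) {
    abort(sprintf("newdata has %d bins but the model was fitted on %d.",
                  ncol(X), length(object$coefficients)))
  }
  Xs <- apply_scaling(X, object$scaling)
  yhat <- object$intercept + drop(Xs %*% object$coefficients)
  tibble::tibble(
    sample_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    response = yhat,
    class = as.integer(yhat >= 0.5))
}

#' @rdname predict.pls_model
#' @param model A `pls_model`.
#' @export
pls_predict <- function(model, newdata) predict(model, newdata)

#' Variable importance in the projection (VIP)
#'
#' Per-bin VIP scores under the explained-response-variance weighting:
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with
#' `SSY_a = b_a^2 * t_a't_a` and unit-norm weight vectors, so the squared
#' scores always average to 1 across bins.
#'
#' @param model A fitted `pls_model`.
#' @return Tibble with `bin`, `column`, `ppm` (bin centre when known) and
#'   `vip`, in bin order.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$y_loadings^2 * model$score_ss
  if (sum(ssy) <= 0) abort("model explains no response variance; VIP undefined.")
  W <- model$weights
  p <- nrow(W)
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  tibble::tibble(
    bin = seq_len(p),
    column = rownames(W) %||% as.character(seq_len(p)),
    ppm = if (!is.null(model$bin_centers)) model$bin_centers else NA_real_,
    vip = unname(vip))
}
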