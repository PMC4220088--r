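test_that("PCA matches the SVD and recovers low-rank structure", {
  # rank-1 matrix: first component explains essentially all variance
  withr::with_seed(1, {
    u <- rnorm(6); v <- rnorm(4)
  })
  X1 <- tcrossprod(u, v)
  colnames(X1) <- paste0("b", 1:4)
  p1 <- pca_fit(X1, k = 2)
  expect_gt(p1$explained_variance[1], 0.999)

  # k = min dimension reconstructs X within 1e-8
  withr::with_seed(2, X <- matrix(rnorm(24), 6, 4))
  X <- scale(X, scale = FALSE)
  colnames(X) <- paste0("b", 1:4)
  pf <- pca_fit(X, k = 4)
  S <- as.matrix(pf$scores[, -1])
  expect_equal(S %*% t(pf$loadings), unclass(X), tolerance = 1e-8,
               ignore_attr = TRUE)

  # scores equal the SVD oracle (prcomp) up to column sign
  withr::with_seed(3, H <- matrix(rnorm(15), 5, 3))
  H <- scale(H, scale = FALSE); colnames(H) <- paste0("b", 1:3)
  ph <- pca_fit(H, k = 3)
  oracle <- stats::prcomp(H, center = FALSE)
  for (a in 1:3) {
    s_mine <- as.matrix(ph$scores[, -1])[, a]
    s_ref <- oracle$x[, a]
    expect_equal(abs(s_mine), abs(s_ref), tolerance = 1e-8, ignore_attr = TRUE)
  }

  # loadings orthonormal; explained variance non-increasing and <= 1
  G <- crossprod(ph$loadings)
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(ph$explained_variance) <= 1e-12))
  expect_lte(sum(ph$explained_variance), 1 + 1e-12)

  expect_error(pca_fit(X, k = 6), "exceeds")
})

test_that("NIPALS PLS recovers an exactly informative column", {
  # X column 1 equals y, other columns are zero after centring
  y <- c(0, 0, 0, 1, 1, 1)
  X <- cbind(b1 = y, b2 = rep(1, 6), b3 = rep(2, 6))
  m <- pls_fit(X, y, ncomp = 1, scaling = "none")
  expect_lt(sum((m$y - m$fitted)^2), 1e-20)
  expect_gt(abs(m$coefficients[1]), 1e-3)
  expect_equal(unname(abs(m$coefficients[2:3])), c(0, 0), tolerance = 1e-12)

  # one-component weights are proportional to the X'y covariance
  f <- toy_features(n = 10, p = 5, seed = 9)
  m1 <- pls_fit(f$X, f$y, ncomp = 1, scaling = "none")
  Xc <- scale(f$X, scale = FALSE)
  covxy <- drop(crossprod(Xc, f$y - mean(f$y)))
  expect_equal(m1$weights[, 1], covxy / sqrt(sum(covxy^2)), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(pls_fit(f$X, rep(1, 10), ncomp = 1), "both classes")
  expect_error(pls_fit(f$X, f$y, ncomp = 50), "exceeds")
})

test_that("PLS agrees with the reference implementation (mixOmics)", {
  skip_if_not_installed("mixOmics")
  f <- toy_features(n = 6, p = 4, seed = 12)
  Xs <- scale(f$X)  # shared scaled input so both fit the same matrix
  colnames(Xs) <- colnames(f$X)
  mine <- pls_fit(Xs, f$y, ncomp = 2, scaling = "none")
  ref <- mixOmics::pls(Xs, f$y, ncomp = 2, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, newdata = Xs)$predict[, 1, 2]
  expect_equal(unname(mine$fitted), unname(pred_ref), tolerance = 1e-6)

  # collapsed coefficients agree on held-out rows as well
  withr::with_seed(5, new <- matrix(rnorm(8), 2, 4,
                                    dimnames = list(NULL, colnames(f$X))))
  expect_equal(unname(predict(mine, new)$response),
               unname(predict(ref, newdata = new)$predict[, 1, 2]),
               tolerance = 1e-6)
})

test_that("PLS internal structure satisfies its contracts", {
  f <- toy_features(n = 12, p = 6, seed = 21)
  m <- pls_fit(f$X, f$y, ncomp = 3)

  # score vectors mutually orthogonal, weights unit norm
  TT <- crossprod(m$x_scores)
  expect_equal(TT, diag(diag(TT)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(colSums(m$weights^2)), rep(1, 3), tolerance = 1e-10)

  # prediction via components equals prediction via collapsed coefficients
  via_comp <- m$intercept + drop(m$x_scores %*% m$y_loadings)
  expect_equal(via_comp, unname(m$fitted), tolerance = 1e-8)

  # the training mean feature vector predicts the mean response
  mbar <- matrix(colMeans(f$X), 1, dimnames = list(NULL, colnames(f$X)))
  expect_equal(predict(m, mbar)$response, mean(f$y), tolerance = 1e-8)

  # row permutation permutes scores identically
  perm <- withr::with_seed(4, sample(seq_len(12)))
  mp <- pls_fit(f$X[perm, ], f$y[perm], ncomp = 3)
  expect_equal(mp$x_scores, m$x_scores[perm, ], tolerance = 1e-8)

  # prediction rejects mismatched dimensions
  expect_error(predict(m, matrix(0, 1, 3)), "bins")
})

test_that("VIP follows the explained-variance formula and its normalisation", {
  # A = 1 with equal |weights| forces every VIP to 1
  y <- c(0, 1, 0, 1)
  X <- cbind(b1 = c(-1, 1, -1, 1), b2 = c(-1, 1, -1, 1))
  m <- pls_fit(X, y, ncomp = 1, scaling = "none")
  expect_equal(vip_scores(m)$vip, c(1, 1), tolerance = 1e-9)

  # hand evaluation of the formula on a fitted 6 x 4 model
  f <- toy_features(n = 6, p = 4, seed = 33)
  m2 <- pls_fit(f$X, f$y, ncomp = 2)
  ssy <- m2$y_loadings^2 * m2$score_ss
  hand <- sqrt(4 * (m2$weights^2 %*% ssy) / sum(ssy))
  expect_equal(vip_scores(m2)$vip, drop(hand), tolerance = 1e-8,
               ignore_attr = TRUE)

  # sum of squared VIP equals the bin count on fuzzed inputs
  for (s in 1:8) {
    withr::with_seed(100 + s, {
      n <- sample(6:14, 1); p <- sample(3:12, 1)
      Xf <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("b", 1:p)))
      yf <- rep(c(0, 1), length.out = n)
    })
    mf <- pls_fit(Xf, yf, ncomp = min(3, n - 1, p))
    expect_equal(sum(vip_scores(mf)$vip^2), p, tolerance = 1e-6)
  }

  # a single informative bin among noise attains the top VIP, above 1.5
  f3 <- toy_features(n = 16, p = 12, seed = 77)
  m3 <- pls_fit(f3$X, f3$y, ncomp = 2)
  v3 <- vip_scores(m3)
  expect_equal(which.max(v3$vip), 1L)
  expect_gt(max(v3$vip), 1.5)
})
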