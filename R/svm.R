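#' Kernel specification for score-space SVM classification
#'
#' The four kernels used to separate the latent-score plots: quadratic
#' `(u.v + 1)^2`, polynomial `(gamma u.v + coef0)^degree`, Gaussian
#' radial basis `exp(-gamma ||u - v||^2)`, and multilayer perceptron
#' (sigmoid) `tanh(gamma u.v + coef0)`.
#'
#' @param name One of `"quadratic"`, `"polynomial"`, `"rbf"`, `"mlp"`.
#' @param degree Polynomial degree (default 3; fixed at 2 for quadratic).
#' @param gamma Kernel scale; `NULL` resolves to `1/k` (score dimension)
#'   at evaluation/training time. Fixed at 1 for quadratic.
#' @param coef0 Offset for polynomial/mlp (1 for quadratic/polynomial,
#'   0 for mlp by default).
#' @return A `kernel_spec`.
#' @export
kernel_spec <- function(name = c("rbf", "quadratic", "polynomial", "mlp"),
                        degree = 3L, gamma = NULL, coef0 = NULL) {
  name <- match.arg(name)
  if (name == "quadratic") {
    degree <- 2L; gamma <- 1; coef0 <- 1
  }
  if (is.null(coef0)) coef0 <- if (name == "polynomial") 1 else 0
  if (!is.null(gamma)) check_number(gamma, "gamma", min = 0, strict = TRUE)
  degree <- check_count(degree, "degree", min = 1L)
  check_number(coef0, "coef0")
  structure(list(name = name, degree = degree, gamma = gamma, coef0 = coef0),
            class = "kernel_spec")
}

resolve_gamma <- function(spec, k) spec$gamma %||% (1 / k)

#' Evaluate a kernel on two score vectors
#'
#' @param spec A [kernel_spec()].
#' @param u,v Numeric vectors of equal length.
#' @return A single kernel value; symmetric in `(u, v)`.
#' @export
#' @examples
#' kernel_eval(kernel_spec("quadratic"), c(1, 0), c(0, 1))
kernel_eval <- function(spec, u, v) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(u) != length(v)) abort("`u` and `v` must have equal dimension.")
  g <- resolve_gamma(spec, length(u))
  switch(spec$name,
    quadratic  = (sum(u * v) + 1)^2,
    polynomial = (g * sum(u * v) + spec$coef0)^spec$degree,
    rbf        = exp(-g * sum((u - v)^2)),
    mlp        = tanh(g * sum(u * v) + spec$coef0))
}

score_matrix <- function(scores) {
  if (is.matrix(scores)) {
    m <- scores
  } else {
    stopifnot(is.data.frame(scores))
    cols <- setdiff(names(scores), "sample_id")
    m <- as.matrix(scores[, cols, drop = FALSE])
    if ("sample_id" %in% names(scores)) rownames(m) <- scores$sample_id
  }
  storage.mode(m) <- "double"
  m
}

#' Train a soft-margin SVM on latent scores
#'
#' Solves the C-soft-margin dual (via libsvm) on the supplied score
#' vectors with one of the four [kernel_spec()] kernels. Labels may be
#' given as 0/1 (burn coding) or -1/+1; internally they are recoded to
#' +1 = burn. The solver handles the indefinite mlp (sigmoid) Gram
#' directly, so no Gram regularisation is required. Dual coefficients
#' are bounded by `C` and training is deterministic.
#'
#' @param scores Samples-by-k score tibble (optionally with `sample_id`)
#'   or matrix.
#' @param labels Class labels, 0/1 or -1/+1.
#' @param spec A [kernel_spec()].
#' @param C Soft-margin penalty (default 1).
#' @return A `score_svm` with `support` (support vectors with signed dual
#'   coefficients, oriented so positive decisions mean burn), `bias`, and
#'   the training decision values.
#' @export
svm_train <- function(scores, labels, spec = kernel_spec("rbf"), C = 1) {
  stopifnot(inherits(spec, "kernel_spec"))
  check_number(C, "C", min = 0, strict = TRUE)
  X <- score_matrix(scores)
  if (ncol(X) < 1L) abort("scores must have at least one dimension.")
  ypm <- ifelse(as.numeric(labels) > 0, 1L, -1L)
  if (length(unique(ypm)) < 2L) abort("both classes required to train an SVM.")
  if (length(ypm) != nrow(X)) abort("one label per score vector required.")
  g <- resolve_gamma(spec, ncol(X))
  kern <- switch(spec$name, quadratic = "polynomial", polynomial = "polynomial",
                 rbf = "radial", mlp = "sigmoid")
  fit <- e1071::svm(x = X, y = factor(ypm, levels = c(-1, 1)),
                    type = "C-classification", kernel = kern,
                    degree = spec$degree, gamma = g, coef0 = spec$coef0,
                    cost = C, scale = FALSE)
  # orient the decision function so positive values mean the +1 (burn) class
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  flip <- if (colnames(dv)[1] == "-1/1") -1 else 1
  model <- structure(list(
    spec = spec, C = C, gamma = g, fit = fit, flip = flip, k = ncol(X),
    support = tibble::tibble(
      index = fit$index,
      dual = flip * drop(fit$coefs)),
    support_vectors = fit$SV,
    bias = -flip * fit$rho,
    train = X, train_labels = ypm), class = "score_svm")
  model$train_decision <- predict(model, X)$decision
  model
}

#' Predict classes and decision values from a score-space SVM
#'
#' The decision value is `sum_i alpha_i K(s_i, x) + bias`; its sign gives
#' the class, with exact zeros mapped to the burn class. Classes are
#' reported in the 0/1 coding (1 = burn).
#'
#' @param object A `score_svm`.
#' @param newdata Score tibble or matrix with the training dimension.
#' @param ... Unused.
#' @return Tibble with `decision` and `class`.
#' @export
predict.score_svm <- function(object, newdata, ...) {
  X <- score_matrix(newdata)
  if (ncol(X) != object$k) {
    abort(sprintf("scores have dimension %d but the model was trained on %d.",
                  ncol(X), object$k))
  }
  dv <- attr(predict(object$fit, X, decision.values = TRUE), "decision.values")
  decision <- object$flip * drop(dv)
  tibble::tibble(decision = decision, class = as.integer(decision >= 0))
}

#' @rdname predict.score_svm
#' @param model A `score_svm`.
#' @param scores Score tibble or matrix.
#' @export
svm_predict <- function(model, scores) predict(model, scores)

#' Decision values on a dense 2-D grid
#'
#' Evaluates the decision function over a rectangle of the 2-D score
#' plane, for drawing the separating line as the zero contour.
#'
#' @param model A 2-D `score_svm`.
#' @param x_range,y_range Ranges of the two score axes; default to the
#'   training ranges padded by 10%.
#' @param resolution Grid points per axis.
#' @return Tibble with `x`, `y`, `decision`.
#' @export
boundary_grid <- function(model, x_range = NULL, y_range = NULL,
                          resolution = 100L) {
  stopifnot(inherits(model, "score_svm"))
  if (model$k != 2L) abort("boundary_grid requires a 2-D score space.")
  resolution <- check_count(resolution, "resolution", min = 1L)
  pad <- function(r) r + c(-1, 1) * 0.1 * diff(r)
  x_range <- x_range %||% pad(range(model$train[, 1]))
  y_range <- y_range %||% pad(range(model$train[, 2]))
  xs <- if (resolution == 1L) mean(x_range) else seq(x_range[1], x_range[2], length.out = resolution)
  ys <- if (resolution == 1L) mean(y_range) else seq(y_range[1], y_range[2], length.out = resolution)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  colnames(grid) <- colnames(model$train)
  pred <- predict(model, grid)
  tibble::tibble(x = grid[, 1], y = grid[, 2], decision = pred$decision)
}
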