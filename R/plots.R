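#' Plot spectra with a reversed ppm axis
#'
#' @param spectra Spectra tibble.
#' @param samples Optional subset of sample ids.
#' @return A ggplot object (chemical shift decreasing left to right, the
#'   NMR convention).
#' @export
plot_spectra <- function(spectra, samples = NULL) {
  spectra <- as_spectra(spectra)
  if (!is.null(samples)) spectra <- spectra[spectra$sample_id %in% samples, ]
  ggplot2::ggplot(spectra, ggplot2::aes(.data$ppm, .data$intensity,
                                        colour = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

score_plot <- function(scores_tbl, labels = NULL, xlab, ylab) {
  if (!is.null(labels)) {
    scores_tbl$class <- factor(labels, levels = c(0, 1),
                               labels = c("healthy", "burn"))
  }
  p <- ggplot2::ggplot(scores_tbl, ggplot2::aes(.data[[xlab]], .data[[ylab]]))
  if (!is.null(labels)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                              shape = .data$class), size = 2)
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::theme_minimal()
}

#' @describeIn pca_fit Score plot of the first two principal components.
#' @param object A `pca_model`.
#' @param labels Optional 0/1 class labels for colouring.
#' @param ... Unused.
#' @export
autoplot.pca_model <- function(object, labels = NULL, ...) {
  if (object$k < 2L) abort("need at least 2 components to draw a score plot.")
  score_plot(object$scores, labels, "PC1", "PC2") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]))
}

#' @describeIn pls_fit Score plot of the first two latent components.
#' @param object A `pls_model`.
#' @param labels Optional 0/1 class labels; defaults to the training y.
#' @param ... Unused.
#' @export
autoplot.pls_model <- function(object, labels = NULL, ...) {
  if (object$n_components < 2L) abort("need at least 2 components to draw a score plot.")
  tbl <- tibble::tibble(sample_id = object$sample_id,
                        t1 = object$x_scores[, 1], t2 = object$x_scores[, 2])
  score_plot(tbl, labels %||% object$y, "t1", "t2") +
    ggplot2::labs(x = "t[1]", y = "t[2]")
}

#' Plot the SVM separating line over the 2-D score plane
#'
#' Draws the training scores and the zero contour of the decision
#' function (the separating line between burn and healthy samples).
#'
#' @param model A 2-D `score_svm`.
#' @param resolution Grid resolution per axis.
#' @return A ggplot object.
#' @export
plot_decision_boundary <- function(model, resolution = 120L) {
  grid <- boundary_grid(model, resolution = resolution)
  pts <- tibble::tibble(x = model$train[, 1], y = model$train[, 2],
                        class = factor(model$train_labels, levels = c(-1, 1),
                                       labels = c("healthy", "burn")))
  ggplot2::ggplot() +
    ggplot2::geom_contour(data = grid,
                          ggplot2::aes(.data$x, .data$y, z = .data$decision),
                          breaks = 0, colour = "black") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$x, .data$y, colour = .data$class,
                                     shape = .data$class), size = 2) +
    ggplot2::labs(x = "t[1]", y = "t[2]") +
    ggplot2::theme_minimal()
}

#' Plot the VIP profile across bins
#'
#' @param vip VIP tibble from [vip_scores()].
#' @param threshold Reference selection threshold line (default 1.5).
#' @return A ggplot object.
#' @export
plot_vip <- function(vip, threshold = 1.5) {
  x <- if (all(is.na(vip$ppm))) vip$bin else vip$ppm
  d <- tibble::tibble(x = x, vip = vip$vip)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$vip)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x, yend = 0), linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2, colour = "red") +
    ggplot2::labs(x = if (all(is.na(vip$ppm))) "bin" else "chemical shift (ppm)",
                  y = "VIP") +
    ggplot2::theme_minimal()
  if (!all(is.na(vip$ppm))) p <- p + ggplot2::scale_x_reverse()
  p
}
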