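#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(
    bin = seq_along(x$coefficients),
    column = names(x$coefficients),
    ppm = if (!is.null(x$bin_centers)) x$bin_centers else NA_real_,
    coefficient = unname(x$coefficients),
    weight_1 = x$weights[, 1])
}

#' @export
glance.pls_model <- function(x, ...) {
  rss <- sum((x$y - x$fitted)^2)
  ssy <- sum((x$y - mean(x$y))^2)
  tibble::tibble(n = length(x$y), n_components = x$n_components,
                 r_squared = 1 - rss / ssy)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k),
                 explained_variance = x$explained_variance)
}

#' @export
tidy.cv_result <- function(x, ...) x$predictions

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_components = x$n_components, press = x$press,
                 ssy = x$ssy, q2 = x$q2, r2 = x$r2, secv = x$secv,
                 sd_x = x$sd_x)
}

#' @export
tidy.component_selection <- function(x, ...) x$table

#' @export
tidy.eigen_metabolome <- function(x, ...) x$matches

#' @export
glance.burn_run <- function(x, ...) {
  tibble::tibble(n = x$cv$n, n_components = x$ncomp, q2 = x$cv$q2,
                 r2 = x$cv$r2, secv = x$cv$secv,
                 n_selected_bins = nrow(x$eigen$selected),
                 n_metabolites = length(x$eigen$metabolites),
                 n_genes = nrow(x$eigen$genes),
                 svm_accuracy = x$svm_accuracy)
}
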