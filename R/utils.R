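#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm rlnorm runif sd var setNames predict p.adjust phyper
#' @importFrom utils head tail
NULL

# single place for argument checks so error messages stay uniform
check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) abort(sprintf("`%s` must be > %s.", name, min))
  if (!strict && x < min) abort(sprintf("`%s` must be >= %s.", name, min))
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

#' Derive a reproducible child seed for a pipeline stage
#'
#' One global seed fans out to per-stage seeds by hashing the stage name,
#' so individual stages can be re-run in isolation and still see the same
#' random stream they saw inside a full pipeline run.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed below 2^31.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed", min = 0L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587)
}

# spectra tibbles: columns sample_id, ppm (descending within sample), intensity
as_spectra <- function(data) {
  if (!is.data.frame(data)) abort("spectra must be a data frame.")
  if (!all(c("ppm", "intensity") %in% names(data))) {
    abort("spectra need `ppm` and `intensity` columns.")
  }
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) data$sample_id <- "s1"
  data[, c("sample_id", "ppm", "intensity")]
}

# apply a per-sample function (tibble in, tibble out) preserving sample order
map_samples <- function(spectra, f, ...) {
  spectra <- as_spectra(spectra)
  ids <- unique(spectra$sample_id)
  parts <- lapply(ids, function(id) f(spectra[spectra$sample_id == id, ], ...))
  dplyr::bind_rows(parts)
}
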