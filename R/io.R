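#' Write and read spectra as two-column delimited text
#'
#' Each spectrum is written as a tab-separated file `<sample_id>.tsv`
#' with columns `ppm` (descending) and `intensity`; alongside, a
#' `labels.tsv` maps sample ids to class labels when labels are given.
#'
#' @param spectra Spectra tibble.
#' @param dir Output directory (created if absent).
#' @param labels Optional tibble (`sample_id`, `class`).
#' @return Invisibly, the written file paths.
#' @export
write_spectra <- function(spectra, dir, labels = NULL) {
  spectra <- as_spectra(spectra)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- unique(spectra$sample_id)
  paths <- vapply(ids, function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    readr::write_tsv(spectra[spectra$sample_id == id, c("ppm", "intensity")], p)
    p
  }, "")
  if (!is.null(labels)) {
    readr::write_tsv(labels, file.path(dir, "labels.tsv"))
    paths <- c(paths, file.path(dir, "labels.tsv"))
  }
  invisible(paths)
}

#' @rdname write_spectra
#' @param path Path of one two-column (ppm, intensity) delimited file.
#' @param sample_id Sample id to assign (default: file name stem).
#' @export
read_spectrum <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_double()))
  if (ncol(d) < 2L) abort("spectrum file needs two columns (ppm, intensity).")
  names(d)[1:2] <- c("ppm", "intensity")
  out <- dplyr::arrange(tibble::tibble(sample_id = sample_id,
                                       ppm = d$ppm, intensity = d$intensity),
                        dplyr::desc(.data$ppm))
  out
}

#' Write and read a feature matrix as CSV
#'
#' The header row carries the bin centres (as `ppm_<centre>` column
#' names) and the first column the sample ids, in a bit-stable order.
#'
#' @param features Feature tibble from [assemble_feature_matrix()].
#' @param path CSV path.
#' @return Invisibly, `path` (writer) or the feature tibble (reader).
#' @export
write_feature_matrix <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  centers <- suppressWarnings(as.numeric(sub("^ppm_", "", setdiff(names(d), "sample_id"))))
  attr(d, "bin_centers") <- centers
  d
}
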