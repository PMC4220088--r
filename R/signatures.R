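#' Packaged plasma metabolite signature table
#'
#' Lorentzian rendering templates for the simulator: one row per resonance
#' with its chemical shift, full width at half maximum and the fraction of
#' the metabolite's total signal it carries. The table holds creatinine
#' (anchored at 3.05 ppm, the referencing peak), the twelve burn-marker
#' metabolites and the major plasma background metabolites (glucose,
#' lactate, alanine). Shifts and multiplet weights are curated from
#' standard plasma spectral compilations, restricted to each metabolite's
#' strongest resolved resonances; they are simulator inputs, editable by
#' replacing the file, never ground truth for any statistical claim.
#'
#' @param path Optional path to an alternative TSV with the same columns
#'   (`metabolite`, `baseline_abundance`, `ppm`, `fwhm`, `relative_area`).
#' @return A tibble, one row per resonance.
#' @export
#' @examples
#' metabolite_signatures()
metabolite_signatures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "metabolite_signatures.tsv",
                                package = "eigenmet", mustWork = TRUE)
  sig <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           metabolite = readr::col_character(),
                           .default = readr::col_double()))
  validate_signatures(sig, require_creatinine = TRUE)
  sig
}

validate_signatures <- function(sig, require_creatinine = FALSE) {
  needed <- c("metabolite", "baseline_abundance", "ppm", "fwhm", "relative_area")
  if (!all(needed %in% names(sig))) {
    abort(paste0("signature table needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(sig$fwhm <= 0)) abort("all signature `fwhm` must be > 0.")
  if (any(sig$relative_area <= 0)) abort("all signature `relative_area` must be > 0.")
  sums <- tapply(sig$relative_area, sig$metabolite, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-9]
  if (length(bad)) {
    abort(paste0("relative areas must sum to 1 per metabolite; offending: ",
                 paste(bad, collapse = ", ")))
  }
  cre <- sig[sig$metabolite == "Creatinine", ]
  if (require_creatinine && nrow(cre) == 0L) {
    abort("signature table must include a creatinine resonance at 3.05 ppm.")
  }
  if (nrow(cre) > 0L && !any(abs(cre$ppm - 3.05) < 1e-9)) {
    abort("the creatinine signature must include its 3.05 ppm resonance.")
  }
  invisible(sig)
}

#' Reference chemical shifts used for metabolite identification
#'
#' Lookup table emulating a database query: each row is a diagnostic
#' resolved resonance of one metabolite. Bins selected by VIP score are
#' matched against these positions by [match_bins_to_metabolites()].
#'
#' @param path Optional path to an alternative TSV (`metabolite`, `ppm`).
#' @return A tibble, one row per reference peak.
#' @export
reference_peaks <- function(path = NULL) {
  path <- path %||% system.file("extdata", "reference_peaks.tsv",
                                package = "eigenmet", mustWork = TRUE)
  ref <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(metabolite = readr::col_character(),
                                                 ppm = readr::col_double()))
  if (nrow(ref) == 0L) abort("reference peak table is empty.")
  ref
}

#' Metabolite to enzyme-gene map
#'
#' The packaged metabolite-to-gene table linking each burn-marker
#' metabolite to the enzyme genes that act on it (HMDB-derived, shipped as
#' a versioned fixture so no live database query is needed). A `-` entry
#' in the source, meaning a metabolite with no mapped enzyme, is read as a
#' metabolite present in the map with an empty gene set.
#'
#' @param path Optional path to an alternative TSV (`metabolite`, `gene`).
#' @return A tibble with columns `metabolite` and `gene`; `gene` is `NA`
#'   for metabolites with no mapped enzyme.
#' @export
#' @examples
#' dplyr::filter(metabolite_gene_map(), metabolite == "3-Methylhistidine")
metabolite_gene_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "metabolite_gene_map.tsv",
                                package = "eigenmet", mustWork = TRUE)
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  map$gene[map$gene %in% c("-", "")] <- NA_character_
  map
}
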