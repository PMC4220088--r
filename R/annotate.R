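#' Select Eigen-metabolome bins by VIP threshold
#'
#' Keeps the bins whose VIP score strictly exceeds the threshold (the
#' biomarker-selection rule, default VIP > 1.5), sorted by descending
#' VIP.
#'
#' @param vip VIP tibble from [vip_scores()] (columns `bin`, `ppm`,
#'   `vip`).
#' @param threshold Strict lower VIP bound (default 1.5).
#' @return The selected rows, descending by `vip`.
#' @export
select_eigen_bins <- function(vip, threshold = 1.5) {
  check_number(threshold, "threshold", min = 0)
  if (!all(c("bin", "vip") %in% names(vip))) {
    abort("`vip` must have `bin` and `vip` columns (see vip_scores()).")
  }
  dplyr::arrange(dplyr::filter(vip, .data$vip > threshold), dplyr::desc(.data$vip))
}

#' Match selected bins to metabolites by chemical shift
#'
#' A bin matches a metabolite when any of the metabolite's reference
#' peaks lies within `tolerance` of the bin's ppm interval (the interval,
#' not just the centre, so peaks near bin edges still match). One bin may
#' match several metabolites; such bins are flagged ambiguous. Unmatched
#' bins are reported with `NA` metabolite.
#'
#' @param bins Tibble with a `bin` column (and `vip` if available),
#'   e.g. from [select_eigen_bins()].
#' @param reference Reference peak tibble, see [reference_peaks()].
#' @param tolerance Matching tolerance in ppm (default 0.03).
#' @param grid The [bin_grid()] the bins came from (supplies intervals).
#' @return Tibble with one row per (bin, metabolite) match plus one row
#'   per unmatched bin: `bin`, `ppm` (centre), `vip`, `metabolite`,
#'   `peak_ppm`, `distance`, `ambiguous`.
#' @export
match_bins_to_metabolites <- function(bins, reference = reference_peaks(),
                                      tolerance = 0.03, grid = bin_grid()) {
  check_number(tolerance, "tolerance", min = 0, strict = TRUE)
  if (nrow(reference) == 0L) abort("reference peak table is empty.")
  stopifnot(inherits(grid, "bin_grid"))
  if (!"bin" %in% names(bins)) abort("`bins` must have a `bin` column.")
  info <- grid$bins[match(bins$bin, grid$bins$bin), ]
  if (anyNA(info$bin)) abort("some bin indices are not part of the grid.")
  seg_dist <- function(lo, hi, p) {
    if (is.na(lo)) return(rep(Inf, length(p)))
    pmax(lo - p, p - hi, 0)
  }
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    d <- pmin(seg_dist(info$lo1[i], info$hi1[i], reference$ppm),
              seg_dist(info$lo2[i], info$hi2[i], reference$ppm))
    hit <- which(d <= tolerance)
    base <- tibble::tibble(bin = bins$bin[i], ppm = info$center[i],
                           vip = bins$vip[i] %||% NA_real_)
    if (!length(hit)) {
      return(dplyr::mutate(base, metabolite = NA_character_,
                           peak_ppm = NA_real_, distance = NA_real_,
                           ambiguous = FALSE))
    }
    hits <- tibble::tibble(metabolite = reference$metabolite[hit],
                           peak_ppm = reference$ppm[hit],
                           distance = d[hit])
    # one row per matched metabolite, keeping its closest peak
    hits <- dplyr::slice_min(dplyr::group_by(hits, .data$metabolite),
                             .data$distance, n = 1, with_ties = FALSE)
    hits <- dplyr::ungroup(hits)
    dplyr::mutate(dplyr::bind_cols(base[rep(1, nrow(hits)), ], hits),
                  ambiguous = nrow(hits) > 1L)
  })
  dplyr::bind_rows(rows)
}

#' Expand matched metabolites to their enzyme genes
#'
#' Takes the union of enzyme-gene symbols mapped to the given
#' metabolites. Duplicate genes are collapsed to one row, but the
#' metabolites contributing each gene are retained as provenance.
#' Metabolites absent from the map trigger a warning and are skipped,
#' never dropped silently; metabolites present with an empty mapping
#' (no known enzyme) simply contribute no genes.
#'
#' @param metabolites Character vector of metabolite names.
#' @param gene_map Mapping tibble, see [metabolite_gene_map()].
#' @return Tibble with `gene`, `metabolites` (collapsed provenance) and
#'   `n_metabolites`.
#' @export
#' @examples
#' map_metabolites_to_genes("3-Methylhistidine")
map_metabolites_to_genes <- function(metabolites, gene_map = metabolite_gene_map()) {
  metabolites <- unique(metabolites[!is.na(metabolites)])
  missing <- setdiff(metabolites, unique(gene_map$metabolite))
  if (length(missing)) {
    warn(paste0("metabolites absent from the gene map were skipped: ",
                paste(missing, collapse = ", ")))
    metabolites <- setdiff(metabolites, missing)
  }
  hits <- gene_map[gene_map$metabolite %in% metabolites & !is.na(gene_map$gene), ]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(gene = character(), metabolites = character(),
                          n_metabolites = integer()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    metabolites = paste(sort(unique(.data$metabolite)), collapse = "; "),
    n_metabolites = dplyr::n_distinct(.data$metabolite), .groups = "drop")
  dplyr::arrange(out, .data$gene)
}

#' Build the Eigen-metabolome from a fitted PLS-DA model's VIP profile
#'
#' The full biomarker-annotation chain: VIP thresholding, chemical-shift
#' matching of selected bins against the reference peak table, and
#' expansion of the matched metabolites to their enzyme genes.
#'
#' @param vip VIP tibble from [vip_scores()].
#' @param grid The [bin_grid()] the features were binned on.
#' @param reference Reference peak tibble.
#' @param gene_map Metabolite-to-gene tibble.
#' @param threshold VIP selection threshold (strict, default 1.5).
#' @param tolerance Shift-matching tolerance in ppm (default 0.03).
#' @return An `eigen_metabolome`: list with `selected` (bins), `matches`,
#'   `metabolites` (distinct matched names) and `genes`.
#' @export
build_eigen_metabolome <- function(vip, grid = bin_grid(),
                                   reference = reference_peaks(),
                                   gene_map = metabolite_gene_map(),
                                   threshold = 1.5, tolerance = 0.03) {
  selected <- select_eigen_bins(vip, threshold)
  matches <- match_bins_to_metabolites(selected, reference, tolerance, grid)
  metabolites <- sort(unique(matches$metabolite[!is.na(matches$metabolite)]))
  genes <- suppressWarnings(map_metabolites_to_genes(metabolites, gene_map))
  structure(list(selected = selected, matches = matches,
                 metabolites = metabolites, genes = genes,
                 threshold = threshold, tolerance = tolerance),
            class = "eigen_metabolome")
}

#' @export
print.eigen_metabolome <- function(x, ...) {
  cat(sprintf("<eigen_metabolome> %d bins with VIP > %.2f -> %d metabolites, %d genes\n",
              nrow(x$selected), x$threshold, length(x$metabolites), nrow(x$genes)))
  if (length(x$metabolites)) cat(paste(" ", x$metabolites, collapse = "\n"), "\n")
  invisible(x)
}
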