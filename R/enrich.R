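#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the chance that a
#' random query of `n` genes from a universe of `N` overlaps a `K`-gene
#' term in at least `k` genes. Vectorised over its arguments.
#'
#' @param N Universe size.
#' @param K Term (annotated set) size.
#' @param n Query size.
#' @param k Observed overlap.
#' @return Probability in `(0, 1]`; exactly 1 when `k = 0`.
#' @export
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1 / choose(10, 5)
hypergeom_tail <- function(N, K, n, k) {
  m <- cbind(N, K, n, k)
  N <- m[, 1]; K <- m[, 2]; n <- m[, 3]; k <- m[, 4]
  if (any(m < 0) || any(m != floor(m))) abort("all counts must be non-negative integers.")
  if (any(K > N) || any(n > N)) abort("`K` and `n` must not exceed `N`.")
  if (any(k > pmin(K, n))) abort("`k` must not exceed min(K, n).")
  unname(phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Build a term annotation table
#'
#' @param terms Tibble with `term_id`, `term_name`, `category` (one of
#'   BP/CC/MF) and `genes` (list-column of character vectors).
#' @param universe Background gene set; defaults to the union of all
#'   annotated genes.
#' @return An `annotation_table`.
#' @export
annotation_table <- function(terms, universe = NULL) {
  needed <- c("term_id", "term_name", "category", "genes")
  if (!all(needed %in% names(terms))) {
    abort(paste0("`terms` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (!all(terms$category %in% c("BP", "CC", "MF"))) {
    abort("`category` must be one of BP, CC, MF.")
  }
  terms$genes <- lapply(terms$genes, function(g) unique(as.character(g)))
  if (any(lengths(terms$genes) == 0L)) abort("every term must annotate at least one gene.")
  annotated <- unique(unlist(terms$genes))
  universe <- unique(as.character(universe %||% annotated))
  extra <- setdiff(annotated, universe)
  if (length(extra)) {
    abort(paste0("annotated genes missing from the universe: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  structure(list(terms = tibble::as_tibble(terms), universe = universe),
            class = "annotation_table")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated
#' `term<TAB>description<TAB>gene1<TAB>gene2...`. When the description
#' field is one of BP/CC/MF it is taken as the term's category; otherwise
#' `category` applies.
#'
#' @param path GMT file path.
#' @param category Fallback category for terms whose description is not a
#'   category code.
#' @return An [annotation_table()].
#' @export
read_gmt <- function(path, category = "BP") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("GMT file is empty.")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) abort(sprintf("GMT line %d has fewer than 3 fields.", which(bad)[1]))
  terms <- tibble::tibble(
    term_id = vapply(parts, `[[`, "", 1L),
    term_name = vapply(parts, `[[`, "", 2L),
    category = vapply(parts, function(p) {
      if (p[[2]] %in% c("BP", "CC", "MF")) p[[2]] else category
    }, ""),
    genes = lapply(parts, function(p) unique(p[-(1:2)])))
  terms$term_name <- ifelse(terms$term_name %in% c("BP", "CC", "MF"),
                            terms$term_id, terms$term_name)
  annotation_table(terms)
}

#' Hypergeometric term enrichment of a gene set
#'
#' For every annotated term that overlaps the query, reports the term
#' size `T`, the effective query size `Q`, the overlap `k` and the
#' ratios `k/Q` and `k/T`, with an upper-tail hypergeometric p-value.
#' The effective query and the universe are recomputed per category
#' against that category's annotated genes (which is why `Q` can differ
#' between categories), terms with zero overlap are omitted, rows are
#' sorted by ascending p, and Benjamini-Hochberg adjusted p-values are
#' reported per category alongside the raw ones.
#'
#' @param query Character vector of gene symbols.
#' @param annotation An [annotation_table()].
#' @param categories Categories to test (default all of BP, CC, MF).
#' @return Tibble with columns `term_id`, `category`, `term_name`, `T`,
#'   `Q`, `k`, `ratio_q`, `ratio_t`, `p`, `p_adj`.
#' @export
enrich_terms <- function(query, annotation, categories = c("BP", "CC", "MF")) {
  stopifnot(inherits(annotation, "annotation_table"))
  query <- unique(as.character(query))
  categories <- match.arg(categories, c("BP", "CC", "MF"), several.ok = TRUE)
  if (!length(intersect(query, annotation$universe))) {
    abort("query shares no genes with the annotation universe.")
  }
  out <- lapply(categories, function(cat) {
    terms <- annotation$terms[annotation$terms$category == cat, ]
    if (nrow(terms) == 0L) return(NULL)
    cat_genes <- intersect(annotation$universe, unique(unlist(terms$genes)))
    N <- length(cat_genes)
    q_eff <- intersect(query, cat_genes)
    Q <- length(q_eff)
    if (Q == 0L) return(NULL)
    rows <- purrr::map_dfr(seq_len(nrow(terms)), function(i) {
      genes <- terms$genes[[i]]
      k <- length(intersect(q_eff, genes))
      if (k == 0L) return(NULL)
      Tsize <- length(genes)
      tibble::tibble(term_id = terms$term_id[i], category = cat,
                     term_name = terms$term_name[i],
                     T = Tsize, Q = Q, k = k,
                     ratio_q = k / Q, ratio_t = k / Tsize,
                     p = hypergeom_tail(N, Tsize, Q, k))
    })
    if (is.null(rows) || nrow(rows) == 0L) return(NULL)
    rows$p_adj <- p.adjust(rows$p, method = "BH")
    rows
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(res)
  dplyr::arrange(res, .data$p)
}

#' Deterministic synthetic term annotation for pipeline demonstrations
#'
#' Generates a GO-style annotation table (labelled synthetic) over the
#' supplied genes plus invented background genes: some terms are seeded
#' with genes drawn from the supplied set so enrichment has signal to
#' find, the rest are random background sets. Real annotations can be
#' supplied through [read_gmt()] instead.
#'
#' @param genes Character vector of genes of interest to weave into terms.
#' @param n_background Number of invented background genes.
#' @param n_terms Terms per category.
#' @param seed Seed making the table reproducible.
#' @return An [annotation_table()].
#' @export
synthetic_annotation <- function(genes, n_background = 400L, n_terms = 15L,
                                 seed = 1L) {
  n_background <- check_count(n_background, "n_background", min = 10L)
  n_terms <- check_count(n_terms, "n_terms", min = 2L)
  withr::local_seed(check_count(seed, "seed", min = 0L))
  genes <- unique(as.character(genes))
  background <- sprintf("SYNGENE%04d", seq_len(n_background))
  universe <- c(genes, background)
  make_cat <- function(cat) {
    purrr::map_dfr(seq_len(n_terms), function(i) {
      seeded <- i <= ceiling(n_terms / 3) && length(genes) > 1L
      size <- sample(5:60, 1)
      members <- if (seeded) {
        n_sig <- min(length(genes), sample(3:10, 1))
        unique(c(sample(genes, n_sig), sample(background, max(size - n_sig, 1))))
      } else {
        sample(universe, size)
      }
      tibble::tibble(term_id = sprintf("SYN:%s%03d", cat, i),
                     term_name = sprintf("synthetic %s term %d", cat, i),
                     category = cat, genes = list(members))
    })
  }
  annotation_table(dplyr::bind_rows(lapply(c("BP", "CC", "MF"), make_cat)),
                   universe = universe)
}
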