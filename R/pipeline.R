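#' Configuration for a full fingerprinting pipeline run
#'
#' Collects every stage's parameters plus one global seed. Unknown keys
#' in any section are rejected rather than silently ignored. The global
#' seed fans out to per-stage child seeds via [stage_seed()], so a stage
#' re-run in isolation reproduces its in-pipeline behaviour.
#'
#' @param design A [cohort_design()]; its seed is overridden by the
#'   derived simulate-stage seed.
#' @param axis An [axis_config()].
#' @param preprocess Named list of overrides: `baseline_order`,
#'   `reference_window`, `water_window`, `region`, `n_bins`, `scaling`.
#' @param model Named list: `max_components`.
#' @param svm Named list: `kernel` (name), `C`.
#' @param annotate Named list: `threshold`, `tolerance`.
#' @param enrich Named list: `categories`, `n_background`, `n_terms`.
#' @param seed Global seed.
#' @param out_dir Optional directory; when set, stage artifacts are
#'   written as delimited text.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(design = cohort_design(), axis = axis_config(),
                            preprocess = list(), model = list(), svm = list(),
                            annotate = list(), enrich = list(),
                            seed = 1L, out_dir = NULL) {
  take <- function(given, defaults, section) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      abort(sprintf("unknown key(s) in `%s`: %s", section,
                    paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  structure(list(
    design = design, axis = axis,
    preprocess = take(preprocess,
                      list(baseline_order = 2L, reference_window = c(2.95, 3.15),
                           water_window = c(4.5, 5.1), region = c(0.2, 10),
                           n_bins = 200L, scaling = "unit-variance"),
                      "preprocess"),
    model = take(model, list(max_components = 5L), "model"),
    svm = take(svm, list(kernel = "rbf", C = 1), "svm"),
    annotate = take(annotate, list(threshold = 1.5, tolerance = 0.03), "annotate"),
    enrich = take(enrich,
                  list(categories = c("BP", "CC", "MF"),
                       n_background = 400L, n_terms = 15L),
                  "enrich"),
    seed = check_count(seed, "seed", min = 0L),
    out_dir = out_dir), class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the complete fingerprinting pipeline
#'
#' simulate -> preprocess -> fit (component selection, PLS-DA, VIP) ->
#' validate (leave-one-out) -> classify (SVM on the first two latent
#' scores) -> annotate (VIP selection, shift matching, gene expansion)
#' -> enrich (synthetic term annotation). Deterministic under a fixed
#' config seed; a failure in any stage aborts with the stage named.
#'
#' @param config A [pipeline_config()].
#' @param signatures Signature table for the simulator.
#' @param reference Reference peak table for annotation.
#' @param gene_map Metabolite-to-gene map.
#' @return A `burn_run` report: cohort, feature matrix, CV table, chosen
#'   component count, fitted model, VIP profile, Eigen-metabolome,
#'   enrichment table and SVM training accuracy.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(design = cohort_design(n_case = 6, n_control = 3),
#'                        axis = axis_config(0, 10, 4096), seed = 11)
#' run <- run_pipeline(cfg)
#' run$cv
#' }
run_pipeline <- function(config = pipeline_config(),
                         signatures = metabolite_signatures(),
                         reference = reference_peaks(),
                         gene_map = metabolite_gene_map()) {
  stopifnot(inherits(config, "pipeline_config"))
  pp <- config$preprocess

  cohort <- run_stage("simulate", {
    design <- config$design
    design$seed <- stage_seed(config$seed, "simulate")
    simulate_cohort(design, signatures, config$axis)
  })

  grid <- bin_grid(region = pp$region, n_bins = pp$n_bins,
                   water_window = pp$water_window)
  features <- run_stage("preprocess", {
    preprocess_spectra(cohort$spectra, baseline_order = pp$baseline_order,
                       reference_window = pp$reference_window,
                       water_window = pp$water_window, grid = grid)
  })
  y <- cohort$labels$class

  selection <- run_stage("fit", {
    select_n_components(features, y,
                        max_components = config$model$max_components,
                        scaling = pp$scaling)
  })
  model <- run_stage("fit", {
    pls_fit(features, y, ncomp = selection$ncomp, scaling = pp$scaling)
  })
  vip <- run_stage("fit", vip_scores(model))

  cv <- run_stage("validate", {
    loo_cross_validate(features, y, ncomp = selection$ncomp, scaling = pp$scaling)
  })

  svm_fit <- run_stage("classify", {
    scores <- model$x_scores[, seq_len(min(2L, ncol(model$x_scores))), drop = FALSE]
    svm_train(scores, y, kernel_spec(config$svm$kernel), C = config$svm$C)
  })
  svm_acc <- mean(predict(svm_fit, svm_fit$train)$class == y)

  eigen <- run_stage("annotate", {
    build_eigen_metabolome(vip, grid, reference, gene_map,
                           threshold = config$annotate$threshold,
                           tolerance = config$annotate$tolerance)
  })

  enrichment <- run_stage("enrich", {
    if (nrow(eigen$genes) == 0L) {
      tibble::tibble()
    } else {
      ann <- synthetic_annotation(eigen$genes$gene,
                                  n_background = config$enrich$n_background,
                                  n_terms = config$enrich$n_terms,
                                  seed = stage_seed(config$seed, "enrich"))
      enrich_terms(eigen$genes$gene, ann, config$enrich$categories)
    }
  })

  report <- structure(list(
    config = config, seed = config$seed,
    cohort = cohort, features = features,
    component_table = selection$table, ncomp = selection$ncomp,
    model = model, vip = vip, cv = cv,
    svm = svm_fit, svm_accuracy = svm_acc,
    eigen = eigen, enrichment = enrichment), class = "burn_run")

  if (!is.null(config$out_dir)) run_stage("write", write_run(report, config$out_dir))
  report
}

#' Planted-marker recovery experiment
#'
#' Runs the full pipeline on a cohort in which every marker metabolite of
#' the metabolite-to-gene map carries the same planted case-vs-control
#' fold change, and returns the distinct metabolites recovered by VIP
#' selection plus chemical-shift matching. With the default two-fold
#' effect the recovered set should equal the twelve planted markers.
#'
#' @param seed Seed for the simulated cohort.
#' @param fold_change Multiplicative case effect planted on every marker.
#' @param concentration_cv Between-subject coefficient of variation.
#' @param config Base [pipeline_config()]; its design's fold changes and
#'   concentration CV are replaced by the planted ones.
#' @param gene_map Map whose metabolites define the planted marker set.
#' @return Character vector of recovered metabolite names (sorted).
#' @export
marker_recovery <- function(seed, fold_change = 2, concentration_cv = 0.15,
                            config = pipeline_config(),
                            gene_map = metabolite_gene_map()) {
  markers <- unique(gene_map$metabolite)
  design <- config$design
  design$fold_changes <- setNames(rep(fold_change, length(markers)), markers)
  design$concentration_cv <- concentration_cv
  config$design <- design
  config$seed <- check_count(seed, "seed", min = 0L)
  run <- run_pipeline(config, gene_map = gene_map)
  run$eigen$metabolites
}

write_run <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(report$cohort$spectra, file.path(dir, "spectra"),
                labels = report$cohort$labels)
  readr::write_tsv(report$cohort$concentrations, file.path(dir, "ground_truth.tsv"))
  write_feature_matrix(report$features, file.path(dir, "feature_matrix.csv"))
  readr::write_tsv(report$component_table, file.path(dir, "cv_table.tsv"))
  readr::write_tsv(report$vip, file.path(dir, "vip.tsv"))
  readr::write_tsv(report$eigen$matches, file.path(dir, "eigen_bins.tsv"))
  readr::write_tsv(report$eigen$genes, file.path(dir, "eigen_genes.tsv"))
  if (nrow(report$enrichment)) {
    readr::write_tsv(report$enrichment, file.path(dir, "enrichment.tsv"))
  }
  invisible(dir)
}

#' @export
print.burn_run <- function(x, ...) {
  cat("<burn_run>\n")
  cat(sprintf("  cohort: %d cases / %d controls (seed %d)\n",
              sum(x$cohort$labels$class == 1), sum(x$cohort$labels$class == 0),
              x$seed))
  cat(sprintf("  PLS-DA: A = %d, R2 = %.3f, Q2 = %.3f, SECV = %.3f\n",
              x$ncomp, x$cv$r2, x$cv$q2, x$cv$secv))
  cat(sprintf("  SVM (%s) training accuracy: %.2f\n", x$svm$spec$name, x$svm_accuracy))
  cat(sprintf("  Eigen-metabolome: %d bins, %d metabolites, %d genes\n",
              nrow(x$eigen$selected), length(x$eigen$metabolites), nrow(x$eigen$genes)))
  cat(sprintf("  enrichment: %d term(s) with overlap\n", nrow(x$enrichment)))
  invisible(x)
}
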