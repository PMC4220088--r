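# shared fixtures: small axes and cohorts keep module tests fast; the
# full-resolution defaults are exercised in the acceptance tests

small_axis <- function(n = 4096L) axis_config(-0.5, 10.5, n)

# minimal two-metabolite signature table for targeted rendering tests
toy_signatures <- function() {
  tibble::tibble(
    metabolite = c("Creatinine", "Creatinine", "MarkerA", "MarkerB"),
    baseline_abundance = c(3, 3, 1, 2),
    ppm = c(3.05, 4.06, 1.20, 7.20),
    fwhm = c(0.01, 0.01, 0.01, 0.01),
    relative_area = c(0.6, 0.4, 1.0, 1.0))
}

toy_cohort <- function(seed = 7, n_case = 6L, n_control = 4L, n = 4096L,
                       fold = 3) {
  simulate_cohort(
    cohort_design(n_case = n_case, n_control = n_control,
                  fold_changes = c(MarkerA = fold),
                  concentration_cv = 0.1, noise_sd = 0.2,
                  shift_jitter_sd = 0.005, baseline_amplitude = 1,
                  water_amplitude = 20, seed = seed),
    signatures = toy_signatures(), axis = small_axis(n))
}

# deterministic small feature matrix with one informative column
toy_features <- function(n = 8L, p = 4L, seed = 42L) {
  withr::with_seed(seed, {
    y <- rep(c(0, 1), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[, 1] <- X[, 1] * 0.1 + 2 * y
    colnames(X) <- paste0("b", seq_len(p))
    rownames(X) <- paste0("s", seq_len(n))
    list(X = X, y = y)
  })
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
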