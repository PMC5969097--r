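# Small worlds used across test files. Sizes are kept modest so the whole
# suite stays fast; calibration-sensitive checks size up locally.

tiny_scenario <- function(seed = 1L, ...) {
  scenario_config(
    n_physicians = 40,
    patients_per_physician = list(mean = 25, dispersion = 8),
    seed = seed,
    ...
  )
}

# A hand-built analysis cohort for algebraic estimator checks: every column
# the estimators touch, nothing generated.
toy_iv_cohort <- function(z, x, y, cluster = NULL) {
  n <- length(z)
  if (is.null(cluster)) cluster <- rep(1:2, length.out = n)
  tibble::tibble(
    patient_id = seq_len(n),
    physician_id = cluster,
    practice_id = 1L,
    index_date = as.Date("2010-01-01") + seq_len(n),
    exposure = as.integer(x),
    z = z,
    yval = y
  )
}

# covariance-ratio / Wald oracle for just-identified IV without covariates
cov_ratio_oracle <- function(z, x, y) {
  cov(z, y) / cov(z, x)
}
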