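test_that("covariate-free 2SLS equals the covariance-ratio oracle exactly", {
  z <- c(0, 1, 2, 3, 4, 5)
  x <- c(0, 0, 1, 0, 1, 1)
  y <- c(1.2, 0.4, 1.9, 2.1, 3.0, 2.4)
  cohort <- toy_iv_cohort(z, x, y, cluster = c(1, 1, 2, 2, 3, 3))
  est <- estimate_iv(cohort, "yval", covariates = character(0))
  expect_equal(est$estimate, cov_ratio_oracle(z, x, y), tolerance = 1e-10)
})

test_that("binary-instrument 2SLS equals the Wald ratio exactly", {
  z <- c(1, 1, 1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 1, 0, 1, 0, 0, 0)
  y <- c(5, 3, 4, 2, 6, 1, 2, 2)
  cohort <- toy_iv_cohort(z, x, y, cluster = rep(1:4, each = 2))
  est <- estimate_iv(cohort, "yval", covariates = character(0))
  wald <- (mean(y[z == 1]) - mean(y[z == 0])) /
    (mean(x[z == 1]) - mean(x[z == 0]))
  expect_equal(est$estimate, wald, tolerance = 1e-10)
})

test_that("a zero first stage raises the weak-instrument error", {
  z <- rep(c(0, 1), 10)
  x <- rep(c(0, 1, 1, 0), 5) # exactly uncorrelated with z
  y <- rnorm(20)
  cohort <- toy_iv_cohort(z, x, y, cluster = rep(1:4, 5))
  expect_error(estimate_iv(cohort, "yval", covariates = character(0)), "weak")
})

test_that("null scenario: OR near 1 and risk difference near 0", {
  sim <- generate_cohort(scenario_null(seed = 51))
  cohort <- build_cohort(sim)$cohort
  lin <- fit_multivariable(cohort, "death_all", 24, "full", "linear")
  expect_lt(abs(lin$estimate), 4 * lin$se_beta)
  logi <- fit_multivariable(cohort, "death_all", 24, "full", "logit")
  expect_lt(abs(logi$beta), 4 * logi$se_beta)
})

test_that("linear RD matches the logistic average marginal effect when rare", {
  sim <- generate_cohort(scenario_confounded(delta = 0.02, seed = 52))
  cohort <- build_cohort(sim)$cohort
  lin <- fit_multivariable(cohort, "death_all", 24, "full", "linear")
  # independent AME oracle from a plain glm fit
  keep <- cohort$cens_death_all_m24 == 0L
  d <- cohort[keep, ]
  fit <- glm(y_death_all_m24 ~ exposure + male + age + charlson_any +
               factor(rx_year), family = binomial(), data = d)
  p1 <- predict(fit, transform(d, exposure = 1L), type = "response")
  p0 <- predict(fit, transform(d, exposure = 0L), type = "response")
  ame <- 100 * mean(p1 - p0)
  expect_lt(abs(lin$estimate - ame) / abs(ame), 0.10)
})

test_that("cluster-robust OLS matches the sandwich reference implementation", {
  sim <- generate_cohort(tiny_scenario(seed = 53))
  cohort <- build_cohort(sim)$cohort
  est <- fit_multivariable(cohort, "death_all", 24, "basic", "linear")
  keep <- cohort$cens_death_all_m24 == 0L
  d <- cohort[keep, ]
  fit <- lm(y_death_all_m24 ~ exposure + factor(rx_year) + male + age, data = d)
  V <- sandwich::vcovCL(fit, cluster = d$physician_id, type = "HC1",
                        cadjust = TRUE)
  expect_equal(est$beta / 100, unname(coef(fit)["exposure"]), tolerance = 1e-10)
  expect_equal(est$se_beta / 100, unname(sqrt(V["exposure", "exposure"])),
               tolerance = 1e-10)
})

test_that("clustered SEs exceed iid SEs under intra-physician correlation", {
  sc <- scenario_confounded(delta = 0, seed = 54, n_physicians = 250,
                            patients_mean = 40)
  sc$physician_outcome_sd <- 0.03
  # the large cluster effect intentionally strains the risk model; the
  # generator's clipping warning is expected here
  cohort <- build_cohort(suppressWarnings(generate_cohort(sc)))$cohort
  est <- fit_multivariable(cohort, "death_all", 24, "basic", "linear")
  keep <- cohort$cens_death_all_m24 == 0L
  d <- cohort[keep, ]
  fit <- lm(y_death_all_m24 ~ exposure + factor(rx_year) + male + age, data = d)
  iid_se <- 100 * sqrt(diag(vcov(fit)))[["exposure"]]
  expect_gt(est$se_beta, iid_se)
})

test_that("an all-zero outcome stratum raises a separation error", {
  sim <- generate_cohort(tiny_scenario(seed = 55))
  cohort <- build_cohort(sim)$cohort
  cohort$y_death_all_m3[] <- 0L
  expect_error(fit_multivariable(cohort, "death_all", 3, "basic", "logit"),
               "separation")
})

test_that("propensity scores reduce to closed forms in degenerate designs", {
  # covariates carry no signal: the score collapses to the marginal share
  sim <- generate_cohort(scenario_null(seed = 56))
  cohort <- build_cohort(sim)$cohort
  ps <- fit_propensity(cohort, covariates = c("male", "age", "charlson_any"))
  expect_lt(sd(ps$score), 0.02)
  expect_lt(abs(mean(ps$score) - mean(cohort$exposure)), 0.01)

  # one binary confounder: the saturated logistic score equals group means
  set.seed(57)
  n <- 4000
  c1 <- rbinom(n, 1, 0.4)
  x <- rbinom(n, 1, plogis(-1 + 1.5 * c1))
  toy <- tibble::tibble(patient_id = 1:n, physician_id = rep(1:40, 100),
                        exposure = x, c1 = c1)
  ps <- fit_propensity(toy, covariates = "c1")
  expect_equal(unique(round(ps$score[c1 == 1], 10)),
               round(mean(x[c1 == 1]), 10))
  expect_equal(unique(round(ps$score[c1 == 0], 10)),
               round(mean(x[c1 == 0]), 10))

  # a confounded scenario discriminates better than chance
  cohort2 <- build_cohort(generate_cohort(scenario_confounded(seed = 58,
    n_physicians = 100, patients_mean = 30)))$cohort
  ps2 <- fit_propensity(cohort2)
  r <- rank(ps2$score)
  n1 <- sum(cohort2$exposure == 1)
  n0 <- sum(cohort2$exposure == 0)
  auc <- (sum(r[cohort2$exposure == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  expect_gt(auc, 0.5)
})

test_that("nearest-neighbour matching is 1:1, deterministic, and balances", {
  cohort <- build_cohort(generate_cohort(scenario_confounded(seed = 59,
    n_physicians = 150, patients_mean = 30)))$cohort
  ps <- fit_propensity(cohort)
  m1 <- match_nearest(ps, seed = 5)
  m2 <- match_nearest(ps, seed = 5)
  expect_identical(m1$patient_id, m2$patient_id)
  # 1:1 without replacement: every control used at most once
  expect_equal(nrow(m1), 2 * sum(cohort$exposure))
  expect_false(any(duplicated(m1$patient_id)))
  bal <- attr(m1, "balance")
  expect_lt(mean(abs(bal$std_diff_after)), mean(abs(bal$std_diff_before)))

  # identical scores match to each other on a toy pair
  toy <- tibble::tibble(patient_id = 1:4, physician_id = c(1, 1, 2, 2),
                        exposure = c(1L, 0L, 0L, 0L))
  tps <- structure(list(model = NULL, score = c(0.5, 0.5, 0.9, 0.1),
                        data = toy, covariates = character(0),
                        cluster = "physician_id", common_support = TRUE),
                   class = "prefiv_ps")
  mt <- match_nearest(tps, seed = 1)
  expect_setequal(mt$patient_id, c(1L, 2L))
})

test_that("matching errors when controls are outnumbered", {
  toy <- tibble::tibble(patient_id = 1:3, physician_id = 1L,
                        exposure = c(1L, 1L, 0L))
  tps <- structure(list(model = NULL, score = c(0.5, 0.6, 0.4), data = toy,
                        covariates = character(0), cluster = "physician_id",
                        common_support = TRUE),
                   class = "prefiv_ps")
  expect_error(match_nearest(tps, seed = 1), "fewer comparator")
})

test_that("PS estimation recovers the effect under measured confounding only", {
  sc <- scenario_confounded(delta = 0.02, seed = 60)
  sc$unobserved <- list(beta_treat = 0, gamma = list(death_all = 0, hosp_all = 0))
  cohort <- build_cohort(generate_cohort(sc))$cohort
  ps <- fit_propensity(cohort)
  matched <- match_nearest(ps, seed = 6)
  est <- estimate_ps_outcome(matched, "death_all", 24, link = "linear")
  expect_lt(abs(est$estimate - 2), 4 * est$se_beta)
})
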