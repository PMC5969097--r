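test_that("physician preferences follow the configured Beta law", {
  # degenerate concentration: Beta(1e6, 1e6) pins every preference at 1/2
  sc <- scenario_config(n_physicians = 200,
                        preference = list(shape1 = 1e6, shape2 = 1e6), seed = 4)
  ph <- generate_physicians(sc)
  expect_true(all(abs(ph$preference - 0.5) < 0.01))

  # Beta(2, 4): mean 1/3, var = 2*4 / ((2+4)^2 (2+4+1))
  sc <- scenario_config(n_physicians = 10000,
                        preference = list(shape1 = 2, shape2 = 4), seed = 4)
  ph <- generate_physicians(sc)
  se <- sqrt((2 * 4 / (36 * 7)) / 10000)
  expect_lt(abs(mean(ph$preference) - 1 / 3), 3 * se)

  expect_error(scenario_config(preference = list(shape1 = -1, shape2 = 2)),
               "Beta")
})

test_that("generation is deterministic under the seed", {
  sc <- tiny_scenario(seed = 9)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  for (nm in c("prescriptions", "covariates", "events", "patients")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  c <- generate_cohort(tiny_scenario(seed = 10))
  expect_false(identical(a$covariates, c$covariates))
})

test_that("generated tables satisfy their schema invariants", {
  sim <- generate_cohort(tiny_scenario(seed = 2))
  expect_true(all(sim$prescriptions$drug_class %in% c("varenicline", "NRT")))
  # exactly one first-ever prescription per patient
  firsts <- tapply(sim$prescriptions$is_first_ever,
                   sim$prescriptions$patient_id, sum)
  expect_true(all(firsts == 1L))
  # death never recorded after the end of follow-up
  deaths <- sim$events[sim$events$class == "death", ]
  fu <- sim$patients$followup_end[match(deaths$patient_id,
                                        sim$patients$patient_id)]
  expect_true(all(deaths$day <= fu))
  # deprivation fifths on 1..5, binary flags on {0,1}
  expect_true(all(stats::na.omit(sim$covariates$imd) %in% 1:5))
  expect_true(all(sim$covariates$male %in% 0:1))
})

test_that("BMI and deprivation missingness hit their configured rates", {
  sc <- scenario_config(n_physicians = 150,
                        patients_per_physician = list(mean = 40, dispersion = 8),
                        missingness = list(bmi = 0.136, imd = 0.05), seed = 6)
  sim <- generate_cohort(sc)
  n <- nrow(sim$covariates)
  se_bmi <- sqrt(0.136 * 0.864 / n)
  expect_lt(abs(mean(is.na(sim$covariates$bmi)) - 0.136), 3 * se_bmi)
  se_imd <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(is.na(sim$covariates$imd)) - 0.05), 3 * se_imd)
})

test_that("with all effects and confounding off, arm differences are null", {
  sc <- scenario_null(seed = 3, n_physicians = 500, patients_mean = 100)
  sim <- generate_cohort(sc)
  cohort <- build_cohort(sim)$cohort
  # unadjusted risk difference in 24-month mortality
  keep <- cohort$cens_death_all_m24 == 0L
  y <- cohort$y_death_all_m24[keep]
  x <- cohort$exposure[keep]
  rd <- mean(y[x == 1]) - mean(y[x == 0])
  se <- sqrt(var(y[x == 1]) / sum(x == 1) + var(y[x == 0]) / sum(x == 0))
  expect_lt(abs(rd), 4 * se)
  # weight gain
  w <- cohort$weight_kg
  kp <- !is.na(w)
  dw <- mean(w[kp & cohort$exposure == 1]) - mean(w[kp & cohort$exposure == 0])
  sew <- sqrt(var(w[kp & cohort$exposure == 1]) / sum(kp & cohort$exposure == 1) +
                var(w[kp & cohort$exposure == 0]) / sum(kp & cohort$exposure == 0))
  expect_lt(abs(dw), 4 * sew)
})

test_that("healthy-user confounding makes the null drug look protective", {
  sim <- generate_cohort(scenario_confounded(delta = 0, seed = 8))
  cohort <- build_cohort(sim)$cohort
  keep <- cohort$cens_death_all_m24 == 0L
  y <- cohort$y_death_all_m24[keep]
  x <- cohort$exposure[keep]
  rd <- mean(y[x == 1]) - mean(y[x == 0])
  se <- sqrt(var(y[x == 1]) / sum(x == 1) + var(y[x == 0]) / sum(x == 0))
  expect_lt(rd + 2 * se, 0) # clearly negative although true effect is zero
})

test_that("excessive probability clipping triggers the scenario warning", {
  sc <- scenario_confounded(seed = 1, n_physicians = 60, patients_mean = 30)
  sc$unobserved$gamma$death_all <- -0.5 # wildly out of scale
  expect_warning(generate_cohort(sc), "clipped")
})

test_that("tables round-trip through CSV and parquet losslessly", {
  sim <- generate_cohort(tiny_scenario(seed = 12))
  for (fmt in c("csv", "parquet")) {
    dir <- withr::local_tempdir()
    write_tables(sim, dir, format = fmt)
    back <- read_tables(dir, format = fmt)
    for (nm in c("prescriptions", "covariates", "events", "patients")) {
      expect_equal(as.data.frame(back[[nm]]), as.data.frame(sim[[nm]]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("an empty cohort still writes valid header-only files", {
  sc <- tiny_scenario(seed = 1)
  sc$n_physicians <- 1
  sc$patients_per_physician <- list(mean = 1e-9, dispersion = 1)
  sim <- generate_cohort(sc)
  expect_equal(nrow(sim$covariates), 0L)
  dir <- withr::local_tempdir()
  write_tables(sim, dir, format = "csv")
  back <- read_tables(dir, format = "csv")
  expect_equal(nrow(back$prescriptions), 0L)
  expect_named(back$prescriptions,
               names(sim$prescriptions))
})
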