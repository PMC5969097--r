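window <- as.Date(c("2006-09-01", "2014-03-31"))

rx <- function(patient, day, class) {
  tibble::tibble(patient_id = patient, physician_id = 1L, practice_id = 1L,
                 issue_date = window[1] + day, drug_class = class,
                 is_first_ever = NA)
}

reg <- function(patients, days_before_window_start = -2000) {
  tibble::tibble(patient_id = patients, practice_id = 1L,
                 registration_date = window[1] + days_before_window_start)
}

test_that("eligibility rules exclude and retain the documented cases", {
  presc <- dplyr::bind_rows(
    rx(1L, 100, "NRT"), rx(1L, 100, "varenicline"), # same-day dual
    rx(2L, 300, "NRT"), rx(2L, -217, "NRT"), # pre-window script 517 d before
    rx(3L, 500, "varenicline"),              # clean, registered early
    rx(4L, 700, "NRT"), rx(4L, 100, "NRT"),  # both in window: day 100 is index
    rx(5L, 300, "NRT"), rx(5L, 300, "NRT")           # exact duplicate record
  )
  registration <- dplyr::bind_rows(
    reg(c(1L, 2L, 4L, 5L)),
    tibble::tibble(patient_id = 3L, practice_id = 1L,
                   registration_date = window[1] + 500 - 400) # 400 d history
  )
  res <- suppressMessages(apply_eligibility(presc, registration, window))
  ex <- setNames(res$exclusions$n, res$exclusions$reason)

  expect_equal(ex[["same_day_dual"]], 1L)
  expect_equal(ex[["washout"]], 1L)
  expect_equal(ex[["duplicate_records"]], 1L)
  expect_equal(ex[["recent_registration"]], 0L)
  expect_setequal(res$index$patient_id, c(3L, 4L, 5L))
  # patient 4's index is the first in-window script (the washout candidate)
  expect_equal(res$index$index_date[res$index$patient_id == 4L],
               window[1] + 100)
  # registration 364 days before index is excluded, 400 days is retained
  registration$registration_date[registration$patient_id == 3L] <-
    window[1] + 500 - 364
  res2 <- suppressMessages(apply_eligibility(presc, registration, window))
  ex2 <- setNames(res2$exclusions$n, res2$exclusions$reason)
  expect_equal(ex2[["recent_registration"]], 1L)
  expect_false(3L %in% res2$index$patient_id)
})

test_that("the exclusion ledger accounts for every patient", {
  sim <- generate_cohort(tiny_scenario(seed = 21))
  res <- apply_eligibility(sim$prescriptions, sim$registration,
                           sim$config$study_window)
  ex <- setNames(res$exclusions$n, res$exclusions$reason)
  n_patients <- length(unique(sim$prescriptions$patient_id))
  expect_equal(sum(ex[setdiff(names(ex), c("duplicate_records"))]), n_patients)
  expect_equal(ex[["retained"]], nrow(res$index))
})

make_index <- function(patients, exposure = 0L, index_day = 0) {
  tibble::tibble(patient_id = patients, physician_id = 1L, practice_id = 1L,
                 index_date = window[1] + index_day,
                 drug_class = ifelse(exposure == 1, "varenicline", "NRT"),
                 exposure = as.integer(exposure))
}

make_patients <- function(patients, followup_days, dereg_days = NULL) {
  if (is.null(dereg_days)) dereg_days <- followup_days
  tibble::tibble(patient_id = patients,
                 deregistration_date = window[1] + dereg_days,
                 followup_end = window[1] + followup_days)
}

test_that("outcome windows use half-open month boundaries at 30.4375 days", {
  linkage <- window[1] + 4000
  idx <- make_index(1L)
  pts <- make_patients(1L, 4000)
  # death at day 100: 3-month cutoff is 91.3125 days, so not a 3-month event
  ev <- tibble::tibble(patient_id = 1L, day = window[1] + 100,
                       class = "death", cause = "other")
  rows <- build_outcome_windows(idx, ev, pts, c(3, 6), linkage)
  expect_equal(rows$y_death_all_m3, 0L)
  expect_equal(rows$y_death_all_m6, 1L)
  expect_equal(rows$cens_death_all_m3, 0L)

  # boundary: day 91 falls inside (0, 91.3125], day 92 outside
  for (d in c(91, 92)) {
    ev$day <- window[1] + d
    rows <- build_outcome_windows(idx, ev, pts, c(3, 6), linkage)
    expect_equal(rows$y_death_all_m3, as.integer(d == 91))
  }
})

test_that("inadequate follow-up censors, and only non-events", {
  linkage <- window[1] + 300
  idx <- make_index(1L)
  pts <- make_patients(1L, 300)
  no_ev <- tibble::tibble(patient_id = integer(), day = as.Date(character()),
                          class = character(), cause = character())
  rows <- build_outcome_windows(
    idx, no_ev, pts, c(3, 6, 9, 12, 24), linkage,
    outcome_defs = list(death_all = list(class = "death", fatal = TRUE)))
  expect_equal(unname(unlist(rows[paste0("cens_death_all_m", c(3, 6, 9))])),
               c(0L, 0L, 0L))
  expect_equal(unname(unlist(rows[paste0("cens_death_all_m", c(12, 24))])),
               c(1L, 1L))
  expect_equal(unname(unlist(rows[paste0("y_death_all_m", c(3, 6, 9))])),
               c(0L, 0L, 0L))
})

test_that("mortality follows linkage, non-fatal outcomes follow registration", {
  linkage <- window[1] + 4000
  idx <- make_index(1L)
  # deregistered at day 50, death recorded at day 200 through linkage
  pts <- make_patients(1L, followup_days = 200, dereg_days = 50)
  ev <- tibble::tibble(patient_id = 1L, day = window[1] + 200,
                       class = "death", cause = "other")
  rows <- build_outcome_windows(idx, ev, pts, c(12), linkage)
  expect_equal(rows$y_death_all_m12, 1L)
  expect_equal(rows$cens_death_all_m12, 0L)

  # a hospitalization outcome for the same patient is censored at day 50
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(patient_id = 1L,
                                             day = window[1] + 40,
                                             class = "hosp", cause = "other"))
  rows2 <- build_outcome_windows(idx, ev2, pts, c(3, 12), linkage)
  expect_equal(rows2$y_hosp_all_m3, 1L)  # observed before deregistration
  expect_equal(rows2$cens_hosp_all_m12, 0L) # event seen, never censored
})

test_that("an event before the index date is rejected as leakage", {
  linkage <- window[1] + 4000
  idx <- make_index(1L, index_day = 100)
  pts <- make_patients(1L, 4000)
  ev <- tibble::tibble(patient_id = 1L, day = window[1] + 50,
                       class = "death", cause = "other")
  expect_error(build_outcome_windows(idx, ev, pts, c(3), linkage), "leakage")
})

test_that("cumulative outcomes are monotone over horizons", {
  sim <- generate_cohort(tiny_scenario(seed = 22))
  cohort <- build_cohort(sim)$cohort
  for (o in c("death_all", "hosp_all")) {
    y <- as.matrix(cohort[paste0("y_", o, "_m", c(3, 6, 9, 12, 24, 48))])
    cens <- as.matrix(cohort[paste0("cens_", o, "_m", c(3, 6, 9, 12, 24, 48))])
    # once an event has happened it stays happened at longer horizons
    expect_true(all(apply(y, 1, function(r) !is.unsorted(r))))
    # a censored horizon never carries an event
    expect_true(all(y[cens == 1L] == 0L))
  }
})

test_that("cohort construction is invariant to input row order", {
  sim <- generate_cohort(tiny_scenario(seed = 23))
  a <- build_cohort(sim)$cohort
  perm <- withr::with_seed(99, sample(nrow(sim$prescriptions)))
  sim$prescriptions <- sim$prescriptions[perm, ]
  b <- build_cohort(sim)$cohort
  expect_equal(as.data.frame(a), as.data.frame(b), ignore_attr = TRUE)
})

test_that("derived covariate flags follow their definitions", {
  sim <- generate_cohort(tiny_scenario(seed = 24))
  cohort <- build_cohort(sim)$cohort
  expect_equal(cohort$frequent_attender,
               as.integer(cohort$visits_prior_year > 5))
  expect_equal(cohort$rx_year, as.integer(format(cohort$index_date, "%Y")))
  # attach_covariates refuses incomplete covariate tables
  elig <- apply_eligibility(sim$prescriptions, sim$registration,
                            sim$config$study_window)
  rows <- build_outcome_windows(elig$index, sim$events, sim$patients,
                                c(3), sim$config$linkage_end)
  expect_error(attach_covariates(rows, sim$covariates[-1, ]), "missing patient")
})
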