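#' Baseline covariate specification for the synthetic prescribing world
#'
#' One row per baseline covariate: its marginal distribution, its effect on
#' the treatment log-odds (`beta_treat`, channeling: negative values make the
#' covariate push patients towards the comparator drug) and its effect on each
#' binary outcome's cumulative risk at the reference horizon
#' (`gamma_<outcome>`, absolute risk shift per unit of the covariate).
#'
#' The default set mirrors the baseline table of a UK smoking-cessation
#' prescribing cohort: demographics, deprivation fifth, consultation
#' frequency, prior psychotropic/cardiovascular/diabetic prescriptions and
#' prior diagnoses. Prevalences are set to the whole-cohort margins of that
#' table; treatment effects are signed so that patients prescribed
#' varenicline come out healthier at baseline in every comorbidity flag,
#' the channeling pattern the generator is designed to emulate.
#'
#' @return a tibble with columns `name`, `type` (`binary`, `continuous`,
#'   `ordinal`, `count`), `mean`, `sd`, `dispersion`, `levels_prob`
#'   (list-column, ordinal types only), `beta_treat`, `gamma_death_all`,
#'   `gamma_hosp_all`.
#' @export
default_confounders <- function() {
  tb <- tibble::tribble(
    ~name,                    ~type,        ~mean,  ~sd, ~beta_treat, ~gamma_death_all, ~gamma_hosp_all,
    "male",                   "binary",     0.475,   NA,       0.15,            0.004,          0.010,
    "age",                    "continuous", 45,      14,      -0.012,           0.0004,         0.002,
    "bmi",                    "continuous", 25.6,     7,      -0.005,           0.0001,         0.0008,
    "alcohol_misuse",         "binary",     0.065,   NA,      -0.35,            0.006,          0.030,
    "drug_misuse",            "binary",     0.026,   NA,      -0.45,            0.008,          0.040,
    "imd",                    "ordinal",    NA,      NA,      -0.06,            0.0015,         0.006,
    "visits_prior_year",      "count",      6,       NA,      -0.02,            0.0004,         0.003,
    "prior_hypnotics",        "binary",     0.193,   NA,      -0.20,            0.003,          0.015,
    "prior_antipsychotic",    "binary",     0.181,   NA,      -0.35,            0.004,          0.015,
    "prior_antidepressant",   "binary",     0.476,   NA,      -0.25,            0.002,          0.010,
    "prior_statin",           "binary",     0.180,   NA,      -0.30,            0.004,          0.015,
    "prior_antihypertensive", "binary",     0.194,   NA,      -0.25,            0.003,          0.015,
    "prior_diabetes_med",     "binary",     0.083,   NA,      -0.35,            0.005,          0.020,
    "prior_self_harm",        "binary",     0.098,   NA,      -0.20,            0.004,          0.015,
    "prior_mi",               "binary",     0.026,   NA,      -0.60,            0.008,          0.030,
    "prior_copd",             "binary",     0.074,   NA,      -0.30,            0.008,          0.025,
    "charlson_any",           "binary",     0.362,   NA,      -0.25,            0.006,          0.020,
    "psych_any",              "binary",     0.460,   NA,      -0.30,            0.003,          0.012
  )
  tb$dispersion <- ifelse(tb$type == "count", 1.5, NA_real_)
  # deprivation fifths 1 (least deprived) .. 5 (most deprived); the most
  # deprived fifth is over-represented among smoking-cessation patients
  tb$levels_prob <- ifelse(tb$type == "ordinal",
    list(c(0.14, 0.18, 0.20, 0.23, 0.25)), list(NULL)
  )
  tb
}

#' Define a synthetic prescribing scenario
#'
#' A scenario is the complete parameterisation of the synthetic world:
#' prescriber panel, latent physician preferences, observed confounders, an
#' unobserved healthy-user axis, true causal effects, per-horizon baseline
#' risks and the observation process (follow-up, missingness, records that
#' fail eligibility).
#'
#' Physician preference is a continuous latent probability `p_g` drawn from a
#' Beta distribution; the default `Beta(1.02, 2.06)` is calibrated so that
#' (i) the marginal varenicline share is about 33% and (ii) the expected
#' percentage-point increase in prescribing varenicline after a varenicline
#' prescription to the previous patient, `Var(p)/(E[p](1 - E[p]))`, is about
#' 24.5 points — both features of the prescribing landscape the generator
#' emulates.
#'
#' Binary outcomes are generated risk-difference-natively. Each patient
#' carries a structural risk shift
#' `s = delta * X + sum(gamma_C * (C - mean(C))) + gamma_U * U + e_g`
#' expressed on the absolute risk scale at the reference horizon
#' (`effect_reference_horizon`, default 24 months). Per-horizon event
#' probability is `baseline_t * max(0, 1 + s / baseline_ref)` (capped at 1),
#' i.e. covariate and treatment effects scale proportionally with the
#' cumulative baseline so probabilities stay in range and cumulative risks
#' stay monotone in the horizon; at the reference horizon the configured
#' `delta` and `gamma` values are exactly the absolute risk differences. A
#' constant-shift variant (`effect_scaling = "constant"`) implements
#' `baseline_t + s` with clipping, for stress tests.
#'
#' @param n_physicians number of prescribers.
#' @param patients_per_physician list(mean, dispersion): negative-binomial
#'   patient panel size per prescriber.
#' @param preference list(shape1, shape2): Beta law of the latent preference.
#' @param confounders covariate specification, see [default_confounders()].
#' @param unobserved list(beta_treat, gamma): the unmeasured healthy-user
#'   confounder `U ~ N(0,1)`; `beta_treat` is its treatment log-odds shift
#'   per SD, `gamma` a named list of absolute risk shifts per SD at the
#'   reference horizon, one per binary outcome.
#' @param true_effects named list of causal effects of varenicline vs NRT:
#'   absolute risk differences at the reference horizon for binary outcomes,
#'   kilograms for `weight_kg`, log rate ratio for `consult_rate_log`.
#' @param baseline_risks named list (one element per binary outcome) of
#'   per-horizon cumulative event probabilities under NRT, non-decreasing.
#' @param horizons follow-up horizons in months, strictly increasing.
#' @param effect_reference_horizon horizon (months) at which configured
#'   effects equal absolute risk differences; must be in `horizons`.
#' @param effect_scaling `"proportional"` (default) or `"constant"`, see
#'   Details.
#' @param physician_outcome_sd SD of a physician-level outcome-risk intercept
#'   (drawn independently of preference, so instrument validity holds).
#' @param study_window Date vector length 2: first and last prescription day.
#' @param linkage_end Date: end of linked event follow-up (deaths observed
#'   to this day regardless of deregistration).
#' @param followup list(deregister_rate): fraction of patients who deregister
#'   at a uniform time between index and linkage end.
#' @param missingness list(bmi, imd): fractions set missing completely at
#'   random.
#' @param ineligible list(recent_registration, prior_script, same_day_dual):
#'   fractions of patients given records that fail each eligibility rule.
#' @param secular_trend log-odds shift in preference per calendar year after
#'   the window start (0 disables).
#' @param seed integer seed; identical scenarios produce byte-identical
#'   tables.
#' @return an object of class `prefiv_scenario` (a validated list).
#' @seealso [generate_cohort()], [scenario_null()], [scenario_confounded()]
#' @export
scenario_config <- function(n_physicians = 150,
                            patients_per_physician = list(mean = 40, dispersion = 8),
                            preference = list(shape1 = 1.02, shape2 = 2.06),
                            confounders = default_confounders(),
                            unobserved = list(
                              beta_treat = 0.5,
                              gamma = list(death_all = -0.006, hosp_all = -0.04)
                            ),
                            true_effects = list(
                              death_all = 0, hosp_all = 0,
                              weight_kg = 1.14, consult_rate_log = -0.217
                            ),
                            baseline_risks = list(
                              death_all = c(`3` = 0.0035, `6` = 0.0072, `9` = 0.011,
                                            `12` = 0.015, `24` = 0.029, `48` = 0.055),
                              hosp_all = c(`3` = 0.08, `6` = 0.13, `9` = 0.17,
                                           `12` = 0.21, `24` = 0.33, `48` = 0.48)
                            ),
                            horizons = c(3, 6, 9, 12, 24, 48),
                            effect_reference_horizon = 24,
                            effect_scaling = c("proportional", "constant"),
                            physician_outcome_sd = 0.004,
                            study_window = as.Date(c("2006-09-01", "2014-03-31")),
                            linkage_end = as.Date("2016-03-31"),
                            followup = list(deregister_rate = 0.15),
                            missingness = list(bmi = 0.136, imd = 0.001),
                            ineligible = list(recent_registration = 0.02,
                                              prior_script = 0.03,
                                              same_day_dual = 0.01),
                            secular_trend = 0,
                            seed = 1L) {
  cfg <- list(
    n_physicians = n_physicians,
    patients_per_physician = patients_per_physician,
    preference = preference,
    confounders = confounders,
    unobserved = unobserved,
    true_effects = true_effects,
    baseline_risks = baseline_risks,
    horizons = horizons,
    effect_reference_horizon = effect_reference_horizon,
    effect_scaling = match.arg(effect_scaling),
    physician_outcome_sd = physician_outcome_sd,
    study_window = as.Date(study_window),
    linkage_end = as.Date(linkage_end),
    followup = followup,
    missingness = missingness,
    ineligible = ineligible,
    secular_trend = secular_trend,
    seed = as.integer(seed)
  )
  class(cfg) <- "prefiv_scenario"
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  if (!inherits(cfg, "prefiv_scenario")) {
    abort_prefiv("expected a `prefiv_scenario`; build one with scenario_config()")
  }
  with(cfg, {
    if (!is.numeric(n_physicians) || n_physicians < 1) {
      abort_prefiv("n_physicians must be a positive count")
    }
    if (!(preference$shape1 > 0 && preference$shape2 > 0)) {
      abort_prefiv("invalid preference distribution: Beta parameters must be > 0")
    }
    if (patients_per_physician$mean <= 0 || patients_per_physician$dispersion <= 0) {
      abort_prefiv("patients_per_physician mean and dispersion must be > 0")
    }
    if (is.unsorted(horizons, strictly = TRUE) || any(horizons <= 0)) {
      abort_prefiv("horizons must be strictly increasing and positive")
    }
    if (!effect_reference_horizon %in% horizons) {
      abort_prefiv("effect_reference_horizon must be one of the configured horizons")
    }
    for (o in names(baseline_risks)) {
      b <- baseline_risks[[o]]
      if (length(b) != length(horizons)) {
        abort_prefiv("baseline_risks$", o, " must have one entry per horizon")
      }
      if (any(b < 0 | b > 1)) {
        abort_prefiv("baseline_risks$", o, " must be probabilities in [0, 1]")
      }
      if (is.unsorted(b)) {
        abort_prefiv("baseline_risks$", o,
                     " must be non-decreasing in horizon (cumulative incidence)")
      }
      if (is.null(true_effects[[o]])) {
        abort_prefiv("true_effects$", o, " missing for configured outcome")
      }
      if (is.null(unobserved$gamma[[o]])) {
        abort_prefiv("unobserved$gamma$", o, " missing for configured outcome")
      }
    }
    for (p in c(missingness$bmi, missingness$imd,
                ineligible$recent_registration, ineligible$prior_script,
                ineligible$same_day_dual, followup$deregister_rate)) {
      if (p < 0 || p > 1) abort_prefiv("all rate parameters must lie in [0, 1]")
    }
    need <- c("name", "type", "mean", "sd", "beta_treat")
    if (!all(need %in% names(confounders))) {
      abort_prefiv("confounders table must have columns ",
                   paste(need, collapse = ", "))
    }
    bad <- setdiff(confounders$type, c("binary", "continuous", "ordinal", "count"))
    if (length(bad)) abort_prefiv("unknown confounder type: ", bad[1])
    if (study_window[2] <= study_window[1]) abort_prefiv("empty study window")
    if (linkage_end < study_window[2]) {
      abort_prefiv("linkage_end must not precede the study window end")
    }
  })
  cfg
}

#' @export
print.prefiv_scenario <- function(x, ...) {
  cat("<prefiv_scenario>\n")
  cat(sprintf("  physicians: %d, patients/physician ~ NB(mean %.0f, disp %.1f)\n",
              x$n_physicians, x$patients_per_physician$mean,
              x$patients_per_physician$dispersion))
  cat(sprintf("  preference: Beta(%.3g, %.3g); unobserved beta_treat = %.2f\n",
              x$preference$shape1, x$preference$shape2, x$unobserved$beta_treat))
  cat(sprintf("  outcomes: %s; horizons (months): %s\n",
              paste(names(x$baseline_risks), collapse = ", "),
              paste(x$horizons, collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Effect-free, confounding-free scenario
#'
#' Covariates are drawn with the usual margins but have no effect on
#' treatment or outcomes, the unobserved confounder is switched off and all
#' true effects are zero. Every arm-difference statistic should then sit
#' within Monte-Carlo error of its null value — the generator's calibration
#' scenario.
#'
#' @param seed integer seed.
#' @param n_physicians,patients_mean panel size controls.
#' @return a `prefiv_scenario`.
#' @export
scenario_null <- function(seed = 1L, n_physicians = 250, patients_mean = 40) {
  conf <- default_confounders()
  conf$beta_treat <- 0
  conf$gamma_death_all <- 0
  conf$gamma_hosp_all <- 0
  scenario_config(
    n_physicians = n_physicians,
    patients_per_physician = list(mean = patients_mean, dispersion = 8),
    confounders = conf,
    unobserved = list(beta_treat = 0, gamma = list(death_all = 0, hosp_all = 0)),
    true_effects = list(death_all = 0, hosp_all = 0,
                        weight_kg = 0, consult_rate_log = 0),
    physician_outcome_sd = 0,
    missingness = list(bmi = 0, imd = 0),
    seed = seed
  )
}

#' Unmeasured-confounding stress scenario
#'
#' The healthy-user stress test: a latent health axis `U ~ N(0,1)` shifts the
#' treatment log-odds by +0.5 per SD and the reference-horizon mortality risk
#' by -2 per 100 per SD, on top of a small measured covariate set (sex, age,
#' chronic-disease flag). The true causal mortality effect defaults to zero,
#' so conditional-exchangeability estimators are biased by design while a
#' valid preference instrument is not. Baseline mortality is raised relative
#' to the default scenario so that a 2-per-100 latent shift rarely drives
#' per-horizon probabilities out of range. No missingness: this scenario
#' isolates confounding, not incomplete data.
#'
#' @param delta true causal risk difference (absolute, at the reference
#'   horizon) of varenicline on mortality; 0 by default.
#' @param seed integer seed.
#' @param n_physicians,patients_mean panel size controls (defaults give
#'   roughly 20,000 patients).
#' @return a `prefiv_scenario`.
#' @export
scenario_confounded <- function(delta = 0, seed = 1L,
                                n_physicians = 400, patients_mean = 50) {
  conf <- tibble::tribble(
    ~name,          ~type,        ~mean, ~sd, ~beta_treat, ~gamma_death_all, ~gamma_hosp_all,
    "male",         "binary",     0.475,  NA,        0.20,            0.004,           0.010,
    "age",          "continuous", 45,     14,       -0.020,           0.0008,          0.003,
    "charlson_any", "binary",     0.362,  NA,       -0.40,            0.015,           0.040
  )
  conf$dispersion <- NA_real_
  conf$levels_prob <- list(NULL)
  scenario_config(
    n_physicians = n_physicians,
    patients_per_physician = list(mean = patients_mean, dispersion = 8),
    confounders = conf,
    unobserved = list(beta_treat = 0.5,
                      gamma = list(death_all = -0.02, hosp_all = -0.04)),
    true_effects = list(death_all = delta, hosp_all = 0,
                        weight_kg = 1.14, consult_rate_log = -0.217),
    baseline_risks = list(
      death_all = c(`3` = 0.012, `6` = 0.022, `9` = 0.032,
                    `12` = 0.040, `24` = 0.060, `48` = 0.090),
      hosp_all = c(`3` = 0.08, `6` = 0.13, `9` = 0.17,
                   `12` = 0.21, `24` = 0.33, `48` = 0.48)
    ),
    missingness = list(bmi = 0, imd = 0),
    followup = list(deregister_rate = 0.10),
    seed = seed
  )
}
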