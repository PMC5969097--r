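#' Apply new-user eligibility rules to raw prescriptions
#'
#' Implements the index-prescription (new-user, intention-to-treat) design:
#' each retained patient contributes exactly one index prescription — their
#' first smoking-cessation script inside the study window — and is excluded
#' when any of the following holds, in this order of precedence:
#'
#' 1. `same_day_dual`: both drug classes issued on the index calendar date;
#' 2. `washout`: any cessation prescription in the `washout_days` before the
#'    index date (a prior script `gap` days earlier excludes the patient when
#'    `gap < washout_days`, i.e. retention requires at least `washout_days`
#'    prescription-free days);
#' 3. `recent_registration`: registered at the practice fewer than
#'    `min_registration_days` before index, leaving too little history to
#'    define baseline covariates.
#'
#' Exact duplicate records (same patient, date and drug class) are removed
#' first and logged. The returned exclusion ledger accounts for every
#' patient: reasons plus retained sum to the number of distinct patients.
#'
#' @param prescriptions tibble of prescription records (`patient_id`,
#'   `physician_id`, `practice_id`, `issue_date`, `drug_class`). Input order
#'   is irrelevant; records are sorted internally.
#' @param registration tibble with `patient_id`, `registration_date`; every
#'   patient with an in-window prescription must appear.
#' @param study_window Date vector length 2.
#' @param washout_days washout window length in days (default 548, 18
#'   months).
#' @param min_registration_days minimum registration history in days.
#' @return list with `index` (one row per retained patient: ids,
#'   `index_date`, `drug_class`, `exposure` 1 = varenicline) and
#'   `exclusions` (tibble reason / n, including `duplicate_records` counted
#'   at record level and `retained`).
#' @export
apply_eligibility <- function(prescriptions, registration, study_window,
                              washout_days = 548L,
                              min_registration_days = 365L) {
  dt <- as.data.table(prescriptions)
  n_raw <- nrow(dt)
  dt <- unique(dt, by = c("patient_id", "issue_date", "drug_class"))
  n_dup <- n_raw - nrow(dt)
  if (n_dup > 0) {
    message(sprintf("removed %d duplicate prescription record(s)", n_dup))
  }
  window_start <- as.Date(study_window[1])
  window_end <- as.Date(study_window[2])

  inw <- dt[dt$issue_date >= window_start & dt$issue_date <= window_end, ]
  n_patients <- length(unique(dt$patient_id))
  if (nrow(inw) == 0) {
    return(list(
      index = tibble::tibble(patient_id = integer(), physician_id = integer(),
                             practice_id = integer(),
                             index_date = as.Date(character()),
                             drug_class = character(), exposure = integer()),
      exclusions = tibble::tibble(
        reason = c("duplicate_records", "no_in_window_prescription",
                   "same_day_dual", "washout", "recent_registration", "retained"),
        n = c(n_dup, n_patients, 0L, 0L, 0L, 0L)
      )
    ))
  }

  setorderv(inw, c("patient_id", "issue_date", "drug_class"))
  idx <- inw[, list(index_date = min(issue_date)), by = "patient_id"]
  n_outside <- n_patients - nrow(idx)

  # same-day dual prescribing, checked on the calendar date of index
  at_index <- merge(inw, idx, by = "patient_id")
  at_index <- at_index[at_index$issue_date == at_index$index_date, ]
  n_class <- at_index[, list(k = length(unique(drug_class))), by = "patient_id"]
  dual_ids <- n_class$patient_id[n_class$k > 1L]

  # washout: any prescription (in or out of window) within washout_days
  prior <- merge(dt, idx, by = "patient_id")
  gap <- as.integer(prior$index_date - prior$issue_date)
  washout_ids <- unique(prior$patient_id[gap > 0L & gap < washout_days])
  washout_ids <- setdiff(washout_ids, dual_ids)

  reg <- as.data.table(registration)[, c("patient_id", "registration_date")]
  idx <- merge(idx, reg, by = "patient_id", all.x = TRUE)
  if (anyNA(idx$registration_date)) {
    abort_prefiv("registration table is missing ",
                 sum(is.na(idx$registration_date)), " indexed patient(s)")
  }
  reg_days <- as.integer(idx$index_date - idx$registration_date)
  recent_ids <- setdiff(idx$patient_id[reg_days < min_registration_days],
                        c(dual_ids, washout_ids))

  drop_ids <- c(dual_ids, washout_ids, recent_ids)
  keep <- idx[!idx$patient_id %in% drop_ids, c("patient_id", "index_date")]

  first_rec <- at_index[!duplicated(at_index$patient_id), ]
  index <- merge(keep, first_rec[, c("patient_id", "physician_id",
                                     "practice_id", "issue_date", "drug_class")],
                 by = "patient_id")
  index$issue_date <- NULL
  index <- tibble::as_tibble(index)
  index$exposure <- as.integer(index$drug_class == "varenicline")
  index <- dplyr::arrange(index, .data$patient_id)

  exclusions <- tibble::tibble(
    reason = c("duplicate_records", "no_in_window_prescription",
               "same_day_dual", "washout", "recent_registration", "retained"),
    n = c(n_dup, n_outside, length(dual_ids), length(washout_ids),
          length(recent_ids), nrow(index))
  )
  list(index = index, exclusions = exclusions)
}

default_outcome_defs <- function(events) {
  defs <- list()
  for (cls in sort(unique(events$class))) {
    defs[[paste0(cls, "_all")]] <- list(class = cls, cause = NULL,
                                        fatal = cls == "death")
  }
  defs
}

#' Per-horizon outcome and censoring indicators
#'
#' For each outcome definition and each horizon `t` (months), sets
#' `y_<outcome>_m<t> = 1` when an event of that class occurs in the window
#' `(index, index + t * 30.4375 days]` — an event on the boundary day counts
#' — and a censoring flag `cens_<outcome>_m<t> = 1` when the patient's
#' available follow-up is shorter than the window and no event was observed
#' inside it. Fatal outcomes are censored against the linked mortality
#' follow-up end (`linkage_end`), never against practice deregistration;
#' non-fatal outcomes are censored at deregistration or death, whichever
#' comes first.
#'
#' @param index eligible index prescriptions from [apply_eligibility()].
#' @param events event table (`patient_id`, `day`, `class`, `cause`).
#' @param patients patient table with `deregistration_date`, `followup_end`.
#' @param horizons months, strictly increasing.
#' @param linkage_end Date, end of linked mortality follow-up.
#' @param outcome_defs named list; each element `list(class=, cause=, fatal=)`
#'   defines one outcome. Defaults to one all-cause outcome per event class
#'   present.
#' @return tibble: ids, `index_date`, `exposure`, `followup_days` and
#'   per-outcome per-horizon `y_*` / `cens_*` indicator columns, with
#'   attributes `horizons` and `outcomes`.
#' @export
build_outcome_windows <- function(index, events, patients, horizons,
                                  linkage_end, outcome_defs = NULL) {
  if (is.unsorted(horizons, strictly = TRUE)) {
    abort_prefiv("horizons must be strictly increasing")
  }
  outcome_defs <- outcome_defs %||% default_outcome_defs(events)
  cutoffs <- months_to_days(horizons)

  pt <- merge(as.data.table(index),
              as.data.table(patients)[, c("patient_id", "deregistration_date",
                                          "followup_end")],
              by = "patient_id")
  setorderv(pt, "patient_id")
  ev <- merge(as.data.table(events),
              pt[, c("patient_id", "index_date")], by = "patient_id")
  if (nrow(ev) && any(ev$day < ev$index_date)) {
    abort_prefiv("event precedes index date for patient(s) ",
                 paste(head(unique(ev$patient_id[ev$day < ev$index_date]), 3),
                       collapse = ", "),
                 "; upstream leakage suspected")
  }

  n <- nrow(pt)
  avail_fatal <- as.numeric(as.Date(linkage_end) - pt$index_date)
  avail_nonfatal <- as.numeric(pmin(pt$deregistration_date, pt$followup_end) -
                                 pt$index_date)
  out <- list()
  for (o in names(outcome_defs)) {
    def <- outcome_defs[[o]]
    sel <- ev[ev$class == def$class, ]
    if (!is.null(def$cause)) sel <- sel[sel$cause %in% def$cause, ]
    eday <- rep(NA_real_, n)
    if (nrow(sel)) {
      first_ev <- sel[, list(eday = min(as.numeric(day - index_date))),
                      by = "patient_id"]
      eday[match(first_ev$patient_id, pt$patient_id)] <- first_ev$eday
    }
    avail <- if (isTRUE(def$fatal)) avail_fatal else avail_nonfatal
    for (j in seq_along(horizons)) {
      y <- as.integer(!is.na(eday) & eday <= cutoffs[j])
      cens <- as.integer(avail < cutoffs[j] & y == 0L)
      out[[sprintf("y_%s_m%d", o, horizons[j])]] <- y
      out[[sprintf("cens_%s_m%d", o, horizons[j])]] <- cens
    }
  }

  res <- dplyr::bind_cols(
    tibble::as_tibble(pt[, c("patient_id", "physician_id", "practice_id",
                             "index_date", "drug_class", "exposure")]),
    tibble::tibble(
      followup_days = as.numeric(pt$followup_end - pt$index_date)
    ),
    tibble::as_tibble(out)
  )
  attr(res, "horizons") <- horizons
  attr(res, "outcomes") <- names(outcome_defs)
  res
}

#' Attach baseline covariates to cohort rows
#'
#' Joins the covariate table (frozen at index: the generator draws them as
#' baseline values) and derives analysis flags: `frequent_attender`
#' (more than five primary-care consultations in the prior year) and
#' `rx_year` (calendar year of first prescription). Latent columns
#' (`u_latent`) are carried through for oracle checks but are never part of
#' the adjustment covariate set.
#'
#' @param rows cohort rows from [build_outcome_windows()].
#' @param covariates baseline covariate table, one row per patient.
#' @return `rows` with covariate columns and a `covariates` attribute naming
#'   the adjustment set.
#' @export
attach_covariates <- function(rows, covariates) {
  miss <- setdiff(rows$patient_id, covariates$patient_id)
  if (length(miss)) {
    abort_prefiv("covariate table is missing patient(s) ",
                 paste(head(miss, 3), collapse = ", "))
  }
  covs <- covariates[match(rows$patient_id, covariates$patient_id), ]
  drop <- intersect(c("patient_id", "physician_id", "practice_id"), names(covs))
  covs <- covs[, setdiff(names(covs), drop), drop = FALSE]
  out <- dplyr::bind_cols(rows, covs)
  if ("visits_prior_year" %in% names(out)) {
    out$frequent_attender <- as.integer(out$visits_prior_year > 5)
  }
  out$rx_year <- as.integer(format(out$index_date, "%Y"))
  covariate_names <- setdiff(names(covs), "u_latent")
  if ("frequent_attender" %in% names(out)) {
    covariate_names <- c(covariate_names, "frequent_attender")
  }
  for (a in c("horizons", "outcomes")) attr(out, a) <- attr(rows, a)
  attr(out, "covariates") <- covariate_names
  out
}

#' Build the analysis cohort from a synthetic world
#'
#' Convenience wrapper chaining [apply_eligibility()],
#' [build_outcome_windows()] and [attach_covariates()], and joining the
#' continuous outcomes (weight at one year, two-year consultation count).
#'
#' @param sim a `prefiv_sim` from [generate_cohort()].
#' @param horizons months; defaults to the scenario's horizons.
#' @param outcome_defs see [build_outcome_windows()].
#' @return list with `cohort` (one analysis row per eligible patient) and
#'   `exclusions` (the eligibility ledger).
#' @export
build_cohort <- function(sim, horizons = NULL, outcome_defs = NULL) {
  stopifnot(inherits(sim, "prefiv_sim"))
  horizons <- horizons %||% sim$config$horizons
  elig <- apply_eligibility(sim$prescriptions, sim$registration,
                            sim$config$study_window)
  rows <- build_outcome_windows(elig$index, sim$events, sim$patients,
                                horizons, sim$config$linkage_end, outcome_defs)
  cohort <- attach_covariates(rows, sim$covariates)
  extra <- sim$patients[match(cohort$patient_id, sim$patients$patient_id),
                        c("weight_kg", "consult_count")]
  at <- attributes(cohort)
  cohort <- dplyr::bind_cols(cohort, extra)
  for (a in c("horizons", "outcomes", "covariates")) {
    attr(cohort, a) <- at[[a]]
  }
  list(cohort = cohort, exclusions = elig$exclusions)
}
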