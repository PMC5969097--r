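#' Draw the prescriber panel
#'
#' Each physician receives a latent preference `p_g` — their propensity to
#' issue varenicline rather than NRT to an exchangeable patient — drawn
#' i.i.d. from the scenario's Beta law. Physicians are nested in practices
#' (three per practice).
#'
#' @param config a `prefiv_scenario`.
#' @return tibble with `physician_id`, `practice_id`, `preference`.
#' @export
#' @examples
#' generate_physicians(scenario_config(n_physicians = 5))
generate_physicians <- function(config) {
  config <- validate_scenario(config)
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- as.integer(config$n_physicians)
    p <- rbeta(n, config$preference$shape1, config$preference$shape2)
    # guard against numerically degenerate draws before the logit link
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    tibble::tibble(
      physician_id = seq_len(n),
      practice_id = (seq_len(n) - 1L) %/% 3L + 1L,
      preference = p
    )
  })
}

# map an outcome label to the event class the generator records
event_class_of <- function(outcome) sub("_all$", "", outcome)

draw_covariates <- function(conf, n) {
  values <- vector("list", nrow(conf))
  centered <- matrix(0, nrow = n, ncol = nrow(conf),
                     dimnames = list(NULL, conf$name))
  for (i in seq_len(nrow(conf))) {
    row <- conf[i, ]
    v <- switch(row$type,
      binary = rbinom(n, 1L, row$mean),
      continuous = rnorm(n, row$mean, row$sd),
      ordinal = {
        probs <- row$levels_prob[[1]]
        sample.int(length(probs), n, replace = TRUE, prob = probs)
      },
      count = rnbinom(n, size = row$dispersion, mu = row$mean)
    )
    mu <- switch(row$type,
      ordinal = sum(row$levels_prob[[1]] * seq_along(row$levels_prob[[1]])),
      row$mean
    )
    values[[i]] <- v
    centered[, i] <- v - mu
  }
  names(values) <- conf$name
  list(values = tibble::as_tibble(values), centered = centered)
}

#' Generate a synthetic prescribing world
#'
#' Simulates prescription-level, covariate and event tables for a panel of
#' prescribers with latent drug preferences. Treatment assignment follows
#' `logit Pr(varenicline) = logit(p_g) + sum(beta_C (C - mean C)) + beta_U U`,
#' so a patient's drug depends on their physician's preference, their
#' observed baseline covariates and an unobserved health axis `U` — the
#' healthy-user structure that motivates preference-based instruments.
#' Binary outcomes are risk-difference-native (see [scenario_config()]);
#' weight at one year is Gaussian with a mean shift for the treated arm and
#' the two-year consultation count is negative-binomial with a log-rate
#' shift.
#'
#' A configurable fraction of patients receives records that violate the
#' downstream eligibility rules (registration within a year of index, a
#' cessation prescription during the washout window, same-day dual
#' prescriptions) so cohort construction can be exercised realistically.
#'
#' Deaths are recorded whenever they occur before the linked follow-up end,
#' even after deregistration (mirroring national mortality linkage);
#' hospitalizations and measurements are only recorded while the patient is
#' registered and alive.
#'
#' @param config a `prefiv_scenario`.
#' @return an object of class `prefiv_sim`: a list of tibbles
#'   `prescriptions` (patient_id, physician_id, practice_id, issue_date,
#'   drug_class, is_first_ever), `covariates` (baseline covariates plus the
#'   latent `u_latent`, which analysis code must never adjust for),
#'   `events` (patient_id, day, class, cause), `registration`,
#'   `patients` (follow-up ends, weight and consultation outcomes) and
#'   `physicians`, plus the `config`.
#' @export
generate_cohort <- function(config) {
  config <- validate_scenario(config)
  phys <- generate_physicians(config)

  withr::with_seed(derive_seed(config$seed, 2L), {
    n_i <- rnbinom(nrow(phys), size = config$patients_per_physician$dispersion,
                   mu = config$patients_per_physician$mean)
    n <- sum(n_i)
    g <- rep.int(phys$physician_id, n_i)

    window_start <- config$study_window[1]
    window_days <- as.integer(config$study_window[2] - window_start)
    linkage_day <- as.integer(config$linkage_end - window_start)

    index_day <- runif_int(n, 0L, window_days)

    cov <- draw_covariates(config$confounders, n)
    u <- rnorm(n)

    pref_logit <- qlogis(phys$preference)[g] +
      config$secular_trend * index_day / 365.25
    eta <- pref_logit +
      drop(cov$centered %*% config$confounders$beta_treat) +
      config$unobserved$beta_treat * u
    x <- rbinom(n, 1L, plogis(eta))

    phys_eff <- rnorm(nrow(phys), 0, config$physician_outcome_sd)[g]

    cutoffs <- months_to_days(config$horizons)
    ref_j <- match(config$effect_reference_horizon, config$horizons)
    day_lo <- c(1, floor(cutoffs[-length(cutoffs)]) + 1)
    day_hi <- pmax(floor(cutoffs), day_lo)

    # --- binary outcome event times ------------------------------------
    n_clipped <- 0L
    n_draws <- 0L
    event_days <- list()
    for (o in names(config$baseline_risks)) {
      b <- unname(config$baseline_risks[[o]])
      gamma_col <- paste0("gamma_", o)
      gam <- if (gamma_col %in% names(config$confounders)) {
        config$confounders[[gamma_col]]
      } else {
        rep(0, nrow(config$confounders))
      }
      s <- config$true_effects[[o]] * x +
        drop(cov$centered %*% gam) +
        config$unobserved$gamma[[o]] * u +
        phys_eff
      if (config$effect_scaling == "proportional") {
        mult <- 1 + s / b[ref_j]
        p <- outer(pmax(mult, 0), b)           # n x horizons
        n_clipped <- n_clipped + sum(mult < 0) * length(b) + sum(p > 1)
        p <- pmin(p, 1)
      } else {
        p <- outer(s, rep(1, length(b))) + matrix(b, n, length(b), byrow = TRUE)
        n_clipped <- n_clipped + sum(p < 0 | p > 1)
        p <- pmin(pmax(p, 0), 1)
      }
      n_draws <- n_draws + length(p)
      udraw <- runif(n)
      # first horizon bucket whose cumulative risk exceeds the draw
      bucket <- rowSums(udraw > p) + 1L
      has_event <- bucket <= length(b)
      idx <- which(has_event)
      j <- bucket[idx]
      offset <- runif_int(length(idx), day_lo[j], day_hi[j])
      event_days[[o]] <- rep(NA_integer_, n)
      event_days[[o]][idx] <- index_day[idx] + offset
    }
    if (n_draws > 0 && n_clipped / n_draws > 0.01) {
      warning(sprintf(
        "outcome probabilities clipped on %d of %d draws (%.1f%%); the scenario's effects are large relative to its baseline risks",
        n_clipped, n_draws, 100 * n_clipped / n_draws), call. = FALSE)
    }

    death_outcomes <- names(event_days)[startsWith(names(event_days), "death")]
    death_day <- if (length(death_outcomes)) event_days[[death_outcomes[1]]] else rep(NA_integer_, n)
    death_observed <- !is.na(death_day) & death_day <= linkage_day

    # --- follow-up / observation window --------------------------------
    dereg <- runif(n) < config$followup$deregister_rate
    dereg_day <- rep(linkage_day, n)
    room <- pmax(linkage_day - index_day, 1L)
    dereg_day[dereg] <- index_day[dereg] + runif_int(sum(dereg), 1L, room[dereg])
    nonfatal_end <- pmin(dereg_day, linkage_day,
                         ifelse(death_observed, death_day, .Machine$integer.max))
    followup_end <- ifelse(death_observed, death_day, pmin(dereg_day, linkage_day))

    # --- event table ----------------------------------------------------
    ev <- list()
    for (o in names(event_days)) {
      d <- event_days[[o]]
      cls <- event_class_of(o)
      observed <- if (cls == "death") {
        !is.na(d) & d <= linkage_day
      } else {
        !is.na(d) & d <= nonfatal_end
      }
      idx <- which(observed)
      if (length(idx)) {
        cause_p <- if (cls == "death") 0.15 else 0.10
        ev[[o]] <- tibble::tibble(
          patient_id = idx,
          day = window_start + d[idx],
          class = cls,
          cause = ifelse(runif(length(idx)) < cause_p, "chronic_lung", "other")
        )
      }
    }
    events <- if (length(ev)) dplyr::bind_rows(ev) else {
      tibble::tibble(patient_id = integer(), day = as.Date(character()),
                     class = character(), cause = character())
    }
    events <- dplyr::arrange(events, .data$patient_id, .data$day)

    # --- continuous / count outcomes -----------------------------------
    weight_day <- index_day + 365L
    weight_obs <- weight_day <= nonfatal_end
    bmi_true <- if ("bmi" %in% names(cov$values)) cov$values$bmi else rep(27, n)
    weight_kg <- 2.89 * bmi_true + 1.0 +
      config$true_effects$weight_kg * x + rnorm(n, 0, 3)
    weight_kg[!weight_obs] <- NA_real_

    consult_cut <- ceiling(months_to_days(24))
    consult_obs <- (nonfatal_end - index_day) >= consult_cut
    visit_shift <- if ("visits_prior_year" %in% names(cov$values)) {
      0.03 * (cov$values$visits_prior_year - 6)
    } else 0
    consult_mu <- exp(log(12) + config$true_effects$consult_rate_log * x + visit_shift)
    consult_count <- rnbinom(n, size = 1.5, mu = consult_mu)
    consult_count[!consult_obs] <- NA_integer_

    # --- eligibility-violating records ---------------------------------
    flag_reg <- runif(n) < config$ineligible$recent_registration
    flag_prior <- runif(n) < config$ineligible$prior_script
    flag_dual <- runif(n) < config$ineligible$same_day_dual

    reg_offset <- runif_int(n, 365L, 5475L)
    reg_offset[flag_reg] <- runif_int(sum(flag_reg), 30L, 364L)
    registration_day <- index_day - reg_offset

    drug <- ifelse(x == 1L, "varenicline", "NRT")
    prescriptions <- tibble::tibble(
      patient_id = seq_len(n),
      physician_id = g,
      practice_id = phys$practice_id[g],
      issue_date = window_start + index_day,
      drug_class = drug,
      is_first_ever = !flag_prior
    )
    if (any(flag_prior)) {
      idx <- which(flag_prior)
      prior_day <- index_day[idx] - runif_int(length(idx), 30L, 547L)
      # keep pre-index use strictly before the study window so the in-window
      # index prescription is unambiguous
      in_window <- prior_day >= 0L
      prior_day[in_window] <- -runif_int(sum(in_window), 1L, 30L)
      prior <- tibble::tibble(
        patient_id = idx,
        physician_id = g[idx],
        practice_id = phys$practice_id[g[idx]],
        issue_date = window_start + prior_day,
        drug_class = sample(c("varenicline", "NRT"), length(idx),
                            replace = TRUE, prob = c(1, 2)),
        is_first_ever = TRUE
      )
      prescriptions <- dplyr::bind_rows(prescriptions, prior)
    }
    if (any(flag_dual)) {
      idx <- which(flag_dual)
      dual <- tibble::tibble(
        patient_id = idx,
        physician_id = g[idx],
        practice_id = phys$practice_id[g[idx]],
        issue_date = window_start + index_day[idx],
        drug_class = ifelse(x[idx] == 1L, "NRT", "varenicline"),
        is_first_ever = FALSE
      )
      prescriptions <- dplyr::bind_rows(prescriptions, dual)
    }
    prescriptions <- dplyr::arrange(prescriptions, .data$patient_id,
                                    .data$issue_date, .data$drug_class)

    covariates <- dplyr::bind_cols(
      tibble::tibble(patient_id = seq_len(n), physician_id = g,
                     practice_id = phys$practice_id[g]),
      cov$values,
      tibble::tibble(u_latent = u)
    )
    # missingness is completely at random by construction
    if ("bmi" %in% names(covariates) && config$missingness$bmi > 0) {
      covariates$bmi[runif(n) < config$missingness$bmi] <- NA_real_
    }
    if ("imd" %in% names(covariates) && config$missingness$imd > 0) {
      covariates$imd[runif(n) < config$missingness$imd] <- NA_integer_
    }

    patients <- tibble::tibble(
      patient_id = seq_len(n),
      physician_id = g,
      practice_id = phys$practice_id[g],
      registration_date = window_start + registration_day,
      deregistration_date = window_start + dereg_day,
      followup_end = window_start + followup_end,
      weight_kg = weight_kg,
      consult_count = consult_count
    )
    registration <- patients[, c("patient_id", "practice_id", "registration_date")]

    out <- list(
      prescriptions = prescriptions,
      covariates = covariates,
      events = events,
      registration = registration,
      patients = patients,
      physicians = phys,
      config = config
    )
    class(out) <- "prefiv_sim"
    out
  })
}

#' @export
print.prefiv_sim <- function(x, ...) {
  cat("<prefiv_sim>\n")
  cat(sprintf("  %d prescriptions, %d patients, %d physicians, %d event records\n",
              nrow(x$prescriptions), nrow(x$covariates),
              nrow(x$physicians), nrow(x$events)))
  invisible(x)
}

sim_table_names <- c("prescriptions", "covariates", "events",
                     "registration", "patients", "physicians")

table_schema <- function(tb) {
  vapply(tb, function(col) class(col)[1], character(1))
}

#' Write / read the synthetic tables
#'
#' `write_tables()` serialises the generated tables either as RFC-4180 CSV
#' (UTF-8, ISO-8601 dates) or as columnar parquet, together with a
#' machine-readable column dictionary (`schema.json`) recording each
#' column's type. `read_tables()` uses the dictionary to restore identical
#' column types, so `read_tables(write_tables(x)) == x` column for column.
#'
#' @param sim a `prefiv_sim` (or any named list of tibbles).
#' @param path directory to write into (created if needed).
#' @param format `"csv"` or `"parquet"` (parquet requires the arrow package).
#' @return `write_tables()` returns the paths written, invisibly;
#'   `read_tables()` returns a named list of tibbles.
#' @export
write_tables <- function(sim, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  tables <- if (inherits(sim, "prefiv_sim")) sim[sim_table_names] else sim
  tables <- tables[!vapply(tables, is.null, logical(1))]
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_prefiv("cannot create output directory: ", path)
  }
  schema <- lapply(tables, table_schema)
  jsonlite::write_json(schema, file.path(path, "schema.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    f <- file.path(path, paste0(nm, ".", if (format == "csv") "csv" else "parquet"))
    if (format == "csv") {
      readr::write_csv(tables[[nm]], f, progress = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort_prefiv("parquet output requires the arrow package")
      }
      arrow::write_parquet(tables[[nm]], f)
    }
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' @rdname write_tables
#' @export
read_tables <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  schema_path <- file.path(path, "schema.json")
  if (!file.exists(schema_path)) abort_prefiv("no schema.json under ", path)
  schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
  out <- list()
  for (nm in names(schema)) {
    f <- file.path(path, paste0(nm, ".", if (format == "csv") "csv" else "parquet"))
    if (!file.exists(f)) next
    if (format == "csv") {
      cols <- lapply(unlist(schema[[nm]]), function(cl) {
        switch(cl,
          integer = readr::col_integer(),
          numeric = readr::col_double(),
          character = readr::col_character(),
          logical = readr::col_logical(),
          Date = readr::col_date(),
          readr::col_guess()
        )
      })
      names(cols) <- names(schema[[nm]])
      out[[nm]] <- readr::read_csv(f, col_types = do.call(readr::cols, cols),
                                   progress = FALSE)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        abort_prefiv("parquet input requires the arrow package")
      }
      out[[nm]] <- tibble::as_tibble(arrow::read_parquet(f))
    }
  }
  out
}
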