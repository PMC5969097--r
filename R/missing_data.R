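# ---- chained-equation multiple imputation ---------------------------------

# Bayesian linear-regression imputation draw for one continuous variable.
impute_draw_linear <- function(X_obs, y_obs, X_mis) {
  qr_ <- qr(X_obs)
  if (qr_$rank < ncol(X_obs)) stop("collinear imputation model")
  betahat <- qr.coef(qr_, y_obs)
  res <- y_obs - X_obs %*% betahat
  df <- nrow(X_obs) - ncol(X_obs)
  sigma2 <- sum(res^2) / rchisq(1, df)
  R <- qr.R(qr_)
  beta <- betahat + backsolve(R, rnorm(ncol(X_obs))) * sqrt(sigma2)
  as.numeric(X_mis %*% beta + rnorm(nrow(X_mis), 0, sqrt(sigma2)))
}

# Ordinal-logit imputation draw (proportional odds); category probabilities
# are taken at the fitted parameters — a pragmatic simplification relative
# to a full posterior draw, noted in the docs.
impute_draw_ordinal <- function(data_obs, y_obs, data_mis, predictors) {
  df_obs <- data_obs[, predictors, drop = FALSE]
  df_obs$.y <- factor(y_obs, ordered = TRUE)
  fit <- MASS::polr(.y ~ ., data = df_obs, Hess = FALSE)
  probs <- predict(fit, newdata = data_mis[, predictors, drop = FALSE],
                   type = "probs")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  lv <- as.integer(levels(df_obs$.y))
  u <- runif(nrow(probs))
  idx <- rowSums(u > t(apply(probs, 1, cumsum))) + 1L
  lv[idx]
}

#' Chained-equation multiple imputation
#'
#' Fills missing BMI (Bayesian linear regression) and deprivation fifth
#' (proportional-odds ordinal logit) by iterating their conditional models —
#' imputation by chained equations. Predictors in each conditional model are
#' the exposure, the other baseline covariates, the other imputed variable's
#' current working values and a primary outcome indicator (congenial
#' imputation; censored patient-horizons enter the indicator as 0).
#' Observed cells are never altered; the `m` completed datasets differ in
#' their imputed draws.
#'
#' The ordinal draw uses fitted category probabilities rather than a full
#' parameter draw — with per-mille missingness in deprivation the
#' between-imputation variance this ignores is negligible; the continuous
#' draw is fully Bayesian.
#'
#' @param cohort analysis cohort.
#' @param m number of imputations (>= 1).
#' @param iterations chained iterations per imputation (>= 1).
#' @param variables variables to impute; only `bmi` (continuous) and `imd`
#'   (ordinal) are supported, and only those actually present and missing
#'   are modelled.
#' @param predictors predictor columns; defaults to the exposure, the
#'   cohort's covariate set and the primary outcome indicator
#'   (`y_death_all_m24` when present).
#' @param seed integer seed.
#' @return list of `m` completed cohorts, with a `summary` attribute
#'   comparing observed and imputed marginal means per variable.
#' @export
impute_chained <- function(cohort, m = 5L, iterations = 10L,
                           variables = c("bmi", "imd"),
                           predictors = NULL, seed = 1L) {
  if (m < 1L) abort_prefiv("m must be >= 1")
  if (iterations < 1L) abort_prefiv("iterations must be >= 1")
  variables <- intersect(variables, names(cohort))
  variables <- variables[vapply(variables, function(v) anyNA(cohort[[v]]),
                                logical(1))]
  if (is.null(predictors)) {
    predictors <- setdiff(attr(cohort, "covariates") %||% character(0), variables)
    predictors <- intersect(predictors, names(cohort))
    predictors <- union("exposure", predictors)
    ycol <- grep("^y_death_all_m24$", names(cohort), value = TRUE)
    if (!length(ycol)) ycol <- head(grep("^y_", names(cohort), value = TRUE), 1)
    predictors <- union(predictors, ycol)
  }
  other_na <- setdiff(predictors, variables)
  bad <- other_na[vapply(other_na, function(v) anyNA(cohort[[v]]), logical(1))]
  if (length(bad)) {
    abort_prefiv("missingness outside the declared imputation variables: ",
                 paste(bad, collapse = ", "))
  }

  if (!length(variables)) {
    out <- rep(list(cohort), m)
    attr(out, "summary") <- tibble::tibble(variable = character(),
                                           mean_observed = numeric(),
                                           mean_imputed = numeric())
    return(out)
  }

  mis_idx <- lapply(variables, function(v) which(is.na(cohort[[v]])))
  names(mis_idx) <- variables
  obs_idx <- lapply(variables, function(v) which(!is.na(cohort[[v]])))
  names(obs_idx) <- variables

  completed <- vector("list", m)
  for (imp in seq_len(m)) {
    work <- cohort
    withr::with_seed(derive_seed(seed, 100L + imp), {
      # initialise missing cells with draws from the observed margins
      for (v in variables) {
        work[[v]][mis_idx[[v]]] <- sample(cohort[[v]][obs_idx[[v]]],
                                          length(mis_idx[[v]]), replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in variables) {
          preds <- union(predictors, setdiff(variables, v))
          res <- tryCatch({
            if (v == "imd") {
              impute_draw_ordinal(work[obs_idx[[v]], ],
                                  cohort[[v]][obs_idx[[v]]],
                                  work[mis_idx[[v]], ], preds)
            } else {
              X_obs <- design_matrix(work[obs_idx[[v]], ], preds)
              X_mis <- design_matrix_like(work[mis_idx[[v]], ], preds, X_obs)
              impute_draw_linear(X_obs, cohort[[v]][obs_idx[[v]]], X_mis)
            }
          }, error = function(e) {
            abort_prefiv("conditional imputation model for '", v,
                         "' failed: ", conditionMessage(e))
          })
          work[[v]][mis_idx[[v]]] <- res
        }
      }
    })
    completed[[imp]] <- work
  }
  summ <- dplyr::bind_rows(lapply(variables, function(v) {
    imp_vals <- unlist(lapply(completed, function(d) d[[v]][mis_idx[[v]]]))
    tibble::tibble(variable = v,
                   mean_observed = mean(cohort[[v]][obs_idx[[v]]]),
                   mean_imputed = mean(as.numeric(imp_vals)))
  }))
  attr(completed, "summary") <- summ
  completed
}

# design matrix for new rows using the factor layout of a reference matrix
design_matrix_like <- function(data, covariates, ref) {
  X <- design_matrix(data, covariates)
  miss_cols <- setdiff(colnames(ref), colnames(X))
  if (length(miss_cols)) {
    X <- cbind(X, matrix(0, nrow(X), length(miss_cols),
                         dimnames = list(NULL, miss_cols)))
  }
  X[, colnames(ref), drop = FALSE]
}

#' Pool per-imputation estimates by Rubin's rules
#'
#' Pooled point = mean of the per-imputation points; pooled variance =
#' within-imputation mean + `(1 + 1/m)` times the between-imputation
#' variance; confidence intervals use the classic Rubin degrees of freedom
#' `(m - 1) * (1 + W / ((1 + 1/m) B))^2`. Pooling happens on the estimation
#' scale (log odds ratio, risk difference), the display scale is rebuilt
#' afterwards.
#'
#' @param results stacked estimate rows (or a list of them), `m >= 2` rows
#'   per method/outcome/horizon group; every group must contain the same
#'   number of imputations.
#' @return one pooled estimate row per group.
#' @export
pool_estimates <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(results)
  }
  hz <- ifelse(is.na(results$horizon), "none", as.character(results$horizon))
  groups <- split(results,
                  interaction(results$method, results$outcome, hz, drop = TRUE))
  sizes <- vapply(groups, nrow, integer(1))
  if (any(sizes < 2L)) {
    abort_prefiv("pooling needs m >= 2 results per method/outcome/horizon; ",
                 "got a group with ", min(sizes))
  }
  if (length(unique(sizes)) > 1L) {
    abort_prefiv("mismatched imputation counts across method/outcome/horizon ",
                 "groups: ", paste(unique(sizes), collapse = ", "))
  }
  dplyr::bind_rows(lapply(groups, function(gr) {
    if (length(unique(gr$scale)) != 1L) {
      abort_prefiv("cannot pool estimates on different scales")
    }
    m <- nrow(gr)
    qbar <- mean(gr$beta)
    ubar <- mean(gr$se_beta^2)
    b <- var(gr$beta)
    tvar <- ubar + (1 + 1 / m) * b
    df <- if (b > 0) (m - 1) * (1 + ubar / ((1 + 1 / m) * b))^2 else Inf
    se <- sqrt(tvar)
    crit <- qt(0.975, df)
    lo <- qbar - crit * se
    hi <- qbar + crit * se
    scale <- gr$scale[1]
    est <- if (scale == "odds ratio") exp(qbar) else qbar
    tibble::tibble(
      method = gr$method[1], outcome = gr$outcome[1], horizon = gr$horizon[1],
      scale = scale,
      estimate = est,
      conf_low = if (scale == "odds ratio") exp(lo) else lo,
      conf_high = if (scale == "odds ratio") exp(hi) else hi,
      beta = qbar, se_beta = se,
      n = as.integer(round(mean(gr$n))), n_clusters = max(gr$n_clusters)
    )
  }))
}

# ---- mean replacement with indicators -------------------------------------

#' Mean replacement with missing-value indicators
#'
#' The missing-data strategy for the propensity-score analysis: missing BMI
#' and deprivation values are replaced by the observed mean and a binary
#' `<variable>_missing` indicator is added per variable (so the indicator
#' column mean equals the missing fraction).
#'
#' @param cohort analysis cohort.
#' @param variables variables to complete (default BMI and deprivation).
#' @return a single completed cohort with indicator columns.
#' @export
mean_indicator_impute <- function(cohort, variables = c("bmi", "imd")) {
  variables <- intersect(variables, names(cohort))
  at <- attributes(cohort)
  for (v in variables) {
    x <- as.numeric(cohort[[v]])
    if (all(is.na(x))) {
      abort_prefiv("variable '", v, "' is entirely missing; cannot impute a mean")
    }
    ind <- as.integer(is.na(x))
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    cohort[[v]] <- x
    cohort[[paste0(v, "_missing")]] <- ind
  }
  for (a in c("horizons", "outcomes", "covariates")) {
    attr(cohort, a) <- at[[a]]
  }
  cohort
}
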