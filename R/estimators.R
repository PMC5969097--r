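# ---- result container ------------------------------------------------------

# One row per estimate. `beta`/`se_beta` hold the estimation-scale quantities
# (log odds ratio, risk difference per 100, or mean difference) used for
# Rubin pooling; `estimate`/CI are on the display scale.
estimate_result <- function(method, outcome, horizon, scale, beta, se,
                            n, n_clusters) {
  z <- qnorm(0.975)
  lo <- beta - z * se
  hi <- beta + z * se
  if (scale == "odds ratio") {
    est <- exp(beta); lo <- exp(lo); hi <- exp(hi)
  } else {
    est <- beta
  }
  tibble::tibble(
    method = method, outcome = outcome,
    horizon = if (is.null(horizon)) NA_real_ else horizon,
    scale = scale, estimate = est, conf_low = lo, conf_high = hi,
    beta = beta, se_beta = se, n = n, n_clusters = n_clusters
  )
}

# Locate the outcome vector and the rows usable for it. Binary outcomes live
# in per-horizon indicator columns and drop censored rows; continuous
# outcomes (weight, consultation count) drop unobserved rows.
outcome_data <- function(cohort, outcome, horizon = NULL) {
  if (!is.null(horizon)) {
    ycol <- sprintf("y_%s_m%d", outcome, horizon)
    ccol <- sprintf("cens_%s_m%d", outcome, horizon)
    if (!ycol %in% names(cohort)) {
      abort_prefiv("no outcome column ", ycol, " in cohort")
    }
    keep <- cohort[[ccol]] == 0L
    list(y = cohort[[ycol]][keep], keep = keep, type = "binary")
  } else {
    if (!outcome %in% names(cohort)) {
      abort_prefiv("no outcome column ", outcome, " in cohort")
    }
    y <- cohort[[outcome]]
    keep <- !is.na(y)
    list(y = as.numeric(y[keep]), keep = keep, type = "continuous")
  }
}

adjustment_set <- function(cohort, adjustment) {
  basic <- intersect(c("rx_year", "male", "age"), names(cohort))
  if (adjustment == "basic") return(basic)
  full <- attr(cohort, "covariates") %||% character(0)
  union(basic, intersect(full, names(cohort)))
}

# ---- multivariable regression ---------------------------------------------

#' Multivariable adjusted treatment-effect estimate
#'
#' Regression of a per-horizon outcome on the exposure with either the basic
#' adjustment set (sex, age, year of first prescription) or the full set
#' (basic plus every baseline covariate attached to the cohort). The logit
#' link returns an odds ratio; the linear link returns the risk difference
#' per 100 patients treated for binary outcomes, or the raw mean difference
#' for continuous outcomes. Variances are clustered on the prescribing
#' physician. Censored patient-horizons are dropped.
#'
#' @param cohort analysis cohort.
#' @param outcome outcome label (e.g. `"death_all"`) or a continuous outcome
#'   column (e.g. `"weight_kg"`, with `horizon = NULL`).
#' @param horizon months, or `NULL` for continuous outcomes.
#' @param adjustment `"full"` or `"basic"`.
#' @param link `"logit"` or `"linear"`.
#' @param cluster clustering column.
#' @return a one-row estimate tibble.
#' @export
fit_multivariable <- function(cohort, outcome, horizon = NULL,
                              adjustment = c("full", "basic"),
                              link = c("logit", "linear"),
                              cluster = "physician_id") {
  adjustment <- match.arg(adjustment)
  link <- match.arg(link)
  od <- outcome_data(cohort, outcome, horizon)
  data <- cohort[od$keep, ]
  y <- od$y
  covs <- adjustment_set(cohort, adjustment)
  clu <- data[[cluster]]
  method <- sprintf("mv_%s_%s", if (link == "logit") "logistic" else "linear",
                    adjustment)

  if (link == "logit") {
    if (od$type != "binary") {
      abort_prefiv("logit link needs a binary per-horizon outcome")
    }
    if (all(y == 0L) || all(y == 1L)) {
      abort_prefiv("outcome '", outcome, "' at ", horizon,
                   " months is constant in the analysis sample: logistic ",
                   "separation; use the linear link or a longer horizon")
    }
    W <- design_matrix(data, covs)
    df <- data.frame(y = y, exposure = data$exposure,
                     W[, -1, drop = FALSE], check.names = TRUE)
    fit <- glm(y ~ ., family = binomial(), data = df)
    if (!fit$converged) {
      abort_prefiv("logistic fit failed to converge (possible separation)")
    }
    V <- sandwich::vcovCL(fit, cluster = clu, type = "HC0")
    b <- coef(fit)["exposure"]
    se <- sqrt(V["exposure", "exposure"])
    estimate_result(method, outcome, horizon, "odds ratio",
                    unname(b), unname(se), length(y), length(unique(clu)))
  } else {
    W <- design_matrix(data, covs)
    X <- cbind(W[, 1, drop = FALSE], exposure = data$exposure,
               W[, -1, drop = FALSE])
    fit <- ols_cluster(X, y, clu)
    b <- fit$coef["exposure"]
    se <- sqrt(fit$vcov["exposure", "exposure"])
    mult <- if (od$type == "binary") 100 else 1
    scale <- if (od$type == "binary") "risk difference per 100" else "mean difference"
    estimate_result(method, outcome, horizon, scale,
                    unname(b) * mult, unname(se) * mult, fit$n, fit$n_clusters)
  }
}

# ---- propensity score ------------------------------------------------------

#' Fit the treatment propensity score
#'
#' Logistic regression of the exposure on the full baseline covariate set
#' (plus any missing-value indicator columns created by
#' [mean_indicator_impute()]). Reports whether every treated patient's score
#' falls inside the range of comparator scores (common support).
#'
#' @param cohort analysis cohort with complete covariates.
#' @param covariates covariate names; defaults to the cohort's adjustment
#'   set plus `*_missing` indicators.
#' @param cluster clustering column, kept for downstream outcome models.
#' @return object of class `prefiv_ps`: the fitted model, per-patient
#'   `score`, the data, and a `common_support` flag.
#' @export
fit_propensity <- function(cohort, covariates = NULL,
                           cluster = "physician_id") {
  covariates <- covariates %||% c(
    adjustment_set(cohort, "full"),
    grep("_missing$", names(cohort), value = TRUE)
  )
  W <- design_matrix(cohort, covariates)
  df <- data.frame(exposure = cohort$exposure, W[, -1, drop = FALSE],
                   check.names = TRUE)
  fit <- glm(exposure ~ ., family = binomial(), data = df)
  if (!fit$converged || any(fit$fitted.values < 1e-10) ||
      any(fit$fitted.values > 1 - 1e-10)) {
    abort_prefiv("propensity model separation: some patients are perfectly ",
                 "classified by their covariates")
  }
  score <- unname(fit$fitted.values)
  ctrl_range <- range(score[cohort$exposure == 0L])
  support <- all(score[cohort$exposure == 1L] >= ctrl_range[1] &
                   score[cohort$exposure == 1L] <= ctrl_range[2])
  structure(list(model = fit, score = score, data = cohort,
                 covariates = covariates, cluster = cluster,
                 common_support = support),
            class = "prefiv_ps")
}

#' @export
print.prefiv_ps <- function(x, ...) {
  cat("<prefiv_ps>\n")
  cat(sprintf("  %d patients (%d treated), %d covariates\n",
              nrow(x$data), sum(x$data$exposure), length(x$covariates)))
  cat(sprintf("  common support: %s\n",
              if (x$common_support) "all treated scores inside comparator range"
              else "VIOLATED"))
  invisible(x)
}

#' One-to-one nearest-neighbour matching without caliper
#'
#' Greedy 1:1 matching of every treated patient to the untreated patient
#' with the nearest propensity score, without replacement and with no
#' caliper. Treated patients are processed in a seeded random order, which
#' also breaks ties between equidistant comparators reproducibly.
#'
#' @param ps a `prefiv_ps` from [fit_propensity()].
#' @param seed integer seed for the processing order.
#' @return the matched cohort (treated and matched comparators, `pair_id`
#'   column, `ps_score` column) with a `balance` attribute: per-covariate
#'   standardized differences before and after matching.
#' @export
match_nearest <- function(ps, seed = 1L) {
  stopifnot(inherits(ps, "prefiv_ps"))
  data <- ps$data
  score <- ps$score
  t_idx <- which(data$exposure == 1L)
  c_idx <- which(data$exposure == 0L)
  if (length(c_idx) < length(t_idx)) {
    abort_prefiv("fewer comparator than treated patients: 1:1 matching ",
                 "without replacement impossible")
  }
  ord <- withr::with_seed(derive_seed(seed, 71L), sample(t_idx))
  cs <- sort(score[c_idx], index.return = TRUE)
  avail_score <- cs$x
  avail_idx <- c_idx[cs$ix]
  pairs_t <- integer(length(ord))
  pairs_c <- integer(length(ord))
  for (i in seq_along(ord)) {
    s <- score[ord[i]]
    j <- findInterval(s, avail_score)
    # nearest of the two neighbours; ties go to the lower score
    j <- if (j == 0L) 1L
    else if (j >= length(avail_score)) length(avail_score)
    else if (s - avail_score[j] <= avail_score[j + 1L] - s) j else j + 1L
    pairs_t[i] <- ord[i]
    pairs_c[i] <- avail_idx[j]
    avail_score <- avail_score[-j]
    avail_idx <- avail_idx[-j]
  }
  matched <- dplyr::bind_rows(
    dplyr::mutate(data[pairs_t, ], pair_id = seq_along(pairs_t)),
    dplyr::mutate(data[pairs_c, ], pair_id = seq_along(pairs_c))
  )
  matched$ps_score <- score[c(pairs_t, pairs_c)]

  std_diff <- function(v, tr) {
    m1 <- mean(v[tr == 1L]); m0 <- mean(v[tr == 0L])
    s <- sqrt((var(v[tr == 1L]) + var(v[tr == 0L])) / 2)
    if (s == 0) 0 else (m1 - m0) / s
  }
  covs <- intersect(ps$covariates, names(data))
  covs <- covs[vapply(covs, function(v) is.numeric(data[[v]]), logical(1))]
  balance <- tibble::tibble(
    covariate = covs,
    std_diff_before = vapply(covs, function(v) std_diff(data[[v]], data$exposure),
                             numeric(1)),
    std_diff_after = vapply(covs, function(v) std_diff(matched[[v]], matched$exposure),
                            numeric(1))
  )
  for (a in c("horizons", "outcomes", "covariates")) {
    attr(matched, a) <- attr(data, a)
  }
  attr(matched, "balance") <- balance
  matched
}

#' Outcome model on the matched sample
#'
#' Regression of the outcome on the exposure within the matched cohort, with
#' the propensity score included as a covariate and physician-clustered
#' variance.
#'
#' @param matched matched cohort from [match_nearest()].
#' @param outcome,horizon as in [fit_multivariable()].
#' @param link `"logit"` (odds ratio, default) or `"linear"` (risk
#'   difference per 100).
#' @param cluster clustering column.
#' @return a one-row estimate tibble with method `"ps_matched"`.
#' @export
estimate_ps_outcome <- function(matched, outcome, horizon = NULL,
                                link = c("logit", "linear"),
                                cluster = "physician_id") {
  link <- match.arg(link)
  od <- outcome_data(matched, outcome, horizon)
  data <- matched[od$keep, ]
  y <- od$y
  clu <- data[[cluster]]
  if (link == "logit") {
    if (all(y == 0L) || all(y == 1L)) {
      abort_prefiv("constant outcome in matched sample: logistic separation")
    }
    fit <- glm(y ~ exposure + ps_score, family = binomial(), data = data)
    V <- sandwich::vcovCL(fit, cluster = clu, type = "HC0")
    estimate_result("ps_matched", outcome, horizon, "odds ratio",
                    unname(coef(fit)["exposure"]),
                    sqrt(V["exposure", "exposure"]),
                    length(y), length(unique(clu)))
  } else {
    X <- cbind(`(Intercept)` = 1, exposure = data$exposure,
               ps_score = data$ps_score)
    fit <- ols_cluster(X, y, clu)
    mult <- if (od$type == "binary") 100 else 1
    scale <- if (od$type == "binary") "risk difference per 100" else "mean difference"
    estimate_result("ps_matched", outcome, horizon, scale,
                    unname(fit$coef["exposure"]) * mult,
                    sqrt(fit$vcov["exposure", "exposure"]) * mult,
                    fit$n, fit$n_clusters)
  }
}

# ---- instrumental variables ------------------------------------------------

#' Two-stage least-squares estimate with a preference instrument
#'
#' 2SLS of the outcome on the exposure, instrumented by the prescribing
#' preference proxy `z` and adjusted for the basic covariates (year of first
#' prescription, sex, age by default). For binary outcomes the linear 2SLS
#' point estimate coincides with the additive structural mean model estimate
#' of the risk difference (the additive-case equivalence), and is reported
#' per 100 patients treated; continuous outcomes give mean differences.
#' Standard errors use the cluster-robust sandwich with physician-level
#' score aggregation and a `G/(G-1) * (N-1)/(N-K)` small-sample factor,
#' computed from the structural residuals (actual exposure, not its first
#' stage fit).
#'
#' With no covariates the estimate equals the covariance ratio
#' `cov(z, y) / cov(z, x)` exactly — the Wald ratio when `z` is binary.
#'
#' @param cohort instrumented cohort from [build_preference_proxy()].
#' @param outcome,horizon as in [fit_multivariable()].
#' @param covariates adjustment set (may be `character(0)` for none).
#' @param cluster clustering column.
#' @return a one-row estimate tibble with method `"iv_2sls"`.
#' @export
estimate_iv <- function(cohort, outcome, horizon = NULL,
                        covariates = c("rx_year", "male", "age"),
                        cluster = "physician_id") {
  if (!"z" %in% names(cohort)) {
    abort_prefiv("no instrument column `z`; run build_preference_proxy() first")
  }
  od <- outcome_data(cohort, outcome, horizon)
  data <- cohort[od$keep, ]
  y <- od$y
  covariates <- intersect(covariates, names(data))
  W <- design_matrix(data, covariates)
  x <- data$exposure
  z <- data$z
  clu <- data[[cluster]]

  Zfull <- cbind(W, z = z)
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull)) abort_prefiv("collinear first-stage design")
  fs_coef <- qr.coef(qz, x)["z"]
  if (abs(fs_coef) < 1e-8) {
    f <- tryCatch(partial_f(data, covariates, cluster)$partial_f,
                  error = function(e) NA_real_)
    abort_prefiv(sprintf(
      "first-stage coefficient ~ 0 (partial F = %.2f): instrument too weak", f))
  }
  xhat <- qr.fitted(qz, x)
  D <- cbind(exposure = xhat, W)
  qd <- qr(D)
  beta <- qr.coef(qd, y)
  u <- as.numeric(y - cbind(x, W) %*% beta)
  sg <- rowsum(D * u, clu)
  dtdinv <- chol2inv(qr.R(qd))
  g <- nrow(sg); n <- nrow(D); k <- ncol(D)
  adj <- g / (g - 1) * (n - 1) / (n - k)
  V <- adj * dtdinv %*% crossprod(sg) %*% dtdinv
  b <- beta["exposure"]
  se <- sqrt(V[1, 1])
  mult <- if (od$type == "binary") 100 else 1
  scale <- if (od$type == "binary") "risk difference per 100" else "mean difference"
  estimate_result("iv_2sls", outcome, horizon, scale,
                  unname(b) * mult, unname(se) * mult, n, g)
}
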