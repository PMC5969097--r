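# ---- shared regression plumbing -------------------------------------------

# Design matrix with an intercept; calendar year and deprivation fifth enter
# as factors, everything else linearly. Errors on missing covariate values:
# imputation (or the mean-indicator path) must happen upstream.
design_matrix <- function(data, covariates) {
  if (!length(covariates)) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    abort_prefiv("covariate(s) not in cohort: ", paste(miss, collapse = ", "))
  }
  nas <- covariates[vapply(covariates, function(v) anyNA(data[[v]]), logical(1))]
  if (length(nas)) {
    abort_prefiv("missing values in covariate(s) ",
                 paste(nas, collapse = ", "),
                 "; impute first (impute_chained or mean_indicator_impute)")
  }
  term <- vapply(covariates, function(v) {
    # year and deprivation fifth enter as factors; deprivation stays linear
    # after mean replacement leaves fractional values
    categorical <- v == "rx_year" ||
      (v == "imd" && all(data[[v]] == round(data[[v]])))
    if (categorical) sprintf("factor(%s)", v) else v
  }, character(1))
  model.matrix(reformulate(term), data = data)
}

# OLS with cluster-robust (sandwich) variance; the small-sample correction
# G/(G-1) * (N-1)/(N-K) matches the convention of mainstream econometrics
# software so partial F values are comparable across implementations.
ols_cluster <- function(X, y, cluster) {
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) abort_prefiv("collinear design matrix")
  beta <- qr.coef(qr_, y)
  res <- as.numeric(y - X %*% beta)
  sg <- rowsum(X * res, cluster)
  xtxinv <- chol2inv(qr.R(qr_))
  g <- nrow(sg)
  n <- nrow(X)
  k <- ncol(X)
  if (g < 2) abort_prefiv("need at least 2 clusters")
  adj <- g / (g - 1) * (n - 1) / (n - k)
  v <- adj * xtxinv %*% crossprod(sg) %*% xtxinv
  dimnames(v) <- list(colnames(X), colnames(X))
  list(coef = beta, vcov = v, n = n, n_clusters = g, residuals = res)
}

# ---- preference proxy ------------------------------------------------------

#' Build the physician prescribing-preference proxy instrument
#'
#' For each index prescription, the instrument `z` counts how many of the
#' prescribing physician's `k` most recent *prior* eligible first
#' prescriptions were varenicline (0..k). The window is defined over the
#' physician's eligible first prescriptions only — the same patients that
#' enter the cohort — and is strictly past: the current and all later
#' prescriptions never contribute. Rows are ordered internally by physician,
#' index date and patient id, so input row order is irrelevant (same-day
#' ties within a physician are broken by patient id; documented, not
#' meaningful).
#'
#' Rows whose physician has not yet issued `k` eligible prescriptions are
#' dropped from the instrumented sample (keeping `z` on a fixed 0..k scale),
#' and physicians with `min_prescriptions` or fewer eligible prescriptions
#' in total are dropped entirely (the default keeps prescribers with more
#' than 10 scripts). Both counts are recorded in the `iv_exclusions`
#' attribute. The lag-1 indicator `z_lag1` (previous first prescription was
#' varenicline) is kept for the prescriber-persistence statistic.
#'
#' @param cohort analysis cohort (needs `physician_id`, `index_date`,
#'   `patient_id`, `exposure`).
#' @param k window length in prior prescriptions (default 7).
#' @param min_prescriptions drop physicians with `<= min_prescriptions`
#'   eligible scripts (default 10). Must be at least `k`.
#' @param encoding `"count"` keeps `z` on 0..k; `"binary"` keeps only the
#'   extreme rows (`z == k` recoded 1 — the physician's last `k` scripts all
#'   varenicline, a prescriber classified as preferring varenicline — and
#'   `z == 0` recoded 0, preferring NRT).
#' @return the instrumented cohort (possibly fewer rows) with columns `z`,
#'   `z_count` and `z_lag1`, and an `iv_exclusions` attribute.
#' @export
build_preference_proxy <- function(cohort, k = 7L, min_prescriptions = 10L,
                                   encoding = c("count", "binary")) {
  encoding <- match.arg(encoding)
  k <- as.integer(k)
  if (k < 1L) abort_prefiv("k must be >= 1")
  if (min_prescriptions < k) {
    abort_prefiv("min_prescriptions must be at least k")
  }
  need <- c("patient_id", "physician_id", "index_date", "exposure")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) abort_prefiv("cohort lacks column(s): ",
                                 paste(miss, collapse = ", "))
  at <- attributes(cohort)
  dt <- as.data.table(cohort)
  setorderv(dt, c("physician_id", "index_date", "patient_id"))
  dt[, `:=`(n_scripts = .N), by = "physician_id"]
  n0 <- nrow(dt)
  dt <- dt[dt$n_scripts > min_prescriptions, ]
  n_small_phys <- n0 - nrow(dt)
  dt[, `:=`(
    z_count = {
      s <- cumsum(exposure)
      as.integer(shift(s, 1L, fill = 0L) - shift(s, k + 1L, fill = 0L))
    },
    z_lag1 = shift(exposure, 1L),
    pos = seq_len(.N)
  ), by = "physician_id"]
  n1 <- nrow(dt)
  dt <- dt[dt$pos > k, ]
  n_short_history <- n1 - nrow(dt)
  dt[, c("pos", "n_scripts") := NULL]

  out <- tibble::as_tibble(dt)
  if (encoding == "count") {
    out$z <- out$z_count
    n_not_extreme <- 0L
  } else {
    keep <- out$z_count %in% c(0L, k)
    n_not_extreme <- sum(!keep)
    out <- out[keep, ]
    out$z <- as.integer(out$z_count == k)
  }
  for (a in c("horizons", "outcomes", "covariates")) attr(out, a) <- at[[a]]
  attr(out, "instrument") <- list(k = k, min_prescriptions = min_prescriptions,
                                  encoding = encoding)
  attr(out, "iv_exclusions") <- tibble::tibble(
    reason = c("physician_at_most_min_prescriptions", "short_history",
               "not_extreme_preference"),
    n = c(n_small_phys, n_short_history, n_not_extreme)
  )
  out
}

# ---- instrument strength ---------------------------------------------------

#' Instrument strength report
#'
#' First-stage linear regression of the actual prescription on the
#' preference proxy and the basic covariates, with physician-clustered
#' variance. The partial F for the single instrument is the squared
#' cluster-robust t statistic of `z`. Also computes prescriber persistence:
#' the percentage-point increase in the probability of a varenicline
#' prescription when the physician's immediately previous first prescription
#' was varenicline (lag-1 association, cluster-robust CI).
#'
#' @param cohort instrumented cohort from [build_preference_proxy()].
#' @param covariates first-stage adjustment set (default year of first
#'   prescription, sex and age).
#' @param cluster clustering column (default the prescribing physician).
#' @return object of class `prefiv_strength`: `partial_f`,
#'   `first_stage_coef` (change in Pr(varenicline) per unit of `z`),
#'   `first_stage_se`, `persistence_pct`, `persistence_ci`, `n`,
#'   `n_clusters`.
#' @export
partial_f <- function(cohort, covariates = c("rx_year", "male", "age"),
                      cluster = "physician_id") {
  if (!"z" %in% names(cohort)) {
    abort_prefiv("no instrument column `z`; run build_preference_proxy() first")
  }
  if (length(unique(cohort$z)) < 2L) {
    abort_prefiv("instrument z is constant; partial F is undefined")
  }
  covariates <- intersect(covariates, names(cohort))
  W <- design_matrix(cohort, covariates)
  X <- cbind(W, z = cohort$z)
  fs <- ols_cluster(X, cohort$exposure, cohort[[cluster]])
  b <- fs$coef["z"]
  se <- sqrt(fs$vcov["z", "z"])

  pers <- pers_ci <- NULL
  if ("z_lag1" %in% names(cohort)) {
    Xp <- cbind(`(Intercept)` = 1, z_lag1 = cohort$z_lag1)
    ps <- ols_cluster(Xp, cohort$exposure, cohort[[cluster]])
    pb <- ps$coef["z_lag1"]
    pse <- sqrt(ps$vcov["z_lag1", "z_lag1"])
    pers <- 100 * pb
    pers_ci <- 100 * (pb + c(-1, 1) * qnorm(0.975) * pse)
  }
  structure(list(
    partial_f = unname((b / se)^2),
    first_stage_coef = unname(b),
    first_stage_se = unname(se),
    persistence_pct = unname(pers),
    persistence_ci = pers_ci,
    n = fs$n,
    n_clusters = fs$n_clusters,
    covariates = covariates
  ), class = "prefiv_strength")
}

#' @export
print.prefiv_strength <- function(x, ...) {
  cat("Instrument strength (first stage, physician-clustered)\n")
  cat(sprintf("  partial F: %.1f%s\n", x$partial_f,
              if (x$partial_f < 10) "  [WEAK: F < 10]" else ""))
  cat(sprintf("  first-stage coefficient: %.4f (SE %.4f) per prior varenicline script\n",
              x$first_stage_coef, x$first_stage_se))
  if (!is.null(x$persistence_pct)) {
    cat(sprintf("  prescriber persistence: %.1f pp (95%% CI %.1f to %.1f)\n",
                x$persistence_pct, x$persistence_ci[1], x$persistence_ci[2]))
  }
  cat(sprintf("  n = %d patients, %d physicians\n", x$n, x$n_clusters))
  invisible(x)
}
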