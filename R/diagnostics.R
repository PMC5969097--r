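#' Percentage with half-up rounding
#'
#' `100 * num / den`, rounded half away from zero to the requested number of
#' decimals — the convention used in published descriptive tables.
#'
#' @param num numerator count(s).
#' @param den denominator count(s), > 0.
#' @param decimals decimal places (default 1).
#' @return numeric percentage(s).
#' @export
#' @examples
#' proportion(7, 8058, 2) # 0.09
proportion <- function(num, den, decimals = 1) {
  if (any(den <= 0)) abort_prefiv("denominator must be > 0")
  round_half_up(100 * num / den, decimals)
}

#' Bias-component table for instrument validity
#'
#' Compares, covariate by covariate, the imbalance carried by the actual
#' prescription with the imbalance carried by the preference instrument
#' after scaling by instrument strength:
#'
#' * treatment component `B_X(c) = mean(c | X = 1) - mean(c | X = 0)`;
#' * instrument component
#'   `B_Z(c) = (mean(c | Z = hi) - mean(c | Z = lo)) / (mean(X | Z = hi) - mean(X | Z = lo))`.
#'
#' A valid preference instrument should show `|B_Z| < |B_X|` for covariates
#' driven by patient case-mix. The hi/lo groups default to the extremes of
#' the proxy (all seven prior scripts varenicline vs none — the prescriber
#' preference classification); `scaling = "regression"` instead uses
#' reduced-form regression ratios `cov(c, z) / cov(x, z)`, which uses every
#' row. Confidence intervals come from a seeded physician-level (cluster)
#' bootstrap.
#'
#' @param cohort instrumented cohort from [build_preference_proxy()].
#' @param covariates covariate columns to tabulate (default: the cohort's
#'   numeric adjustment set).
#' @param hi,lo instrument values defining the extreme groups (defaults: the
#'   proxy window length `k` and 0).
#' @param scaling `"extremes"` (default) or `"regression"`.
#' @param n_boot bootstrap draws (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param cluster clustering column resampled by the bootstrap.
#' @return tibble: covariate, `b_x` with CI, `b_z` with CI, `ratio`
#'   (`|b_z / b_x|`); attribute `first_stage_diff` holds the denominator.
#' @export
bias_components <- function(cohort, covariates = NULL, hi = NULL, lo = 0L,
                            scaling = c("extremes", "regression"),
                            n_boot = 500L, level = 0.95, seed = 1L,
                            cluster = "physician_id") {
  scaling <- match.arg(scaling)
  if (!"z" %in% names(cohort)) {
    abort_prefiv("no instrument column `z`; run build_preference_proxy() first")
  }
  hi <- hi %||% (attr(cohort, "instrument")$k %||% max(cohort$z))
  covariates <- covariates %||% (attr(cohort, "covariates") %||% character(0))
  covariates <- covariates[vapply(covariates,
                                  function(v) is.numeric(cohort[[v]]),
                                  logical(1))]
  if (!length(covariates)) abort_prefiv("no numeric covariates to tabulate")
  if (anyNA(cohort[covariates])) {
    abort_prefiv("missing covariate values; impute before bias_components()")
  }

  M <- as.matrix(cohort[covariates])
  x <- cohort$exposure
  z <- cohort$z
  gfac <- factor(cohort[[cluster]])
  gint <- as.integer(gfac)
  G <- nlevels(gfac)

  masks <- list(
    x1 = x == 1L, x0 = x == 0L,
    zhi = z >= hi, zlo = z <= lo
  )
  if (scaling == "extremes" && (!any(masks$zhi) || !any(masks$zlo))) {
    abort_prefiv("hi/lo instrument groups are empty; widen hi/lo or use ",
                 "scaling = 'regression'")
  }
  # per-physician building blocks so each bootstrap draw is O(G)
  S <- lapply(masks, function(m) rowsum(M * m, gint))
  ncl <- lapply(masks, function(m) rowsum(as.numeric(m), gint))
  Sx <- lapply(masks, function(m) rowsum(x * m, gint))
  Sz <- rowsum(cbind(z = z, xz = x * z, one = rep(1, length(z))), gint)
  Mz <- rowsum(M * z, gint)
  Sm <- rowsum(M, gint)

  comp <- function(w) {
    gm <- function(S_, n_) as.numeric(crossprod(w, S_)) / sum(w * n_)
    b_x <- gm(S$x1, ncl$x1) - gm(S$x0, ncl$x0)
    if (scaling == "extremes") {
      denom <- sum(w * Sx$zhi) / sum(w * ncl$zhi) -
        sum(w * Sx$zlo) / sum(w * ncl$zlo)
      b_z <- (gm(S$zhi, ncl$zhi) - gm(S$zlo, ncl$zlo)) / denom
    } else {
      n <- sum(w * Sz[, "one"])
      zbar <- sum(w * Sz[, "z"]) / n
      cov_xz <- sum(w * Sz[, "xz"]) / n -
        (sum(w * rowSums(Sx$x1)) / n) * zbar
      # rowSums(Sx$x1) is the per-physician sum of x
      cov_cz <- as.numeric(crossprod(w, Mz)) / n -
        as.numeric(crossprod(w, Sm)) / n * zbar
      denom <- cov_xz
      b_z <- cov_cz / denom
    }
    list(b_x = b_x, b_z = b_z, denom = denom)
  }

  point <- comp(rep(1, G))
  if (abs(point$denom) < 1e-3) {
    abort_prefiv("instrument-group treatment difference ~ 0 (",
                 signif(point$denom, 3), "): weak instrument, components unstable")
  }
  draws_bx <- matrix(NA_real_, n_boot, length(covariates))
  draws_bz <- matrix(NA_real_, n_boot, length(covariates))
  withr::with_seed(derive_seed(seed, 37L), {
    for (b in seq_len(n_boot)) {
      w <- tabulate(sample.int(G, G, replace = TRUE), nbins = G)
      cb <- comp(w)
      draws_bx[b, ] <- cb$b_x
      draws_bz[b, ] <- cb$b_z
    }
  })
  alpha <- (1 - level) / 2
  qs <- function(d) apply(d, 2, quantile, probs = c(alpha, 1 - alpha),
                          na.rm = TRUE)
  q_bx <- qs(draws_bx)
  q_bz <- qs(draws_bz)
  out <- tibble::tibble(
    covariate = covariates,
    b_x = point$b_x, b_x_low = q_bx[1, ], b_x_high = q_bx[2, ],
    b_z = point$b_z, b_z_low = q_bz[1, ], b_z_high = q_bz[2, ],
    ratio = abs(point$b_z / point$b_x)
  )
  attr(out, "first_stage_diff") <- point$denom
  attr(out, "scaling") <- scaling
  out
}

#' Baseline characteristics by treatment arm
#'
#' A descriptive table in the style of a baseline-characteristics
#' ("Table 1") summary: per-arm counts with percentages for binary
#' covariates (percentages as `100 * count / arm n`, half-up rounded to one
#' decimal) and median, mean and SD for continuous covariates, plus
#' follow-up time in years.
#'
#' @param cohort analysis cohort.
#' @param covariates columns to summarise (default: the cohort's covariate
#'   set).
#' @return long tibble: `variable`, `statistic`, one column per arm.
#' @export
cohort_summary <- function(cohort, covariates = NULL) {
  covariates <- covariates %||% (attr(cohort, "covariates") %||%
                                   setdiff(names(cohort),
                                           c("patient_id", "physician_id",
                                             "practice_id", "exposure")))
  covariates <- intersect(covariates, names(cohort))
  arms <- list(nrt = cohort[cohort$exposure == 0L, ],
               varenicline = cohort[cohort$exposure == 1L, ])
  rows <- list(tibble::tibble(variable = "patients", statistic = "n",
                              nrt = nrow(arms$nrt),
                              varenicline = nrow(arms$varenicline)))
  stat_row <- function(variable, statistic, f) {
    vals <- vapply(arms, function(a) {
      if (nrow(a) == 0) return(NA_real_)
      f(a)
    }, numeric(1))
    tibble::tibble(variable = variable, statistic = statistic,
                   nrt = vals[["nrt"]], varenicline = vals[["varenicline"]])
  }
  for (v in covariates) {
    col <- cohort[[v]]
    if (!is.numeric(col)) next
    vv <- v
    is_binary <- all(stats::na.omit(col) %in% c(0, 1))
    if (is_binary) {
      rows[[length(rows) + 1]] <- stat_row(vv, "count",
        function(a) sum(a[[vv]], na.rm = TRUE))
      rows[[length(rows) + 1]] <- stat_row(vv, "pct",
        function(a) proportion(sum(a[[vv]], na.rm = TRUE), nrow(a), 1))
    } else {
      rows[[length(rows) + 1]] <- stat_row(vv, "median",
        function(a) median(a[[vv]], na.rm = TRUE))
      rows[[length(rows) + 1]] <- stat_row(vv, "mean",
        function(a) mean(a[[vv]], na.rm = TRUE))
      rows[[length(rows) + 1]] <- stat_row(vv, "sd",
        function(a) sd(a[[vv]], na.rm = TRUE))
    }
  }
  if ("followup_days" %in% names(cohort)) {
    rows[[length(rows) + 1]] <- stat_row("followup_years", "mean",
      function(a) mean(a$followup_days / 365.25))
    rows[[length(rows) + 1]] <- stat_row("followup_years", "sd",
      function(a) sd(a$followup_days / 365.25))
  }
  dplyr::bind_rows(rows)
}
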