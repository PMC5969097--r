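#!/usr/bin/env Rscript
# Small Monte-Carlo study on the unmeasured-confounding stress scenario
# (true mortality effect zero): the fully adjusted regression absorbs the
# designed healthy-user bias, the preference-IV estimator centres on the
# null. A 25-replicate illustration; the test suite runs the full 200.

source(file.path("analysis", "_common.R"))

sc <- scenario_confounded(delta = 0)
reps <- simulate_replicates(sc, n_reps = 25, seed = 1,
                            methods = c("iv", "mv_full", "mv_basic"))

summ <- dplyr::summarise(
  dplyr::group_by(reps, method),
  mean_estimate = mean(estimate),
  sd_estimate = sd(estimate),
  mean_se = mean(se_beta),
  .groups = "drop"
)
message("risk difference per 100 at 24 months (true effect = 0):")
for (i in seq_len(nrow(summ))) {
  message(sprintf("  %-9s mean %6.3f (replicate SD %.3f)",
                  summ$method[i], summ$mean_estimate[i], summ$sd_estimate[i]))
}

readr::write_csv(reps, file.path(RESULTS, "07_replicate_estimates.csv"))
readr::write_csv(summ, file.path(RESULTS, "07_replicate_summary.csv"))
message("wrote results/07_replicate_estimates.csv and results/07_replicate_summary.csv")
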