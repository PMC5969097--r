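#!/usr/bin/env Rscript
# The head-to-head of the three confounding-control strategies across all
# horizons, via the orchestrated pipeline: multivariable regression (MI +
# Rubin pooling), propensity matching, and preference-instrument 2SLS.
# The expected contrast under healthy-user confounding: conditional-
# exchangeability estimators drift away from the null over follow-up while
# the IV curve stays close to it.

source(file.path("analysis", "_common.R"))

res <- run_pipeline(study_scenario(), out_dir = file.path(RESULTS, "05_pipeline"))

e <- res$estimates
at24 <- e[!is.na(e$horizon) & e$horizon == 24 & e$outcome == "death_all", ]
message("24-month all-cause mortality, all methods:")
for (i in seq_len(nrow(at24))) {
  r <- at24[i, ]
  message(sprintf("  %-18s %-24s %6.2f (%.2f to %.2f)",
                  r$method, r$scale, r$estimate, r$conf_low, r$conf_high))
}

readr::write_csv(e, file.path(RESULTS, "05_estimates.csv"))
message("wrote results/05_estimates.csv and results/05_pipeline/")
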