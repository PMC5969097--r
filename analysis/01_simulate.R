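#!/usr/bin/env Rscript
# Generate the synthetic prescribing world and record what it looks like.
# Writes the raw tables (CSV + column dictionary) and a generation summary.

source(file.path("analysis", "_common.R"))

sim <- generate_cohort(study_scenario())

message(sprintf("generated %d prescriptions for %d patients under %d physicians",
                nrow(sim$prescriptions), nrow(sim$covariates),
                nrow(sim$physicians)))
message(sprintf("varenicline share of index prescriptions: %.1f%%",
                100 * mean(sim$prescriptions$drug_class[sim$prescriptions$is_first_ever] == "varenicline")))
message(sprintf("BMI missing: %.1f%%; deprivation missing: %.2f%%",
                100 * mean(is.na(sim$covariates$bmi)),
                100 * mean(is.na(sim$covariates$imd))))

# full raw tables are bulky intermediates: keep them out of results/
write_tables(sim, file.path("scratch", "synthetic_emr"), format = "csv")

summary_tab <- data.frame(
  table = c("prescriptions", "covariates", "events", "patients", "physicians"),
  rows = c(nrow(sim$prescriptions), nrow(sim$covariates), nrow(sim$events),
           nrow(sim$patients), nrow(sim$physicians))
)
readr::write_csv(summary_tab, file.path(RESULTS, "01_simulation_summary.csv"))
message("wrote results/01_simulation_summary.csv and scratch/synthetic_emr/")
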