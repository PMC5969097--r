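#!/usr/bin/env Rscript
# Build the physician-preference proxy (varenicline count among the previous
# seven first prescriptions) and quantify its strength: partial F and the
# lag-1 prescriber persistence.

source(file.path("analysis", "_common.R"))

cohort <- study_cohort()$cohort
ivc <- build_preference_proxy(cohort, k = 7, min_prescriptions = 10)
ex <- attr(ivc, "iv_exclusions")
message("instrumented sample exclusions:")
for (i in seq_len(nrow(ex))) {
  message(sprintf("  %-38s %6d", ex$reason[i], ex$n[i]))
}

s <- partial_f(ivc)
print(s)

jsonlite::write_json(
  list(partial_f = s$partial_f,
       first_stage_coef = s$first_stage_coef,
       first_stage_se = s$first_stage_se,
       persistence_pct = s$persistence_pct,
       persistence_ci = s$persistence_ci,
       n = s$n, n_physicians = s$n_clusters),
  file.path(RESULTS, "04_instrument_strength.json"),
  auto_unbox = TRUE, digits = NA)
message("wrote results/04_instrument_strength.json")
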