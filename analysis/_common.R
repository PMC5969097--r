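# Shared setup for the analysis drivers. Every script regenerates what it
# needs from the scenario (generation is deterministic and cheap), so the
# scripts can be run independently or in sequence.

suppressMessages(library(prefiv))

RESULTS <- file.path("results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

# The study world: ~20,000 patients across 400 prescribers, Table-1-style
# covariate margins, healthy-user channeling, 13.6% missing BMI.
study_scenario <- function(seed = 1L) {
  scenario_config(
    n_physicians = 400,
    patients_per_physician = list(mean = 50, dispersion = 8),
    seed = seed
  )
}

study_cohort <- function(seed = 1L) {
  build_cohort(generate_cohort(study_scenario(seed)))
}
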