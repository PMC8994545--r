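# Shared configuration for the analysis scripts.
#
# The cohort here is a desk-scale rendition of the study conditions: the five
# groups keep their published proportions but are scaled down, and trial
# counts are reduced from the session's 180 per deviant dimension, so the
# whole workflow runs in minutes on one CPU. Every script re-simulates
# deterministically from this configuration, so intermediate binaries never
# need to be kept.

library(mmnpipe)

SEED <- 1
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

analysis_simulation_config <- function(seed = SEED) {
  groups <- c(controls = 16, bvFTD = 8, nfvPPA = 4, PCA = 5, ADMCI = 9)
  simulation_config(
    groups = groups,
    n_trials_per_condition = 20,
    coupling_table = default_coupling_table(names(groups)),
    seed = seed
  )
}

analysis_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(analysis_simulation_config())
    cache
  }
})
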