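#!/usr/bin/env Rscript
# Step 1: simulate the synthetic survey cohort.
#
# The study's participant-level data cannot be released, so every later step
# runs on a synthetic cohort with the same statistical structure: a
# stratified sample of non-drinkers and (non-)dependent drinkers who drink
# intermittently but heavily (median around 17 standard drinks per
# occasion). Writes the survey CSVs in both occasion dialects.

suppressPackageStartupMessages(library(grogscreen))

params <- cohort_params(seed = 20260930 %% .Machine$integer.max)
cohort <- simulate_cohort_files(params, "results/cohort", dialect = "drinks")
# a smaller companion cohort demonstrating the beverage-level encoding
simulate_cohort_files(cohort_params(n_participants = 60, seed = params$seed),
                      "results/cohort_beverage", dialect = "beverage")

n_drinkers <- sum(vapply(cohort, function(p) !is.null(p$occasions), logical(1)))
cat(sprintf("Simulated %d participants (%d drinkers, %d non-drinkers)\n",
            params$n_participants, n_drinkers,
            params$n_participants - n_drinkers))
cat("Wrote results/cohort (drinks dialect) and results/cohort_beverage\n")
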