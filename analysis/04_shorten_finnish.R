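#!/usr/bin/env Rscript
# Step 4: how much accuracy do shortened Finnish variants retain?
#
# For every combination of occasions used for quantity (rows) and frequency
# (columns), the squared correlation between the shortened average-drinks-
# per-day estimate and the full four-occasion estimate, on the simulated
# cohort; repeated after dropping drinkers with zero variation in occasion
# quantities.

suppressPackageStartupMessages(library(grogscreen))

occ <- resolve_occasions(read_occasions("results/cohort/occasions.csv"))
resp <- read_responses("results/cohort/responses.csv")
drinker_ids <- resp$person_id[resp$prep_drank == "yes" |
                                resp$check_drank == "yes"]
occ <- occ[occ$person_id %in% drinker_ids, ]

ret <- retention_grid(occ)
cat(sprintf("Retention grid on %d drinkers (%d excluded with <4 in-window occasions)\n",
            ret$n_used, ret$n_excluded))
cat("r^2 retained (%), rows = occasions for quantity, cols = for frequency:\n")
print(round(100 * ret$grid, 1))

novar <- exclude_zero_variance(occ)
ret2 <- retention_grid(novar$occasions)
cat(sprintf("\nAfter dropping %d zero-variance drinkers:\n", novar$n_dropped))
print(round(100 * ret2$grid, 1))

to_long <- function(r) {
  do.call(rbind, lapply(1:4, function(kq) {
    data.frame(k_quantity = kq, k_frequency = 1:4,
               r_squared_percent = round(100 * r$grid[kq, ], 1))
  }))
}
write.csv(to_long(ret), "results/retention.csv", row.names = FALSE)
write.csv(to_long(ret2), "results/retention_zero_variance_excluded.csv",
          row.names = FALSE)
cat("\nWrote results/retention.csv and results/retention_zero_variance_excluded.csv\n")
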