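#!/usr/bin/env Rscript
# Summarize the strategy comparison written by 03_run_strategies.R:
# the per-cycle gain table (genetic-SD units, with Sum row), the
# reciprocal-recurrent comparison for the index strategy, and the
# inbreeding trajectories.

library(safsim)

wide <- read.csv("results/records_all.csv")
as_result <- function(strategy) {
  rec <- wide[wide$strategy == strategy, ]
  structure(list(records = rec, strategy = strategy), class = "sim_result")
}
res <- setNames(lapply(unique(wide$strategy), as_result),
                unique(wide$strategy))

gt <- gain_table(res)
write.csv(gt, "results/gain_table.csv", row.names = FALSE)
print(gt, digits = 3)

sum_gain <- function(strategy, trait) {
  g <- cycle_gains(res[[strategy]])
  mean(aggregate(gain ~ replicate, g[g$trait == trait, ], sum)$gain)
}
for (tr in c("GY", "OL")) {
  idx <- sum_gain("GY_plus_OL", tr)
  rec_exp <- reciprocal_recurrent_expectation(sum_gain("GY", tr),
                                              sum_gain("OL", tr))
  cat(sprintf(
    "%s: index gain %.2f vs reciprocal-recurrent expectation %.2f (%s)\n",
    tr, idx, rec_exp,
    if (idx > rec_exp) "index more efficient" else "index not better"))
}

traj <- inbreeding_trajectory(res)
write.csv(traj, "results/inbreeding_trajectory.csv", row.names = FALSE)
first <- traj[traj$cycle == 1, ]
cat("\nF at the first selected parent set, by strategy:\n")
print(setNames(round(first$F_mean, 3), first$strategy))
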