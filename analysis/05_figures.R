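#!/usr/bin/env Rscript
# Render the GEBV-by-cycle (mean +/- SD) and inbreeding-by-cycle figures
# for the four strategies, from the records written by 03_run_strategies.R.

library(safsim)

wide <- read.csv("results/records_all.csv")
res <- setNames(lapply(unique(wide$strategy), function(s) {
  structure(list(records = wide[wide$strategy == s, ], strategy = s),
            class = "sim_result")
}), unique(wide$strategy))

files <- plot_results(res, "results/figures")
cat("wrote:\n")
cat(paste(" ", files, collapse = "\n"), "\n")
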