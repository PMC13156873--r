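#!/usr/bin/env Rscript
# Build the three plain-text report tables and the count-estimate outcome
# shares from the completed grid (run 02 first).

library(screenstop)

if (!file.exists("results/grid/run_stats.csv")) {
  stop("results/grid/run_stats.csv missing; run analysis/02_run_grid.R first")
}
stats <- readr::read_csv("results/grid/run_stats.csv", show_col_types = FALSE)
rep <- report_grid(stats, "results/report")

message("relative error of the estimated relevant count (%):")
writeLines(rep$t3)
message("\nscreened percent to the last relevant record:")
writeLines(rep$t4)
message("\nlargest irrelevant gap between relevants (% of dataset):")
writeLines(rep$t5)
message("\ncount-estimate outcome shares:")
print(as.data.frame(rep$shares))
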