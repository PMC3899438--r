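#!/usr/bin/env Rscript
# Step 2: replicated sampling under the six designs and RMSE summarization.
#
# Runs the benchmark scenario file (regenerating the same population as step 1
# from its seed), drawing replicated samples under the conventional design
# (M1: 100 clusters per stratum, systematic, all households) and the two-stage
# PPS design (M2: 1000-5000 clusters selected proportional to household
# counts, household fractions 1 down to 1/5), estimating the mean of X and the
# proportion X >= 140 per stratum and in total for every draw, and summarizing
# accuracy as RMSE against the known truth.
#
# Outputs: results/table2_sample_sizes.csv, results/table3_rmse.csv,
#          results/run_summary.json.
#
# Usage: Rscript analysis/02_run_simulations.R [--replicates R] [--seed S]

library(svysim)

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else as.integer(args[i + 1])
}
replicates <- get_arg("--replicates", 1000L)
seed <- get_arg("--seed", NULL)

scenario_path <- if (file.exists("inst/extdata/scenarios/reference.yaml")) {
  "inst/extdata/scenarios/reference.yaml"
} else {
  system.file("extdata", "scenarios", "reference.yaml", package = "svysim")
}

res <- run_scenario(scenario_path, replications = replicates, seed = seed)

cat("\nTotal-population RMSE of the estimated mean of X by scenario:\n")
tot <- res$comparison$rmse$mean_x
print(tot[tot$stratum == "total", -1], row.names = FALSE)
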