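#' Write the population truth table as CSV
#'
#' One row per stratum plus an explicit `"total"` row, with cluster, household
#' and individual counts, the mean of X and the percentage at or above the
#' threshold.
#'
#' @param truth An `svy_truth` object from [summarize_population()].
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_population_table <- function(truth, path) {
  stopifnot(inherits(truth, "svy_truth"))
  out <- data.frame(
    stratum_id = truth$stratum,
    clusters = truth$n_clusters,
    households = truth$n_households,
    individuals = truth$n_individuals,
    mean_x = round(truth$mean_x, 4),
    prop_ge_threshold = round(truth$prop_ge_threshold, 5)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# Wide block table: stratum column + <measure>_<scenario> columns.
block_table <- function(tabs, digits) {
  out <- data.frame(stratum_id = tabs[[1]]$stratum)
  for (measure in names(tabs)) {
    tab <- tabs[[measure]]
    for (nm in setdiff(names(tab), "stratum")) {
      out[[paste(measure, nm, sep = "_")]] <- round(tab[[nm]], digits)
    }
  }
  out
}

#' Write the average-sample-size table as CSV
#'
#' Rows: strata plus total. Column blocks: average selected clusters,
#' households and individuals for every scenario.
#'
#' @param comparison An `svy_comparison` object from [compare_designs()].
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_size_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "svy_comparison"))
  out <- block_table(comparison$sizes, digits = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write the RMSE table as CSV
#'
#' Rows: strata plus total. Column blocks: RMSE of the estimated mean of X and
#' of the estimated proportion above threshold, for every scenario.
#'
#' @param comparison An `svy_comparison` object from [compare_designs()].
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_rmse_table <- function(comparison, path) {
  stopifnot(inherits(comparison, "svy_comparison"))
  out <- block_table(comparison$rmse, digits = 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Write a JSON provenance summary of a simulation run
#'
#' Records the package version, the root seed and per-design derived seeds,
#' the replicate count, a hash of the scenario configuration, and the
#' total-population RMSE changes relative to the conventional design.
#'
#' @param comparison An `svy_comparison` object.
#' @param scenario The `svy_scenario` that produced it.
#' @param path Output JSON path.
#' @return Invisibly, the summary list.
#' @export
write_run_summary <- function(comparison, scenario, path) {
  stopifnot(inherits(comparison, "svy_comparison"))
  summary <- list(
    package = "svysim",
    version = as.character(utils::packageVersion("svysim")),
    root_seed = scenario$seed,
    population_seed = scenario$population$seed,
    design_seeds = stats::setNames(
      vapply(comparison$summaries, `[[`, integer(1), "seed"),
      names(comparison$summaries)),
    replications = comparison$R,
    config_hash = config_hash(scenario),
    scenarios = names(comparison$summaries),
    pct_change_total_rmse = comparison$pct_change_total
  )
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(summary)
}

# Polynomial rolling hash of the deparsed scenario, as a hex string. Stable
# across runs; used for provenance only.
config_hash <- function(x) {
  b <- as.double(charToRaw(paste(deparse(unclass(x)), collapse = "\n")))
  h <- 2166136261 %% 2147483647
  for (i in seq_along(b)) {
    h <- (h * 131 + b[i]) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
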