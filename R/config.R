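#' Read a scenario configuration file
#'
#' Parses a YAML scenario file describing a population, a list of sample
#' designs, a replicate count and a root seed, validating every key. Unknown
#' keys are rejected with a message naming them.
#'
#' The schema (all population keys optional, defaulting to
#' [population_config()] defaults):
#' \preformatted{
#' population:
#'   anchored: true            # use the reference stratum layout
#'   n_strata: 10
#'   cluster_count_range: [4000, 40000]
#'   n_clusters: [...]         # explicit per-stratum counts
#'   households_per_cluster: {mean: 50, sd: 1}
#'   members_range: [1, 6]
#'   mu_h: [...]               # explicit per-stratum means
#'   mu_h_prior: {mean: 130, sd: 2.5}
#'   sigma_h_prior: {mean: 5, sd: 0.1}
#'   sigma_hi_prior: {mean: 7, sd: 0.2}
#'   sigma_hij_prior: {mean: 10, sd: 0.2}
#'   threshold: 140
#'   keep_individuals: false
#'   keep_latent: false
#' designs:
#'   - {name: M1, method: M1, clusters_per_stratum: 100}
#'   - {name: M2-1000, method: M2, n_clusters: 1000, household_fraction: "1/1"}
#' replications: 1000
#' seed: 1
#' output_dir: results
#' }
#'
#' @param path Path to the YAML file.
#' @return An object of class `svy_scenario`: list with `population`
#'   (`svy_popconfig`), `designs` (list of `svy_design`), `replications`,
#'   `seed`, `output_dir`.
#' @export
read_scenario_file <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known_top <- c("population", "designs", "replications", "seed", "output_dir")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown)) {
    stop("unknown top-level keys in scenario file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$designs) || !length(raw$designs)) {
    stop("scenario file must list at least one design", call. = FALSE)
  }
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  p <- if (is.null(raw$population)) list() else raw$population
  known_pop <- c("anchored", "n_strata", "n_clusters", "cluster_count_range",
                 "households_per_cluster", "members_range", "mu_h",
                 "mu_h_prior", "sigma_h_prior", "sigma_hi_prior",
                 "sigma_hij_prior", "threshold", "keep_individuals",
                 "keep_latent")
  unknown <- setdiff(names(p), known_pop)
  if (length(unknown)) {
    stop("unknown population keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  as_pair <- function(v, nm) {
    if (is.null(v)) return(NULL)
    if (is.list(v)) {
      if (!setequal(names(v), c("mean", "sd"))) {
        stop(sprintf("'%s' must be {mean, sd} or a 2-vector", nm), call. = FALSE)
      }
      c(v$mean, v$sd)
    } else {
      as.numeric(v)
    }
  }
  args <- list(seed = seed)
  if (isTRUE(p$anchored)) {
    ref <- reference_strata()
    args$n_strata <- nrow(ref)
    args$n_clusters <- ref$n_clusters
    args$mu_h <- ref$mu_x
  }
  if (!is.null(p$n_strata)) args$n_strata <- p$n_strata
  if (!is.null(p$n_clusters)) args$n_clusters <- unlist(p$n_clusters)
  if (!is.null(p$cluster_count_range)) args$cluster_count_range <- unlist(p$cluster_count_range)
  if (!is.null(p$households_per_cluster)) {
    args$households_per_cluster <- as_pair(p$households_per_cluster, "households_per_cluster")
  }
  if (!is.null(p$members_range)) args$members_range <- unlist(p$members_range)
  if (!is.null(p$mu_h)) args$mu_h <- unlist(p$mu_h)
  for (nm in c("mu_h_prior", "sigma_h_prior", "sigma_hi_prior", "sigma_hij_prior")) {
    if (!is.null(p[[nm]])) args[[nm]] <- as_pair(p[[nm]], nm)
  }
  if (!is.null(p$threshold)) args$threshold <- p$threshold
  if (!is.null(p$keep_individuals)) args$keep_individuals <- p$keep_individuals
  if (!is.null(p$keep_latent)) args$keep_latent <- p$keep_latent
  popcfg <- do.call(population_config, args)

  known_design <- c("name", "method", "clusters_per_stratum", "interval_rule",
                    "n_clusters", "household_fraction", "rounding")
  designs <- lapply(raw$designs, function(d) {
    unknown <- setdiff(names(d), known_design)
    if (length(unknown)) {
      stop("unknown design keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(d$method)) stop("design entry lacks 'method'", call. = FALSE)
    if (d$method == "M1") {
      a <- list()
      if (!is.null(d$clusters_per_stratum)) a$clusters_per_stratum <- d$clusters_per_stratum
      if (!is.null(d$interval_rule)) a$interval_rule <- d$interval_rule
      if (!is.null(d$name)) a$name <- d$name
      do.call(design_m1, a)
    } else if (d$method == "M2") {
      if (is.null(d$n_clusters)) stop("M2 design lacks 'n_clusters'", call. = FALSE)
      a <- list(n_clusters = d$n_clusters)
      if (!is.null(d$household_fraction)) a$f <- d$household_fraction
      if (!is.null(d$rounding)) a$rounding <- d$rounding
      if (!is.null(d$name)) a$name <- d$name
      do.call(design_m2, a)
    } else {
      stop("design method must be 'M1' or 'M2', got: ", d$method, call. = FALSE)
    }
  })

  structure(list(
    population = popcfg,
    designs = designs,
    replications = if (is.null(raw$replications)) 1000L else as.integer(raw$replications),
    seed = seed,
    output_dir = if (is.null(raw$output_dir)) "results" else raw$output_dir
  ), class = "svy_scenario")
}

#' The reference scenario collection of sample designs
#'
#' The designs under study: the conventional design with 100 clusters per
#' stratum (M1) and the two-stage PPS design at 1000 to 5000 total clusters
#' with household fractions 1, 1/2, 1/3, 1/4, 1/5 (M2), i.e. roughly constant
#' expected household sample size across scenarios.
#'
#' @return A list of `svy_design` objects.
#' @export
reference_designs <- function() {
  list(
    design_m1(100),
    design_m2(1000, "1/1"),
    design_m2(2000, "1/2"),
    design_m2(3000, "1/3"),
    design_m2(4000, "1/4"),
    design_m2(5000, "1/5")
  )
}

#' Run a scenario file end to end
#'
#' Generates the population, runs every design with replicated sampling,
#' and writes the population truth table, the sample-size and RMSE tables and
#' a JSON provenance summary into the output directory. Outputs are fully
#' determined by the scenario file (byte-identical on rerun).
#'
#' @param scenario A path to a YAML scenario file or an `svy_scenario` object.
#' @param output_dir Override the scenario's output directory.
#' @param replications Override the scenario's replicate count.
#' @param seed Override the scenario's root seed.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the population, truth, comparison object and
#'   the written file paths.
#' @export
run_scenario <- function(scenario, output_dir = NULL, replications = NULL,
                         seed = NULL, quiet = FALSE) {
  if (is.character(scenario)) scenario <- read_scenario_file(scenario)
  stopifnot(inherits(scenario, "svy_scenario"))
  if (!is.null(seed)) {
    scenario$seed <- as.integer(seed)
    scenario$population$seed <- as.integer(seed)
  }
  if (!is.null(replications)) scenario$replications <- as.integer(replications)
  if (!is.null(output_dir)) scenario$output_dir <- output_dir
  dir.create(scenario$output_dir, recursive = TRUE, showWarnings = FALSE)

  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating population (seed %d)...", scenario$population$seed)
  t0 <- proc.time()[["elapsed"]]
  pop <- generate_population(scenario$population)
  truth <- summarize_population(pop)
  say("  %d clusters, %.0f households, %.0f individuals [%.1f s]",
      nrow(pop$clusters), sum(pop$strata$n_households),
      sum(pop$strata$n_individuals), proc.time()[["elapsed"]] - t0)

  say("running %d designs x %d replicates...", length(scenario$designs),
      scenario$replications)
  cmp <- compare_designs(pop, scenario$designs, R = scenario$replications,
                         seed = derive_seed(scenario$seed, 1001L))

  paths <- c(
    population = file.path(scenario$output_dir, "table1_population.csv"),
    sizes = file.path(scenario$output_dir, "table2_sample_sizes.csv"),
    rmse = file.path(scenario$output_dir, "table3_rmse.csv"),
    summary = file.path(scenario$output_dir, "run_summary.json")
  )
  write_population_table(truth, paths[["population"]])
  write_size_table(cmp, paths[["sizes"]])
  write_rmse_table(cmp, paths[["rmse"]])
  write_run_summary(cmp, scenario, paths[["summary"]])
  say("wrote %s", paste(paths, collapse = ", "))
  invisible(list(population = pop, truth = truth, comparison = cmp,
                 paths = paths))
}
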