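#' Root mean squared error against a known truth
#'
#' `sqrt(mean((estimates - truth)^2))`, the accuracy measure combining the
#' sampling variance and the squared bias of an estimator (with the
#' population-style divisor, `RMSE^2 = Var * (R-1)/R + bias^2` for `R`
#' estimates). Missing estimates (empty domains) are dropped.
#'
#' @param estimates Numeric vector of replicated estimates.
#' @param truth The known population value.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' rmse(c(1, 3), 2)  # 1
rmse <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0L) stop("no estimates supplied", call. = FALSE)
  if (!is.finite(truth)) stop("'truth' must be finite", call. = FALSE)
  sqrt(mean((estimates - truth)^2))
}

#' Replicated sampling under one design
#'
#' Draws `R` independent samples under `design`, estimates the mean of X and
#' the proportion above threshold per stratum and in total for each draw, and
#' summarizes the sampling distributions against the population truth:
#' mean, SD, bias and RMSE per cell, plus average realized sample sizes.
#' Each replicate uses its own RNG stream derived from `seed`, so results are
#' independent of execution order and reproducible.
#'
#' @param pop An object of class `svy_population`.
#' @param design An object of class `svy_design`.
#' @param R Number of replicates (>= 1).
#' @param seed Integer root seed for the replicate streams.
#' @param keep_estimates Retain the per-replicate estimate matrices
#'   (default `FALSE`).
#' @return An object of class `svy_replication_summary`: a list with
#'   `scenario`, `R`, `seed`, `truth` (from [summarize_population()]),
#'   `stats` (long data.frame: `estimand`, `stratum`, `mean`, `sd`, `bias`,
#'   `rmse`, `n_used`), `sizes` (average clusters/households/individuals per
#'   stratum and total), and optionally `estimates`.
#' @export
run_replications <- function(pop, design, R = 1000, seed = 1L,
                             keep_estimates = FALSE) {
  stopifnot(inherits(pop, "svy_population"), inherits(design, "svy_design"),
            R >= 1)
  R <- as.integer(R)
  truth <- summarize_population(pop)
  H <- pop$n_strata
  ncell <- H + 1L
  est_mean <- matrix(NA_real_, R, ncell)
  est_prop <- matrix(NA_real_, R, ncell)
  sz_cl <- matrix(NA_real_, R, ncell)
  sz_hh <- matrix(NA_real_, R, ncell)
  sz_ind <- matrix(NA_real_, R, ncell)
  streams <- rng_streams(seed, R)
  for (r in seq_len(R)) {
    est <- with_rng(streams[[r]], {
      d <- draw_sample(pop, design)
      estimate_draw(d, pop)
    })
    est_mean[r, ] <- est$mean_x
    est_prop[r, ] <- est$prop_ge_threshold
    sz_cl[r, ] <- est$n_clusters
    sz_hh[r, ] <- est$n_households
    sz_ind[r, ] <- est$n_individuals
  }
  cells <- c(as.character(seq_len(H)), "total")
  summarize_cells <- function(mat, truth_vals, estimand) {
    data.frame(
      estimand = estimand,
      stratum = cells,
      mean = colMeans(mat, na.rm = TRUE),
      sd = apply(mat, 2, stats::sd, na.rm = TRUE),
      bias = colMeans(mat, na.rm = TRUE) - truth_vals,
      rmse = vapply(seq_len(ncol(mat)),
                    function(j) rmse(mat[, j], truth_vals[j]), numeric(1)),
      n_used = colSums(!is.na(mat))
    )
  }
  stats_df <- rbind(
    summarize_cells(est_mean, truth$mean_x, "mean_x"),
    summarize_cells(est_prop, truth$prop_ge_threshold, "prop_ge_threshold")
  )
  rownames(stats_df) <- NULL
  sizes <- data.frame(
    stratum = cells,
    avg_clusters = colMeans(sz_cl),
    avg_households = colMeans(sz_hh),
    avg_individuals = colMeans(sz_ind)
  )
  structure(list(
    scenario = design$name,
    design = design,
    R = R,
    seed = as.integer(seed),
    truth = truth,
    stats = stats_df,
    sizes = sizes,
    estimates = if (keep_estimates) {
      list(mean_x = est_mean, prop_ge_threshold = est_prop)
    } else NULL
  ), class = "svy_replication_summary")
}

#' @export
print.svy_replication_summary <- function(x, ...) {
  cat(sprintf("Replication summary: scenario %s, R = %d\n", x$scenario, x$R))
  tot <- x$stats[x$stats$stratum == "total", ]
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %-18s total: mean %.4f  bias %+.5f  RMSE %.5f\n",
                tot$estimand[i], tot$mean[i], tot$bias[i], tot$rmse[i]))
  }
  invisible(x)
}

#' Compare sample designs by replicated RMSE
#'
#' Runs [run_replications()] for every design and assembles wide tables of
#' RMSE (per stratum and total, for both estimands) and of average sample
#' sizes, plus the percent change of each scenario's total RMSE relative to
#' the first M1 design in the list (if present).
#'
#' @param pop An object of class `svy_population`.
#' @param designs A list of `svy_design` objects.
#' @param R Replicates per design.
#' @param seed Root seed; each design gets an independent derived seed.
#' @return An object of class `svy_comparison`: list with `summaries` (named
#'   list of replication summaries), `rmse` (list of two wide data.frames,
#'   one per estimand), `sizes` (list of wide data.frames for clusters,
#'   households, individuals), and `pct_change_total`.
#' @export
compare_designs <- function(pop, designs, R = 1000, seed = 1L) {
  stopifnot(length(designs) >= 1)
  if (inherits(designs, "svy_design")) designs <- list(designs)
  names(designs) <- vapply(designs, `[[`, "", "name")
  summaries <- vector("list", length(designs))
  names(summaries) <- names(designs)
  for (i in seq_along(designs)) {
    summaries[[i]] <- run_replications(pop, designs[[i]], R = R,
                                       seed = derive_seed(seed, i))
  }
  cells <- summaries[[1]]$sizes$stratum
  wide <- function(extract) {
    out <- data.frame(stratum = cells)
    for (nm in names(summaries)) out[[nm]] <- extract(summaries[[nm]])
    out
  }
  rmse_tabs <- list(
    mean_x = wide(function(s) s$stats$rmse[s$stats$estimand == "mean_x"]),
    prop_ge_threshold = wide(function(s)
      s$stats$rmse[s$stats$estimand == "prop_ge_threshold"])
  )
  size_tabs <- list(
    clusters = wide(function(s) s$sizes$avg_clusters),
    households = wide(function(s) s$sizes$avg_households),
    individuals = wide(function(s) s$sizes$avg_individuals)
  )
  base_idx <- which(vapply(designs, `[[`, "", "method") == "M1")[1]
  pct <- NULL
  if (!is.na(base_idx)) {
    base <- summaries[[base_idx]]
    pct <- do.call(rbind, lapply(names(summaries), function(nm) {
      s <- summaries[[nm]]
      data.frame(
        scenario = nm,
        estimand = c("mean_x", "prop_ge_threshold"),
        pct_change_total_rmse = vapply(
          c("mean_x", "prop_ge_threshold"), function(e) {
            r0 <- base$stats$rmse[base$stats$estimand == e &
                                    base$stats$stratum == "total"]
            r1 <- s$stats$rmse[s$stats$estimand == e &
                                 s$stats$stratum == "total"]
            100 * (r1 - r0) / r0
          }, numeric(1))
      )
    }))
    rownames(pct) <- NULL
  }
  structure(list(
    summaries = summaries,
    rmse = rmse_tabs,
    sizes = size_tabs,
    pct_change_total = pct,
    R = as.integer(R),
    seed = as.integer(seed)
  ), class = "svy_comparison")
}

#' @export
print.svy_comparison <- function(x, ...) {
  cat(sprintf("Design comparison: %d scenarios, R = %d\n",
              length(x$summaries), x$R))
  cat("Total-population RMSE, mean of X:\n")
  tot <- x$rmse$mean_x[x$rmse$mean_x$stratum == "total", -1, drop = FALSE]
  print(round(unlist(tot), 4))
  invisible(x)
}
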