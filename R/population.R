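#' Reference stratum layout for the benchmark population
#'
#' The package's benchmark finite population emulates a national household
#' health survey frame with 10 strata standing in for prefectures. This helper
#' returns the anchored per-stratum configuration: the number of clusters
#' (census enumeration areas of about 50 households) and the stratum mean of
#' the continuous outcome X (a systolic-blood-pressure-like variable in mmHg).
#' Anchoring these two quantities fixes the stratum weights and stratum
#' locations of the benchmark, while household counts, household sizes and
#' individual outcomes remain random.
#'
#' @return A data.frame with columns `stratum`, `n_clusters`, `mu_x`.
#' @seealso [reference_config()]
#' @export
#' @examples
#' reference_strata()
reference_strata <- function() {
  data.frame(
    stratum = 1:10,
    n_clusters = c(22708L, 6043L, 31176L, 4161L, 18121L,
                   18841L, 21151L, 32143L, 4538L, 36939L),
    mu_x = c(131.0, 126.0, 128.3, 127.4, 131.8,
             133.5, 130.0, 126.2, 129.1, 131.6)
  )
}

#' Configuration of the hierarchical finite population
#'
#' Describes a four-level finite population: strata contain clusters, clusters
#' contain households, households contain individuals. A continuous outcome X
#' is drawn from a four-level Gaussian hierarchy
#' \deqn{X_{hijk} \sim N(\mu_{hij}, \sigma_{hij}^2), \quad
#'       \mu_{hij} \sim N(\mu_{hi}, \sigma_{hi}^2), \quad
#'       \mu_{hi} \sim N(\mu_h, \sigma_h^2),}
#' with the scale parameters themselves drawn once per unit from Gaussian
#' hyperpriors. A binary indicator flags individuals with X at or above
#' `threshold`.
#'
#' Cluster counts per stratum and stratum means of X may be given either as
#' hyperpriors (`cluster_count_range`, `mu_h_prior`) or anchored to explicit
#' per-stratum values (`n_clusters`, `mu_h`); the anchored mode is used by the
#' benchmark scenario because stratum sizes determine the design weights under
#' study.
#'
#' @param n_strata Number of strata (default 10).
#' @param n_clusters Optional explicit per-stratum cluster counts
#'   (length `n_strata`). Overrides `cluster_count_range`.
#' @param cluster_count_range Inclusive integer bounds of the discrete uniform
#'   distribution of cluster counts per stratum (default `c(4000, 40000)`).
#' @param households_per_cluster `c(mean, sd)` of the Gaussian household count
#'   per cluster (default `c(50, 1)`); draws are rounded to the nearest
#'   integer and floored at 1.
#' @param members_range Inclusive integer support of the uniform household
#'   size (default `c(1, 6)`).
#' @param mu_h Optional explicit per-stratum means of X (length `n_strata`).
#'   Overrides `mu_h_prior`.
#' @param mu_h_prior `c(mean, sd)` hyperprior of stratum means
#'   (default `c(130, 2.5)`).
#' @param sigma_h_prior `c(mean, sd)` hyperprior of the between-cluster SD
#'   within stratum (default `c(5, 0.1)`).
#' @param sigma_hi_prior `c(mean, sd)` hyperprior of the between-household SD
#'   within cluster (default `c(7, 0.2)`).
#' @param sigma_hij_prior `c(mean, sd)` hyperprior of the within-household SD
#'   (default `c(10, 0.2)`).
#' @param threshold Cutoff defining the binary indicator X >= threshold
#'   (default 140).
#' @param seed Integer RNG seed for [generate_population()].
#' @param keep_individuals Retain raw individual X values and indicators in
#'   the population object (default `TRUE`; disable at full scale to save
#'   memory — all estimation uses household/cluster aggregates).
#' @param keep_latent Retain per-household latent parameters
#'   (`mu_hij`, `sigma_hij`) for diagnostics (default `TRUE`); stratum- and
#'   cluster-level latents are always retained.
#' @return An object of class `svy_popconfig`.
#' @seealso [generate_population()], [reference_config()]
#' @export
population_config <- function(n_strata = 10,
                              n_clusters = NULL,
                              cluster_count_range = c(4000, 40000),
                              households_per_cluster = c(50, 1),
                              members_range = c(1, 6),
                              mu_h = NULL,
                              mu_h_prior = c(130, 2.5),
                              sigma_h_prior = c(5, 0.1),
                              sigma_hi_prior = c(7, 0.2),
                              sigma_hij_prior = c(10, 0.2),
                              threshold = 140,
                              seed = 1L,
                              keep_individuals = TRUE,
                              keep_latent = TRUE) {
  chk_scalar <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x)) {
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    }
  }
  chk_prior <- function(x, nm) {
    if (length(x) != 2L || any(!is.finite(x))) {
      stop(sprintf("'%s' must be c(mean, sd) with finite values", nm), call. = FALSE)
    }
    if (x[2] < 0) {
      stop(sprintf("'%s': sd hyperparameter must be >= 0", nm), call. = FALSE)
    }
  }
  chk_scalar(n_strata, "n_strata")
  if (n_strata < 1 || n_strata != round(n_strata)) {
    stop("'n_strata' must be a positive integer", call. = FALSE)
  }
  if (is.null(n_clusters)) {
    if (length(cluster_count_range) != 2L ||
        any(cluster_count_range != round(cluster_count_range)) ||
        cluster_count_range[1] < 1 ||
        cluster_count_range[1] > cluster_count_range[2]) {
      stop("'cluster_count_range' must be integer bounds with 1 <= lo <= hi",
           call. = FALSE)
    }
  } else {
    if (length(n_clusters) != n_strata) {
      stop("'n_clusters' must have length n_strata", call. = FALSE)
    }
    if (any(n_clusters < 1) || any(n_clusters != round(n_clusters))) {
      stop("'n_clusters' entries must be positive integers", call. = FALSE)
    }
  }
  chk_prior(households_per_cluster, "households_per_cluster")
  if (length(members_range) != 2L ||
      any(members_range != round(members_range)) ||
      members_range[1] < 1 || members_range[1] > members_range[2]) {
    stop("'members_range' must be integer bounds with 1 <= lo <= hi", call. = FALSE)
  }
  if (is.null(mu_h)) {
    chk_prior(mu_h_prior, "mu_h_prior")
  } else if (length(mu_h) != n_strata || any(!is.finite(mu_h))) {
    stop("'mu_h' must be finite with length n_strata", call. = FALSE)
  }
  chk_prior(sigma_h_prior, "sigma_h_prior")
  chk_prior(sigma_hi_prior, "sigma_hi_prior")
  chk_prior(sigma_hij_prior, "sigma_hij_prior")
  chk_scalar(threshold, "threshold")
  chk_scalar(seed, "seed")

  structure(list(
    n_strata = as.integer(n_strata),
    n_clusters = if (is.null(n_clusters)) NULL else as.integer(n_clusters),
    cluster_count_range = as.integer(cluster_count_range),
    households_per_cluster = as.double(households_per_cluster),
    members_range = as.integer(members_range),
    mu_h = if (is.null(mu_h)) NULL else as.double(mu_h),
    mu_h_prior = as.double(mu_h_prior),
    sigma_h_prior = as.double(sigma_h_prior),
    sigma_hi_prior = as.double(sigma_hi_prior),
    sigma_hij_prior = as.double(sigma_hij_prior),
    threshold = as.double(threshold),
    seed = as.integer(seed),
    keep_individuals = isTRUE(keep_individuals),
    keep_latent = isTRUE(keep_latent)
  ), class = "svy_popconfig")
}

#' Benchmark population configuration
#'
#' The anchored benchmark scenario: 10 strata with cluster counts and stratum
#' means of X fixed to the reference layout of [reference_strata()], all other
#' hyperparameters at their defaults. At full scale this population holds
#' roughly 34 million individuals in 9.8 million households.
#'
#' @param seed Integer RNG seed.
#' @param keep_individuals,keep_latent Passed to [population_config()];
#'   both default to `FALSE` here because at full scale estimation only needs
#'   household and cluster aggregates.
#' @return An object of class `svy_popconfig`.
#' @export
#' @examples
#' cfg <- reference_config(seed = 1)
#' cfg$n_clusters
reference_config <- function(seed = 1L, keep_individuals = FALSE,
                             keep_latent = FALSE) {
  ref <- reference_strata()
  population_config(
    n_strata = nrow(ref),
    n_clusters = ref$n_clusters,
    mu_h = ref$mu_x,
    seed = seed,
    keep_individuals = keep_individuals,
    keep_latent = keep_latent
  )
}

# Group sums of x over contiguous groups whose last positions are `ends`.
group_sums <- function(x, ends) {
  cs <- cumsum(x)
  cs[ends] - c(0, cs[ends[-length(ends)]])
}

# Clamp strictly negative SD draws to a small positive floor; exact zeros are
# preserved so degenerate (zero-variance) configurations stay exact.
clamp_sigma <- function(x) {
  x[x < 0] <- 1e-6
  x
}

#' Generate the hierarchical finite population
#'
#' Draws the full finite population described by a [population_config()]:
#' per-stratum cluster counts, per-cluster household counts (Gaussian, rounded,
#' floored at 1), household sizes (discrete uniform), the four-level Gaussian
#' outcome X, and the binary indicator X >= threshold. Generation is
#' deterministic given the configuration (including its seed): the same config
#' yields a bit-identical population.
#'
#' Draw order is fixed: all stratum-level quantities first (cluster counts,
#' stratum means, between-cluster SDs), then per stratum the cluster-level
#' draws (household counts, cluster means, between-household SDs), the
#' household-level draws (sizes, household means, within-household SDs), and
#' finally the individual outcomes.
#'
#' Aggregates (count, sum of X, sum of squares, count above threshold) are
#' precomputed per household, cluster and stratum so that replicated
#' estimation never touches individual records.
#'
#' @param config An object of class `svy_popconfig`.
#' @return An object of class `svy_population` with components
#'   `strata`, `clusters`, `households` (data.frames of aggregates),
#'   `individuals` (list with `x` and `b`, if retained), `threshold`, and
#'   `config`.
#' @export
#' @examples
#' cfg <- population_config(n_strata = 2, cluster_count_range = c(5, 10),
#'                          seed = 42)
#' pop <- generate_population(cfg)
#' summarize_population(pop)
generate_population <- function(config) {
  if (!inherits(config, "svy_popconfig")) {
    stop("'config' must be created by population_config()", call. = FALSE)
  }
  H <- config$n_strata
  stream <- rng_streams(config$seed, 1L)[[1L]]
  with_rng(stream, {
    # stratum level
    if (is.null(config$n_clusters)) {
      lo <- config$cluster_count_range[1]; hi <- config$cluster_count_range[2]
      n_h <- lo - 1L + sample.int(hi - lo + 1L, H, replace = TRUE)
    } else {
      n_h <- config$n_clusters
    }
    mu_h <- if (is.null(config$mu_h)) {
      stats::rnorm(H, config$mu_h_prior[1], config$mu_h_prior[2])
    } else {
      config$mu_h
    }
    sigma_h <- clamp_sigma(stats::rnorm(H, config$sigma_h_prior[1],
                                        config$sigma_h_prior[2]))

    cl_list <- vector("list", H)
    hh_list <- vector("list", H)
    ind_x <- if (config$keep_individuals) vector("list", H) else NULL
    for (h in seq_len(H)) {
      nc <- n_h[h]
      # cluster level
      n_hi <- pmax(1L, as.integer(round(stats::rnorm(
        nc, config$households_per_cluster[1], config$households_per_cluster[2]))))
      mu_hi <- stats::rnorm(nc, mu_h[h], sigma_h[h])
      sigma_hi <- clamp_sigma(stats::rnorm(nc, config$sigma_hi_prior[1],
                                           config$sigma_hi_prior[2]))
      # household level
      nhh <- sum(n_hi)
      mlo <- config$members_range[1]; mhi <- config$members_range[2]
      n_hij <- mlo - 1L + sample.int(mhi - mlo + 1L, nhh, replace = TRUE)
      mu_hij <- stats::rnorm(nhh, rep.int(mu_hi, n_hi), rep.int(sigma_hi, n_hi))
      sigma_hij <- clamp_sigma(stats::rnorm(nhh, config$sigma_hij_prior[1],
                                            config$sigma_hij_prior[2]))
      # individual level
      x <- stats::rnorm(sum(n_hij), rep.int(mu_hij, n_hij),
                        rep.int(sigma_hij, n_hij))
      b <- as.double(x >= config$threshold)

      hh_ends <- cumsum(n_hij)
      hh <- data.frame(
        n_members = n_hij,
        sum_x = group_sums(x, hh_ends),
        sum_x2 = group_sums(x * x, hh_ends),
        sum_b = group_sums(b, hh_ends)
      )
      if (config$keep_latent) {
        hh$mu_hij <- mu_hij
        hh$sigma_hij <- sigma_hij
      }
      cl_ends <- cumsum(n_hi)
      cl <- data.frame(
        stratum = rep.int(h, nc),
        cluster = seq_len(nc),
        n_households = n_hi,
        n_individuals = as.integer(group_sums(as.double(n_hij), cl_ends)),
        sum_x = group_sums(hh$sum_x, cl_ends),
        sum_x2 = group_sums(hh$sum_x2, cl_ends),
        sum_b = group_sums(hh$sum_b, cl_ends),
        mu_hi = mu_hi,
        sigma_hi = sigma_hi
      )
      cl_list[[h]] <- cl
      hh_list[[h]] <- hh
      if (config$keep_individuals) ind_x[[h]] <- x
    }
  })

  clusters <- do.call(rbind, cl_list)
  rownames(clusters) <- NULL
  households <- do.call(rbind, hh_list)
  rownames(households) <- NULL
  # household block boundaries per cluster, on the concatenated household table
  clusters$hh_end <- cumsum(clusters$n_households)
  clusters$hh_start <- clusters$hh_end - clusters$n_households + 1L

  strata <- data.frame(
    stratum = seq_len(H),
    n_clusters = as.integer(tapply(clusters$n_households, clusters$stratum, length)),
    n_households = as.integer(tapply(clusters$n_households, clusters$stratum, sum)),
    n_individuals = as.double(tapply(clusters$n_individuals, clusters$stratum, sum)),
    sum_x = as.double(tapply(clusters$sum_x, clusters$stratum, sum)),
    sum_x2 = as.double(tapply(clusters$sum_x2, clusters$stratum, sum)),
    sum_b = as.double(tapply(clusters$sum_b, clusters$stratum, sum)),
    mu_h = mu_h,
    sigma_h = sigma_h
  )
  rownames(strata) <- NULL

  pop <- structure(list(
    n_strata = H,
    threshold = config$threshold,
    strata = strata,
    clusters = clusters,
    households = households,
    individuals = if (config$keep_individuals) {
      x <- unlist(ind_x, use.names = FALSE)
      list(x = x, b = as.integer(x >= config$threshold))
    } else NULL,
    config = config
  ), class = "svy_population")
  pop
}

# Internal constructor used by fixtures and tests: builds a svy_population
# from explicit tables of raw values. `x` is household-contiguous;
# `n_members` is per household; `cluster_stratum` and `cluster_n_households`
# define the cluster frame in (stratum, cluster) order.
population_from_raw <- function(cluster_stratum, cluster_n_households,
                                n_members, x, threshold = 140) {
  stopifnot(length(cluster_stratum) == length(cluster_n_households),
            sum(cluster_n_households) == length(n_members),
            sum(n_members) == length(x),
            all(cluster_n_households >= 1), all(n_members >= 1))
  b <- as.double(x >= threshold)
  hh_ends <- cumsum(n_members)
  households <- data.frame(
    n_members = as.integer(n_members),
    sum_x = group_sums(x, hh_ends),
    sum_x2 = group_sums(x * x, hh_ends),
    sum_b = group_sums(b, hh_ends)
  )
  cl_ends <- cumsum(cluster_n_households)
  clusters <- data.frame(
    stratum = as.integer(cluster_stratum),
    cluster = as.integer(unlist(lapply(
      table(factor(cluster_stratum, levels = unique(cluster_stratum))), seq_len),
      use.names = FALSE)),
    n_households = as.integer(cluster_n_households),
    n_individuals = as.integer(group_sums(as.double(n_members), cl_ends)),
    sum_x = group_sums(households$sum_x, cl_ends),
    sum_x2 = group_sums(households$sum_x2, cl_ends),
    sum_b = group_sums(households$sum_b, cl_ends)
  )
  clusters$hh_end <- cl_ends
  clusters$hh_start <- clusters$hh_end - clusters$n_households + 1L
  H <- length(unique(cluster_stratum))
  strata <- data.frame(
    stratum = seq_len(H),
    n_clusters = as.integer(tapply(clusters$n_households, clusters$stratum, length)),
    n_households = as.integer(tapply(clusters$n_households, clusters$stratum, sum)),
    n_individuals = as.double(tapply(clusters$n_individuals, clusters$stratum, sum)),
    sum_x = as.double(tapply(clusters$sum_x, clusters$stratum, sum)),
    sum_x2 = as.double(tapply(clusters$sum_x2, clusters$stratum, sum)),
    sum_b = as.double(tapply(clusters$sum_b, clusters$stratum, sum))
  )
  rownames(strata) <- NULL
  structure(list(
    n_strata = H,
    threshold = threshold,
    strata = strata,
    clusters = clusters,
    households = households,
    individuals = list(x = x, b = as.integer(b)),
    config = NULL
  ), class = "svy_population")
}

#' Summarize a finite population (the truth table)
#'
#' Computes per-stratum and total counts of clusters, households and
#' individuals together with the mean and SD of X and the proportion of
#' individuals at or above the threshold. These are the benchmark ("truth")
#' values that replicated sampling is judged against.
#'
#' @param pop An object of class `svy_population`.
#' @return A data.frame of class `svy_truth` with one row per stratum plus a
#'   `"total"` row; columns `stratum`, `n_clusters`, `n_households`,
#'   `n_individuals`, `mean_x`, `sd_x`, `prop_ge_threshold`.
#' @export
summarize_population <- function(pop) {
  stopifnot(inherits(pop, "svy_population"))
  s <- pop$strata
  if (nrow(s) == 0L || sum(s$n_individuals) == 0) {
    stop("population is empty", call. = FALSE)
  }
  tot <- data.frame(
    stratum = "total",
    n_clusters = sum(s$n_clusters),
    n_households = sum(s$n_households),
    n_individuals = sum(s$n_individuals),
    sum_x = sum(s$sum_x),
    sum_x2 = sum(s$sum_x2),
    sum_b = sum(s$sum_b)
  )
  out <- rbind(
    data.frame(stratum = as.character(s$stratum), n_clusters = s$n_clusters,
               n_households = s$n_households, n_individuals = s$n_individuals,
               sum_x = s$sum_x, sum_x2 = s$sum_x2, sum_b = s$sum_b),
    tot
  )
  n <- out$n_individuals
  out$mean_x <- out$sum_x / n
  out$sd_x <- ifelse(n > 1,
                     sqrt(pmax(0, (out$sum_x2 - n * out$mean_x^2) / (n - 1))),
                     NA_real_)
  out$prop_ge_threshold <- out$sum_b / n
  out$sum_x <- out$sum_x2 <- out$sum_b <- NULL
  class(out) <- c("svy_truth", "data.frame")
  out
}

#' @export
print.svy_population <- function(x, ...) {
  cat("Hierarchical finite population\n")
  cat(sprintf("  strata: %d   clusters: %d   households: %.0f   individuals: %.0f\n",
              x$n_strata, nrow(x$clusters), sum(x$strata$n_households),
              sum(x$strata$n_individuals)))
  cat(sprintf("  threshold for binary indicator: X >= %g\n", x$threshold))
  cat(sprintf("  individual records retained: %s\n",
              if (is.null(x$individuals)) "no (aggregates only)" else "yes"))
  invisible(x)
}

#' @export
print.svy_popconfig <- function(x, ...) {
  cat("Population configuration\n")
  cat(sprintf("  strata: %d   seed: %d\n", x$n_strata, x$seed))
  if (is.null(x$n_clusters)) {
    cat(sprintf("  clusters per stratum: uniform on [%d, %d]\n",
                x$cluster_count_range[1], x$cluster_count_range[2]))
  } else {
    cat("  clusters per stratum: anchored (", paste(x$n_clusters, collapse = ", "),
        ")\n", sep = "")
  }
  if (is.null(x$mu_h)) {
    cat(sprintf("  stratum means: N(%g, %g^2)\n", x$mu_h_prior[1], x$mu_h_prior[2]))
  } else {
    cat("  stratum means: anchored\n")
  }
  invisible(x)
}
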