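#' Design-weighted mean (Hajek estimator)
#'
#' Weighted ratio form `sum(w * x) / sum(w)`, the estimator survey software
#' applies for means under unequal-probability designs.
#'
#' @param values Numeric values.
#' @param weights Positive weights, same length.
#' @return The weighted mean.
#' @export
#' @examples
#' weighted_mean(c(1, 2, 3), c(1, 1, 2))  # 2.25
weighted_mean <- function(values, weights) {
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  if (length(values) != length(weights)) {
    stop("'values' and 'weights' must have equal length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  sum(weights * values) / sum(weights)
}

#' Design-weighted proportion
#'
#' [weighted_mean()] applied to a 0/1 indicator.
#'
#' @param indicators 0/1 values.
#' @param weights Positive weights, same length.
#' @return Weighted proportion in `[0, 1]`.
#' @export
#' @examples
#' weighted_proportion(c(1, 0), c(3, 1))  # 0.75
weighted_proportion <- function(indicators, weights) {
  if (!all(indicators %in% c(0, 1))) {
    stop("indicators must be 0 or 1", call. = FALSE)
  }
  weighted_mean(indicators, weights)
}

#' Design-weighted estimates from a sample draw
#'
#' Computes the Hajek-weighted mean of X and proportion of the binary
#' indicator, per stratum and for the total population, from one sample draw.
#' Under M1 weights are the stratum constants; under M2 individuals inherit
#' their household's weight. Stratum results under M2 are domain estimates
#' (strata are not sampling strata of that design); a stratum with no sampled
#' household yields `NA` and is counted by the simulation layer. All sums use
#' the population's precomputed cluster/household aggregates — households are
#' always sampled intact, so household sums suffice.
#'
#' @param draw An object of class `svy_sample` from [draw_sample()].
#' @param pop The `svy_population` the draw was taken from.
#' @return A data.frame of class `svy_estimates` with one row per stratum plus
#'   a `"total"` row; columns `stratum`, `mean_x`, `prop_ge_threshold`,
#'   `n_clusters`, `n_households`, `n_individuals`.
#' @export
estimate_draw <- function(draw, pop) {
  stopifnot(inherits(draw, "svy_sample"), inherits(pop, "svy_population"))
  H <- pop$n_strata
  if (draw$method == "M1") {
    sx <- sb <- ni <- nh <- nc <- numeric(H)
    for (h in seq_len(H)) {
      rows <- draw$cluster_rows[[h]]
      if (max(rows) > nrow(pop$clusters)) stop("draw/population mismatch", call. = FALSE)
      sx[h] <- sum(pop$clusters$sum_x[rows])
      sb[h] <- sum(pop$clusters$sum_b[rows])
      ni[h] <- sum(pop$clusters$n_individuals[rows])
      nh[h] <- sum(pop$clusters$n_households[rows])
      nc[h] <- length(rows)
    }
    w <- draw$stratum_weight
    mean_h <- sx / ni                       # constant weights cancel in-stratum
    prop_h <- sb / ni
    mean_tot <- sum(w * sx) / sum(w * ni)
    prop_tot <- sum(w * sb) / sum(w * ni)
    out <- data.frame(
      stratum = c(as.character(seq_len(H)), "total"),
      mean_x = c(mean_h, mean_tot),
      prop_ge_threshold = c(prop_h, prop_tot),
      n_clusters = c(nc, sum(nc)),
      n_households = c(nh, sum(nh)),
      n_individuals = c(ni, sum(ni))
    )
  } else {
    rows <- draw$hh_rows
    if (length(rows) == 0L || max(rows) > nrow(pop$households)) {
      stop("draw/population mismatch", call. = FALSE)
    }
    w_hh <- draw$cluster_weight[draw$hh_cluster]
    strat_hh <- pop$clusters$stratum[draw$cluster_rows[draw$hh_cluster]]
    sx <- pop$households$sum_x[rows]
    sb <- pop$households$sum_b[rows]
    nm <- pop$households$n_members[rows]
    g <- factor(strat_hh, levels = seq_len(H))
    agg <- rowsum(cbind(wsx = w_hh * sx, wsb = w_hh * sb, wn = w_hh * nm,
                        ni = nm, one = rep(1, length(rows))),
                  g)
    # rowsum drops absent levels; re-expand
    full <- matrix(0, nrow = H, ncol = ncol(agg),
                   dimnames = list(seq_len(H), colnames(agg)))
    full[rownames(agg), ] <- agg
    nc <- tabulate(pop$clusters$stratum[draw$cluster_rows], nbins = H)
    mean_h <- ifelse(full[, "wn"] > 0, full[, "wsx"] / full[, "wn"], NA_real_)
    prop_h <- ifelse(full[, "wn"] > 0, full[, "wsb"] / full[, "wn"], NA_real_)
    out <- data.frame(
      stratum = c(as.character(seq_len(H)), "total"),
      mean_x = c(mean_h, sum(full[, "wsx"]) / sum(full[, "wn"])),
      prop_ge_threshold = c(prop_h, sum(full[, "wsb"]) / sum(full[, "wn"])),
      n_clusters = c(nc, sum(nc)),
      n_households = c(full[, "one"], sum(full[, "one"])),
      n_individuals = c(full[, "ni"], sum(full[, "ni"]))
    )
  }
  rownames(out) <- NULL
  class(out) <- c("svy_estimates", "data.frame")
  out
}
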