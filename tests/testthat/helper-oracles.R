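# Brute-force Hajek estimation from raw individual records, independent of
# estimate_draw(). Works on populations that retain individual values.
brute_hajek <- function(pop, draw) {
  stopifnot(!is.null(pop$individuals))
  hh_end <- cumsum(pop$households$n_members)
  hh_start <- hh_end - pop$households$n_members + 1L
  xs <- list(); ws <- list(); ss <- list()
  if (draw$method == "M1") {
    for (h in seq_len(pop$n_strata)) {
      for (row in draw$cluster_rows[[h]]) {
        for (j in pop$clusters$hh_start[row]:pop$clusters$hh_end[row]) {
          idx <- hh_start[j]:hh_end[j]
          xs[[length(xs) + 1L]] <- pop$individuals$x[idx]
          ws[[length(ws) + 1L]] <- rep(draw$stratum_weight[h], length(idx))
          ss[[length(ss) + 1L]] <- rep(h, length(idx))
        }
      }
    }
  } else {
    for (i in seq_along(draw$hh_rows)) {
      j <- draw$hh_rows[i]
      ci <- draw$hh_cluster[i]
      idx <- hh_start[j]:hh_end[j]
      xs[[length(xs) + 1L]] <- pop$individuals$x[idx]
      ws[[length(ws) + 1L]] <- rep(draw$cluster_weight[ci], length(idx))
      ss[[length(ss) + 1L]] <- rep(pop$clusters$stratum[draw$cluster_rows[ci]],
                                   length(idx))
    }
  }
  x <- unlist(xs); w <- unlist(ws); s <- unlist(ss)
  b <- as.numeric(x >= pop$threshold)
  res <- data.frame(stratum = character(0), mean_x = numeric(0),
                    prop = numeric(0))
  for (h in seq_len(pop$n_strata)) {
    sel <- s == h
    res <- rbind(res, data.frame(
      stratum = as.character(h),
      mean_x = if (any(sel)) sum(w[sel] * x[sel]) / sum(w[sel]) else NA_real_,
      prop = if (any(sel)) sum(w[sel] * b[sel]) / sum(w[sel]) else NA_real_))
  }
  rbind(res, data.frame(stratum = "total",
                        mean_x = sum(w * x) / sum(w),
                        prop = sum(w * b) / sum(w)))
}

# Small random-mode population used by several tests.
small_random_pop <- function(seed = 99, n_strata = 3,
                             cluster_range = c(30, 60), ...) {
  generate_population(population_config(
    n_strata = n_strata, cluster_count_range = cluster_range,
    households_per_cluster = c(8, 1), seed = seed, ...))
}
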