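test_that("configuration validation names the offending field", {
  expect_error(population_config(n_strata = 0), "n_strata")
  expect_error(population_config(cluster_count_range = c(10, 5)),
               "cluster_count_range")
  expect_error(population_config(sigma_h_prior = c(5, -0.1)), "sigma_h_prior")
  expect_error(population_config(n_strata = 3, n_clusters = c(10, 20)),
               "n_clusters")
  expect_error(population_config(n_strata = 2, mu_h = c(130, NA)), "mu_h")
  expect_error(population_config(threshold = Inf), "threshold")
})

test_that("generation is deterministic given config and seed", {
  cfg <- population_config(n_strata = 2, cluster_count_range = c(10, 20),
                           households_per_cluster = c(6, 1), seed = 31)
  p1 <- generate_population(cfg)
  p2 <- generate_population(cfg)
  expect_identical(p1$clusters, p2$clusters)
  expect_identical(p1$households, p2$households)
  expect_identical(p1$individuals, p2$individuals)
  p3 <- generate_population(population_config(
    n_strata = 2, cluster_count_range = c(10, 20),
    households_per_cluster = c(6, 1), seed = 32))
  expect_false(identical(p1$individuals$x, p3$individuals$x))
})

test_that("population satisfies its structural invariants", {
  pop <- small_random_pop(seed = 12)
  expect_true(all(pop$clusters$n_households >= 1))
  expect_true(all(pop$households$n_members >= 1 & pop$households$n_members <= 6))
  expect_equal(sum(pop$households$n_members), length(pop$individuals$x))
  expect_equal(sum(pop$clusters$n_households), nrow(pop$households))
  expect_identical(pop$individuals$b,
                   as.integer(pop$individuals$x >= pop$threshold))
  # cluster rows sorted by (stratum, cluster) with per-parent unique ids
  expect_true(!is.unsorted(pop$clusters$stratum))
  for (h in seq_len(pop$n_strata)) {
    ids <- pop$clusters$cluster[pop$clusters$stratum == h]
    expect_identical(ids, seq_along(ids))
  }
})

test_that("degenerate zero-variance configuration gives constant X", {
  cfg <- population_config(
    n_strata = 2, cluster_count_range = c(5, 5),
    mu_h = c(130, 130),
    sigma_h_prior = c(0, 0), sigma_hi_prior = c(0, 0),
    sigma_hij_prior = c(0, 0), seed = 4)
  pop <- generate_population(cfg)
  expect_true(all(pop$individuals$x == 130))
  tr <- summarize_population(pop)
  expect_equal(tr$prop_ge_threshold, rep(0, 3))
  expect_equal(tr$mean_x, rep(130, 3))
})

test_that("negative sigma draws are floored, keeping all scales positive", {
  # hyperprior centered below zero forces negative draws
  cfg <- population_config(n_strata = 1, cluster_count_range = c(30, 30),
                           sigma_hi_prior = c(-5, 0.1), seed = 8)
  pop <- generate_population(cfg)
  expect_true(all(pop$clusters$sigma_hi > 0))
})

test_that("realized variance matches the four-level hierarchy's law of total variance", {
  pop <- generate_population(population_config(
    n_strata = 4, cluster_count_range = c(150, 250),
    households_per_cluster = c(20, 1), seed = 21))
  tr <- summarize_population(pop)
  tot <- tr[tr$stratum == "total", ]
  n <- tot$n_individuals
  realized_var <- tot$sd_x^2 * (n - 1) / n
  # prediction from the realized latent household parameters:
  # Var(X) = Var_ind(mu_hij) + E_ind(sigma_hij^2)
  w <- pop$households$n_members
  mu <- pop$households$mu_hij
  mbar <- sum(w * mu) / sum(w)
  predicted <- sum(w * (mu - mbar)^2) / sum(w) +
    sum(w * pop$households$sigma_hij^2) / sum(w)
  expect_lt(abs(realized_var - predicted) / predicted, 0.02)
})

test_that("anchored-mode variance decomposes into between-strata plus within components", {
  ref <- reference_strata()
  pop <- generate_population(population_config(
    n_strata = 10, n_clusters = rep(500L, 10), mu_h = ref$mu_x, seed = 17))
  tr <- summarize_population(pop)
  tot <- tr[tr$stratum == "total", ]
  n_h <- pop$strata$n_individuals
  mu_h <- ref$mu_x
  between <- sum(n_h * (mu_h - sum(n_h * mu_h) / sum(n_h))^2) / sum(n_h)
  predicted <- between + 5^2 + 7^2 + 10^2
  realized <- tot$sd_x^2
  expect_lt(abs(realized - predicted) / predicted, 0.02)
})

test_that("threshold exceedance matches the Gaussian tail implied by realized latents", {
  pop <- generate_population(population_config(
    n_strata = 3, cluster_count_range = c(100, 200),
    households_per_cluster = c(15, 1), seed = 33))
  tr <- summarize_population(pop)
  tot <- tr[tr$stratum == "total", ]
  w <- pop$households$n_members
  p_hh <- stats::pnorm(pop$threshold, pop$households$mu_hij,
                       pop$households$sigma_hij, lower.tail = FALSE)
  predicted <- sum(w * p_hh) / sum(w)
  se <- sqrt(sum(w^2 * p_hh * (1 - p_hh))) / sum(w)
  expect_lt(abs(tot$prop_ge_threshold - predicted), 3 * se + 1e-12)
})

test_that("summaries are exact on a hand-built two-point census", {
  pop <- svysim:::population_from_raw(
    cluster_stratum = 1L, cluster_n_households = 2L,
    n_members = c(1L, 1L), x = c(130, 150), threshold = 140)
  tr <- summarize_population(pop)
  expect_equal(tr$mean_x, c(140, 140))
  expect_equal(tr$prop_ge_threshold, c(0.5, 0.5))
  expect_equal(tr$n_individuals, c(2, 2))
})

test_that("stratum summaries add up to the total", {
  pop <- small_random_pop(seed = 44, n_strata = 4)
  tr <- summarize_population(pop)
  strat <- tr[tr$stratum != "total", ]
  tot <- tr[tr$stratum == "total", ]
  expect_equal(sum(strat$n_individuals), tot$n_individuals)
  expect_equal(sum(strat$n_households), tot$n_households)
  # individual-count-weighted combination of stratum means equals total mean
  expect_equal(sum(strat$n_individuals * strat$mean_x) / tot$n_individuals,
               tot$mean_x, tolerance = 1e-12)
})

test_that("precomputed aggregates equal brute-force recomputation from raw values", {
  pop <- small_random_pop(seed = 55)
  hh_end <- cumsum(pop$households$n_members)
  hh_start <- hh_end - pop$households$n_members + 1L
  set.seed(1)
  check_rows <- sample.int(nrow(pop$clusters), min(100, nrow(pop$clusters)))
  for (row in check_rows) {
    jj <- pop$clusters$hh_start[row]:pop$clusters$hh_end[row]
    idx <- unlist(lapply(jj, function(j) hh_start[j]:hh_end[j]))
    x <- pop$individuals$x[idx]
    expect_equal(pop$clusters$sum_x[row], sum(x), tolerance = 1e-9)
    expect_equal(pop$clusters$sum_x2[row], sum(x^2), tolerance = 1e-9)
    expect_equal(pop$clusters$sum_b[row], sum(x >= pop$threshold))
    expect_equal(pop$clusters$n_individuals[row], length(x))
  }
})

test_that("empty population is rejected", {
  pop <- make_fixture("toy3cluster")
  pop$strata <- pop$strata[0, ]
  expect_error(summarize_population(pop), "empty")
})
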