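test_that("systematic sampling: census, errors, fractional inclusion probabilities", {
  set.seed(1)
  expect_identical(systematic_sample(10, 10), 1:10)
  expect_error(systematic_sample(10, 11), "exceeds")
  expect_error(systematic_sample(10, 0), "positive")
  # fractional rule: inclusion probability n/N for every unit, by integrating
  # the start distribution over a fine deterministic grid
  N <- 10; n <- 2; k <- N / n
  grid <- (seq_len(5000) - 0.5) / 5000 * k
  counts <- numeric(N)
  for (u in grid) {
    pos <- ceiling(u + (seq_len(n) - 1) * k)
    counts[pos] <- counts[pos] + 1
  }
  expect_equal(counts / length(grid), rep(n / N, N), tolerance = 1e-3)
  # and the implementation always returns n distinct in-range positions
  for (i in 1:200) {
    pos <- systematic_sample(N, n)
    expect_length(unique(pos), n)
    expect_true(all(pos >= 1 & pos <= N))
  }
})

test_that("integer-interval systematic rules produce the enumerable size profile", {
  # frame 4161, target 100, ceil interval k = 42: starts 1..3 give 100 units,
  # starts 4..42 give 99; mean size over starts = 99.07
  sizes_by_start <- vapply(1:42, function(s) length(seq.int(s, 4161, by = 42)),
                           integer(1))
  expect_equal(sort(unique(sizes_by_start)), c(99L, 100L))
  expect_equal(mean(sizes_by_start), 99.07, tolerance = 0.005)
  set.seed(2)
  obs <- replicate(300, length(systematic_sample(4161, 100, "ceil")))
  expect_true(all(obs %in% c(99L, 100L)))
  expect_lt(abs(mean(obs) - mean(sizes_by_start)), 0.1)
  # floor rule can overshoot the target instead
  set.seed(3)
  obs_f <- replicate(50, length(systematic_sample(4161, 100, "floor")))
  expect_true(all(obs_f >= 100))
})

test_that("systematic PPS has fixed take and proportional inclusion probabilities", {
  set.seed(4)
  # fixed take over 10^4 random frames
  ok_take <- ok_pi <- TRUE
  for (i in 1:10000) {
    sizes <- sample.int(20, sample(2:12, 1), replace = TRUE)
    n <- sample.int(max(1, floor(sum(sizes) / max(sizes))), 1)
    res <- systematic_pps(sizes, n)
    ok_take <- ok_take && length(unique(res$positions)) == n
    ok_pi <- ok_pi && isTRUE(all.equal(res$pi, pmin(n * sizes / sum(sizes), 1)))
  }
  expect_true(ok_take)
  expect_true(ok_pi)
  # empirical frequencies on the 4-unit frame match pi within 3 binomial SEs
  sizes <- c(1, 2, 3, 4); n <- 2
  pi <- n * sizes / sum(sizes)
  set.seed(5)
  draws <- 20000
  counts <- numeric(4)
  for (i in seq_len(draws)) {
    p <- systematic_pps(sizes, n)$positions
    counts[p] <- counts[p] + 1
  }
  freq <- counts / draws
  se <- sqrt(pi * (1 - pi) / draws)
  expect_true(all(abs(freq - pi) <= 3 * se))
  # symmetry and two-unit cases
  expect_equal(systematic_pps(rep(3, 6), 2)$pi, rep(2 / 6, 6))
  r <- systematic_pps(c(5, 5), 1)
  expect_equal(r$pi, c(0.5, 0.5))
  expect_length(r$positions, 1)
  # certainty units rejected
  expect_error(systematic_pps(c(10, 1, 1), 2), "certainty")
  expect_error(systematic_pps(c(0, 1), 1), "positive")
})

test_that("SRSWOR is equiprobable with m/N inclusion probabilities", {
  set.seed(6)
  expect_setequal(srswor(5, 5), 1:5)
  expect_identical(srswor(1, 1), 1L)
  expect_error(srswor(5, 6), "exceeds")
  draws <- 20000
  counts <- numeric(5)
  for (i in seq_len(draws)) {
    p <- srswor(5, 2)
    counts[p] <- counts[p] + 1
  }
  se <- sqrt(0.4 * 0.6 / draws)
  expect_true(all(abs(counts / draws - 0.4) <= 3 * se))
})

test_that("second-stage counts follow exact rational arithmetic", {
  expect_equal(second_stage_count(50, 1, 1), 50L)          # census fraction
  expect_equal(second_stage_count(50, 1, 4), 13L)          # ceil(12.5)
  expect_equal(second_stage_count(51, 1, 2), 26L)          # ceil(25.5)
  expect_equal(second_stage_count(3, 1, 3), 1L)            # exact third, no FP
  expect_equal(second_stage_count(48, 1, 3), 16L)
  expect_equal(second_stage_count(52, 1, 5, "nearest"), 10L)  # round(10.4)
  expect_equal(second_stage_count(50, 1, 4, "nearest"), 13L)  # half rounds up
  expect_equal(second_stage_count(1, 1, 5), 1L)            # floored at 1
  # vectorized over cluster sizes
  expect_equal(second_stage_count(c(48, 49, 50, 51, 52), 1, 4),
               c(12L, 13L, 13L, 13L, 13L))
})

test_that("M1 draws enumerate census strata and satisfy the exact weight identity", {
  # census stratum: selecting every cluster makes the weight exactly 1
  eq <- make_fixture("single_stratum_equal")
  set.seed(7)
  d <- draw_method1(eq, design_m1(eq$strata$n_clusters[1]))
  expect_equal(d$stratum_weight, 1)
  pop <- make_fixture("two_strata")
  set.seed(8)
  for (i in 1:25) {
    d <- draw_method1(pop, design_m1(4))
    expect_true(all(is.finite(d$stratum_weight)) && all(d$stratum_weight > 0))
    # sum of weights over sampled individuals = stratum population, exactly
    expect_equal(d$stratum_weight * d$n_sampled_individuals,
                 pop$strata$n_individuals, tolerance = 1e-12)
  }
  expect_error(draw_method1(pop, design_m1(10^6)), "exceeds")
})

test_that("M1 average sampled individuals per stratum matches its expectation", {
  pop <- generate_population(population_config(
    n_strata = 2, cluster_count_range = c(400, 500),
    households_per_cluster = c(10, 1), seed = 61))
  npm <- 80
  expected <- npm * pop$strata$n_individuals / pop$strata$n_clusters
  s <- run_replications(pop, design_m1(npm), R = 300, seed = 62)
  avg <- s$sizes$avg_individuals[s$sizes$stratum != "total"]
  expect_true(all(abs(avg - expected) / expected < 0.01))
})

test_that("M2 allocation is contiguous: per-stratum cluster counts track n x stratum share", {
  pop <- make_fixture("two_strata")
  n <- 10
  share <- n * pop$strata$n_households / sum(pop$strata$n_households)
  set.seed(9)
  for (i in 1:50) {
    d <- draw_method2(pop, design_m2(n, "1/2"))
    counts <- tabulate(pop$clusters$stratum[d$cluster_rows], nbins = 2)
    expect_true(all(abs(counts - share) < 1))
    expect_true(all(d$pi > 0 & d$pi <= 1))
    expect_true(all(is.finite(d$cluster_weight) & d$cluster_weight > 0))
    expect_equal(anyDuplicated(d$hh_rows), 0L)
  }
})

test_that("M2 weighted household totals are design-unbiased", {
  pop <- make_fixture("two_strata")
  des <- design_m2(8, "1/2")
  R <- 2000
  set.seed(10)
  totals <- vapply(seq_len(R), function(i) {
    d <- draw_method2(pop, des)
    sum(d$cluster_weight[d$hh_cluster])
  }, numeric(1))
  truth <- sum(pop$strata$n_households)
  se <- stats::sd(totals) / sqrt(R)
  expect_lt(abs(mean(totals) - truth), 3 * se)
})

test_that("design specification rejects invalid inputs", {
  expect_error(design_m1(0), "positive")
  expect_error(design_m2(0, 1), "positive")
  expect_error(design_m2(100, "0/3"), "0 < f")
  expect_error(design_m2(100, "4/3"), "0 < f")
  expect_error(design_m2(100, "a/b"), "parse")
  d <- design_m2(2000, "1/2")
  expect_equal(c(d$f_num, d$f_den), c(1L, 2L))
  expect_equal(d$name, "M2-2000")
})
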