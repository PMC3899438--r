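#' Specify the conventional constant-cluster design (Method 1)
#'
#' One-stage stratified cluster sampling as used by large national household
#' surveys with equal allocation: a fixed number of clusters is drawn from
#' every stratum by systematic random sampling without replacement, and all
#' households of the selected clusters enter the sample. Individual design
#' weights are constant within stratum: stratum population individuals divided
#' by realized sampled individuals.
#'
#' @param clusters_per_stratum Clusters drawn per stratum (default 100).
#' @param interval_rule Systematic interval rule: `"fractional"` (real-valued
#'   interval, always the exact target size; default), `"ceil"` or `"floor"`
#'   (integer interval, realized size may deviate from the target).
#' @param name Scenario label.
#' @return An object of class `svy_design`.
#' @seealso [design_m2()], [draw_sample()]
#' @export
design_m1 <- function(clusters_per_stratum = 100,
                      interval_rule = c("fractional", "ceil", "floor"),
                      name = "M1") {
  interval_rule <- match.arg(interval_rule)
  if (length(clusters_per_stratum) != 1L || clusters_per_stratum < 1 ||
      clusters_per_stratum != round(clusters_per_stratum)) {
    stop("'clusters_per_stratum' must be a positive integer", call. = FALSE)
  }
  structure(list(
    method = "M1",
    name = name,
    clusters_per_stratum = as.integer(clusters_per_stratum),
    interval_rule = interval_rule
  ), class = "svy_design")
}

#' Specify the two-stage PPS design (Method 2)
#'
#' Two-stage cluster sampling of households: in the first stage `n_clusters`
#' clusters are selected across all strata jointly, with probability
#' proportional to their household counts, by fixed-take systematic PPS on the
#' frame sorted by (stratum, cluster) — the sort gives implicit
#' stratification. In the second stage a fraction `f` of each selected
#' cluster's households is drawn by simple random sampling without
#' replacement. Household design weights are the inverse of the product of the
#' cluster inclusion probability and the realized household sampling fraction.
#'
#' @param n_clusters Total clusters selected across strata.
#' @param f Household sampling fraction as an exact rational: either a string
#'   `"1/3"`, a length-2 integer vector `c(numerator, denominator)`, or a
#'   single integer for a unit fraction denominator is 1 (so `f = 1` means all
#'   households).
#' @param rounding Second-stage count rounding rule applied to
#'   `f * N` households: `"ceil"` (default) or `"nearest"`.
#' @param name Scenario label; defaults to `"M2-<n_clusters>"`.
#' @return An object of class `svy_design`.
#' @export
#' @examples
#' design_m2(2000, "1/2")
#' design_m2(1000, 1)
design_m2 <- function(n_clusters, f = 1,
                      rounding = c("ceil", "nearest"),
                      name = NULL) {
  rounding <- match.arg(rounding)
  if (length(n_clusters) != 1L || n_clusters < 1 ||
      n_clusters != round(n_clusters)) {
    stop("'n_clusters' must be a positive integer", call. = FALSE)
  }
  fr <- parse_fraction(f)
  if (fr[1] <= 0 || fr[1] > fr[2]) {
    stop("'f' must satisfy 0 < f <= 1", call. = FALSE)
  }
  structure(list(
    method = "M2",
    name = if (is.null(name)) sprintf("M2-%d", as.integer(n_clusters)) else name,
    n_clusters = as.integer(n_clusters),
    f_num = fr[1],
    f_den = fr[2],
    rounding = rounding
  ), class = "svy_design")
}

# Parse a fraction given as "a/b", c(a, b), or a whole number.
parse_fraction <- function(f) {
  if (is.character(f)) {
    parts <- strsplit(f, "/", fixed = TRUE)[[1L]]
    if (!length(parts) %in% 1:2 || anyNA(suppressWarnings(as.numeric(parts)))) {
      stop("cannot parse fraction: ", f, call. = FALSE)
    }
    num <- as.numeric(parts[1])
    den <- if (length(parts) == 2L) as.numeric(parts[2]) else 1
  } else if (length(f) == 2L) {
    num <- f[1]; den <- f[2]
  } else if (length(f) == 1L) {
    num <- f; den <- 1
  } else {
    stop("fraction must be \"a/b\", c(a, b), or a scalar", call. = FALSE)
  }
  if (any(c(num, den) != round(c(num, den))) || den < 1 || num < 0) {
    stop("fraction must have integer numerator and positive integer denominator",
         call. = FALSE)
  }
  c(as.integer(num), as.integer(den))
}

#' @export
print.svy_design <- function(x, ...) {
  if (x$method == "M1") {
    cat(sprintf("Design %s: stratified systematic cluster sampling, %d clusters/stratum (%s interval)\n",
                x$name, x$clusters_per_stratum, x$interval_rule))
  } else {
    cat(sprintf("Design %s: two-stage PPS, %d clusters, household fraction %d/%d (%s rounding)\n",
                x$name, x$n_clusters, x$f_num, x$f_den, x$rounding))
  }
  invisible(x)
}

#' Systematic random sampling without replacement
#'
#' Selects positions from an ordered frame at a fixed interval after a random
#' start. Under the `"fractional"` rule the interval is the real number
#' `frame_size / n`, the start is uniform on `(0, k]`, and exactly `n`
#' distinct positions `ceiling(u + j * k)` are returned. Under the `"ceil"` /
#' `"floor"` rules the interval is the integer `ceiling(frame_size / n)` /
#' `floor(frame_size / n)`, the start is a uniform integer in `1..k`, and the
#' realized sample size may deviate from `n`.
#'
#' @param frame_size Number of units in the frame.
#' @param n Target sample size, `1 <= n <= frame_size`.
#' @param interval_rule `"fractional"` (default), `"ceil"`, or `"floor"`.
#' @return Ordered integer vector of selected positions.
#' @export
#' @examples
#' set.seed(1)
#' systematic_sample(10, 2)
systematic_sample <- function(frame_size, n,
                              interval_rule = c("fractional", "ceil", "floor")) {
  interval_rule <- match.arg(interval_rule)
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (n > frame_size) {
    stop(sprintf("sample size %d exceeds frame size %d", n, frame_size),
         call. = FALSE)
  }
  if (interval_rule == "fractional") {
    k <- frame_size / n
    u <- k * stats::runif(1)          # uniform on (0, k]; runif never returns 0
    pos <- as.integer(ceiling(u + (seq_len(n) - 1) * k))
    pos[pos > frame_size] <- as.integer(frame_size)  # guard against roundoff at the edge
    pos
  } else {
    k <- if (interval_rule == "ceil") ceiling(frame_size / n) else frame_size %/% n
    start <- sample.int(k, 1L)
    seq.int(start, frame_size, by = k)
  }
}

#' Fixed-take systematic PPS sampling
#'
#' Systematic selection with probability proportional to size on the
#' cumulative size scale: the interval is `sum(sizes) / n`, a single uniform
#' start on `(0, k]` generates `n` equally spaced selection points, and each
#' point is mapped to the unit whose cumulative size interval contains it.
#' Because no unit's size exceeds the interval (enforced via the
#' no-certainty-unit precondition), exactly `n` distinct units are selected,
#' and unit `i`'s inclusion probability is `n * sizes[i] / sum(sizes)`.
#'
#' @param sizes Positive size measures, one per frame unit, in frame order.
#' @param n Number of units to select.
#' @return A list with `positions` (ordered integer vector of length `n`) and
#'   `pi` (inclusion probabilities of all frame units).
#' @export
#' @examples
#' set.seed(1)
#' systematic_pps(c(1, 2, 3, 4), 2)
systematic_pps <- function(sizes, n) {
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (any(sizes <= 0)) stop("all sizes must be positive", call. = FALSE)
  total <- sum(sizes)
  pi <- n * sizes / total
  if (any(pi > 1 + 1e-12)) {
    stop("certainty units present (inclusion probability > 1); ",
         "lower n or remove take-all units", call. = FALSE)
  }
  k <- total / n
  u <- k * stats::runif(1)                       # (0, k]
  points <- u + (seq_len(n) - 1) * k
  # unit i occupies the half-open interval (cum[i-1], cum[i]]
  positions <- findInterval(points, cumsum(sizes), left.open = TRUE) + 1L
  positions[positions > length(sizes)] <- length(sizes)
  list(positions = positions, pi = pmin(pi, 1))
}

#' Simple random sampling without replacement
#'
#' Every subset of size `m` is equiprobable; per-unit inclusion probability is
#' `m / frame_size`.
#'
#' @param frame_size Number of units in the frame.
#' @param m Sample size, `1 <= m <= frame_size`.
#' @return Integer vector of `m` distinct positions.
#' @export
srswor <- function(frame_size, m) {
  if (length(m) != 1L || m < 1 || m != round(m)) {
    stop("'m' must be a positive integer", call. = FALSE)
  }
  if (m > frame_size) {
    stop(sprintf("sample size %d exceeds frame size %d", m, frame_size),
         call. = FALSE)
  }
  sample.int(frame_size, m)
}

#' Second-stage household take per cluster
#'
#' Number of households drawn from a cluster of `n_households` under exact
#' rational fraction `f_num / f_den`. Default rule is the ceiling
#' `ceiling(f * N)` computed in integer arithmetic (no floating point), so
#' e.g. a third of 3 households is exactly 1; `"nearest"` rounds half up.
#' The result is clamped to `[1, n_households]`.
#'
#' @param n_households Households in the cluster.
#' @param f_num,f_den Integer numerator and denominator of the fraction.
#' @param rounding `"ceil"` (default) or `"nearest"`.
#' @return A positive integer.
#' @export
#' @examples
#' second_stage_count(50, 1, 4)   # a quarter of 50 -> 13
second_stage_count <- function(n_households, f_num, f_den,
                               rounding = c("ceil", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(all(n_households >= 1))
  num <- as.double(f_num) * as.double(n_households)
  m <- if (rounding == "ceil") {
    (num + f_den - 1) %/% f_den
  } else {
    (2 * num + f_den) %/% (2 * f_den)
  }
  as.integer(pmin(pmax(m, 1), n_households))
}

#' Draw one sample under a design
#'
#' Dispatches to the conventional stratified cluster design (M1) or the
#' two-stage PPS design (M2). Randomness comes from the current RNG state;
#' callers control reproducibility via `set.seed()` or the stream tooling used
#' by [run_replications()].
#'
#' @param pop An object of class `svy_population`.
#' @param design An object of class `svy_design`.
#' @return An object of class `svy_sample`; see Details.
#'
#' @details
#' For M1 the draw holds, per stratum, the selected cluster rows and the
#' constant individual weight (stratum individuals / sampled individuals), so
#' the sum of weights over sampled individuals reproduces the stratum
#' population count exactly. For M2 the draw holds selected cluster rows with
#' their inclusion probabilities, the per-cluster second-stage take `m`, the
#' selected household rows of the population household table, and the
#' household weight `N_hi / (pi * m)` (inverse of cluster inclusion
#' probability times realized household fraction).
#' @export
draw_sample <- function(pop, design) {
  stopifnot(inherits(pop, "svy_population"), inherits(design, "svy_design"))
  if (design$method == "M1") draw_method1(pop, design) else draw_method2(pop, design)
}

#' @rdname draw_sample
#' @export
draw_method1 <- function(pop, design) {
  stopifnot(inherits(pop, "svy_population"), design$method == "M1")
  npm <- design$clusters_per_stratum
  if (npm > min(pop$strata$n_clusters)) {
    stop(sprintf("clusters_per_stratum = %d exceeds the smallest stratum (%d clusters)",
                 npm, min(pop$strata$n_clusters)), call. = FALSE)
  }
  H <- pop$n_strata
  # cluster rows are sorted by (stratum, cluster); stratum blocks are contiguous
  first_row <- cumsum(c(0L, pop$strata$n_clusters[-H])) + 1L
  rows_list <- vector("list", H)
  weight <- numeric(H)
  n_ind <- numeric(H)
  for (h in seq_len(H)) {
    pos <- systematic_sample(pop$strata$n_clusters[h], npm, design$interval_rule)
    rows <- first_row[h] - 1L + pos
    rows_list[[h]] <- rows
    n_ind[h] <- sum(pop$clusters$n_individuals[rows])
    weight[h] <- pop$strata$n_individuals[h] / n_ind[h]
  }
  structure(list(
    method = "M1",
    design = design,
    cluster_rows = rows_list,              # per stratum
    stratum_weight = weight,               # individual-level, constant in stratum
    n_sampled_individuals = n_ind
  ), class = "svy_sample")
}

#' @rdname draw_sample
#' @export
draw_method2 <- function(pop, design) {
  stopifnot(inherits(pop, "svy_population"), design$method == "M2")
  sizes <- pop$clusters$n_households
  n <- design$n_clusters
  if (n > length(sizes)) {
    stop("n_clusters exceeds the number of clusters in the frame", call. = FALSE)
  }
  ps <- systematic_pps(sizes, n)
  rows <- ps$positions
  pi_sel <- ps$pi[rows]
  N_hi <- sizes[rows]
  m <- second_stage_count(N_hi, design$f_num, design$f_den, design$rounding)
  census <- design$f_num == design$f_den
  hh_sel <- vector("list", n)
  start <- pop$clusters$hh_start[rows]
  for (i in seq_len(n)) {
    loc <- if (census || m[i] == N_hi[i]) seq_len(N_hi[i]) else srswor(N_hi[i], m[i])
    hh_sel[[i]] <- start[i] - 1L + loc
  }
  weight <- N_hi / (pi_sel * m)            # 1 / (pi * m/N_hi)
  structure(list(
    method = "M2",
    design = design,
    cluster_rows = rows,
    pi = pi_sel,
    m = m,
    hh_rows = unlist(hh_sel, use.names = FALSE),
    hh_cluster = rep.int(seq_len(n), m),   # index into cluster_rows per household
    cluster_weight = weight                # household-level, constant in cluster
  ), class = "svy_sample")
}

#' @export
print.svy_sample <- function(x, ...) {
  if (x$method == "M1") {
    cat(sprintf("Sample draw (M1): %d clusters, %.0f individuals\n",
                sum(lengths(x$cluster_rows)), sum(x$n_sampled_individuals)))
  } else {
    cat(sprintf("Sample draw (M2): %d clusters, %d households\n",
                length(x$cluster_rows), length(x$hh_rows)))
  }
  invisible(x)
}
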