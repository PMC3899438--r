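#' Miniature populations for tests and examples
#'
#' Hand-auditable finite populations used by the test suite and documentation:
#' \describe{
#'   \item{`toy3cluster`}{One stratum, 3 clusters of 2/3/5 households with
#'     small fixed integer X values; every estimate can be checked by hand.}
#'   \item{`single_stratum_equal`}{One stratum with 401 equal-sized clusters
#'     (5 households of 2 members each), cluster means i.i.d. Gaussian; equal
#'     cluster sizes make the design self-weighting under M1, enabling the
#'     closed-form one-per-stage cluster-sampling variance oracle
#'     `(1 - n/N) * S_b^2 / n`.}
#'   \item{`two_strata`}{Two unequal strata (8 and 30 clusters) with different
#'     means; exercises domain estimation under the two-stage design.}
#' }
#' All fixtures are deterministic: random ones use fixed internal streams.
#'
#' @param kind One of `"toy3cluster"`, `"single_stratum_equal"`, `"two_strata"`.
#' @return An object of class `svy_population`.
#' @export
#' @examples
#' summarize_population(make_fixture("toy3cluster"))
make_fixture <- function(kind = c("toy3cluster", "single_stratum_equal",
                                  "two_strata")) {
  kind <- match.arg(kind)
  switch(kind,
    toy3cluster = {
      # clusters of 2/3/5 households; household sizes 1-3; X on a readable grid
      n_members <- c(1L, 2L,             # cluster 1
                     2L, 1L, 3L,         # cluster 2
                     1L, 1L, 2L, 2L, 1L) # cluster 3
      x <- c(120,  130, 150,
             125, 145,  160,  110, 130, 120,
             150,  100,  135, 142,  138, 141,  129)
      population_from_raw(
        cluster_stratum = c(1L, 1L, 1L),
        cluster_n_households = c(2L, 3L, 5L),
        n_members = n_members,
        x = x,
        threshold = 140
      )
    },
    single_stratum_equal = {
      N <- 401L; M <- 5L; members <- 2L
      with_rng(rng_streams(760001L, 1L)[[1L]], {
        mu_cl <- stats::rnorm(N, 130, 5)
        x <- stats::rnorm(N * M * members,
                          rep(mu_cl, each = M * members), 8)
      })
      population_from_raw(
        cluster_stratum = rep.int(1L, N),
        cluster_n_households = rep.int(M, N),
        n_members = rep.int(members, N * M),
        x = x,
        threshold = 140
      )
    },
    two_strata = {
      nc <- c(8L, 30L)
      with_rng(rng_streams(760002L, 1L)[[1L]], {
        n_hh <- pmax(1L, as.integer(round(stats::rnorm(sum(nc), 6, 1.5))))
        n_members <- as.integer(sample.int(3L, sum(n_hh), replace = TRUE))
        mu_cl <- stats::rnorm(sum(nc), rep(c(125, 135), nc), 4)
        x <- stats::rnorm(sum(n_members),
                          rep(rep(mu_cl, n_hh), n_members), 9)
      })
      population_from_raw(
        cluster_stratum = rep(1:2, nc),
        cluster_n_households = n_hh,
        n_members = n_members,
        x = x,
        threshold = 140
      )
    }
  )
}
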