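#' Derive independent RNG streams from a root seed
#'
#' Creates `n` L'Ecuyer-CMRG random-number streams from a single integer seed
#' using [parallel::nextRNGStream()]. Streams are statistically independent,
#' so replicated sampling can assign one stream per replicate and any
#' execution order yields identical results.
#'
#' @param seed Integer root seed.
#' @param n Number of streams.
#' @return A list of `n` `.Random.seed` states.
#' @keywords internal
rng_streams <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(n) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  if (is.null(old)) {
    RNGkind("default")
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  streams
}

#' Evaluate an expression under a given RNG state
#'
#' Swaps in the supplied `.Random.seed` state, evaluates `expr`, and restores
#' the caller's RNG state afterwards, so library internals never perturb user
#' random-number sequences.
#'
#' @param stream A `.Random.seed` state, e.g. one element of [rng_streams()].
#' @param expr Expression to evaluate.
#' @keywords internal
with_rng <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream, envir = globalenv())
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Deterministically derive a child seed from a root seed and an index
#'
#' Small integer hash (splitmix-style multiply/xor folded into 31 bits) used to
#' give each scenario its own root seed; replicates within a scenario then use
#' [rng_streams()] substreams of that seed.
#'
#' @param seed Integer root seed.
#' @param index Nonnegative integer tag (scenario position).
#' @return An integer in `[1, 2^31 - 1]`.
#' @keywords internal
derive_seed <- function(seed, index) {
  x <- (as.double(seed) %% 2147483647) + 1
  k <- as.double(index) + 1
  # two rounds of multiply-mod mixing; constants are Park-Miller / Knuth
  x <- (x * 48271 + k * 2654435761) %% 2147483647
  x <- (x * 69621 + 7) %% 2147483647
  as.integer(x + 1)
}
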