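#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N population, K successes, n draws).
#'
#' @param k observed successes in the draw.
#' @param K successes in the population.
#' @param n draws.
#' @param N population size.
#' @return Probability in \[0, 1\].
#' @export
hyper_upper_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Empirical FDR from a permutation null
#'
#' The add-one estimator `(1 + #\{null >= observed\}) / (1 + n)`, which never
#' returns an exact zero.
#'
#' @param observed observed statistic.
#' @param null vector of permutation statistics.
#' @return Estimated tail probability in (0, 1].
#' @export
empirical_fdr <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
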