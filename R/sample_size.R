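# Multinomial sample-size criterion.
#
# Given the analytic density p over joint events, choose the smallest sample
# size N such that P(max_i |N p_i - x_i| > delta) < eps, where x is the
# multinomial count vector of an N-sample.  The exceedance probability is
# estimated either by Monte-Carlo multinomial replicates or by a conservative
# union bound of per-event binomial tails.

max_dev_prob <- function(N, p, delta, method, reps) {
  if (method == "monte-carlo") {
    x <- stats::rmultinom(reps, N, p)
    mean(apply(abs(x - N * p), 2L, max) > delta)
  } else {
    lo <- stats::pbinom(ceiling(N * p - delta) - 1, N, p)
    hi <- 1 - stats::pbinom(floor(N * p + delta), N, p)
    min(1, sum(lo + hi))
  }
}

#' Smallest sample size meeting a maximum-deviation accuracy constraint
#'
#' Searches N on a doubling-then-bisection grid for the smallest value whose
#' estimated probability of any event count deviating from its expectation
#' N p_i by more than `delta` stays below `eps`.  With `relative = TRUE`,
#' `delta` is interpreted as a fraction of N (the deviation threshold grows
#' with the sample).
#'
#' @param p probability vector over joint events (normalized).
#' @param delta maximum tolerated count deviation (> 0); a count if
#'   `relative = FALSE`, a fraction of N otherwise.
#' @param eps tail probability bound in (0, 1).
#' @param method "monte-carlo" (default; `reps` multinomial replicates per
#'   probe) or "union-bound" (conservative analytic bound).
#' @param reps Monte-Carlo replicates per probed N.
#' @param n_max search cap; exceeding it raises a bound-not-attained error.
#' @param relative interpret `delta` as a fraction of N.
#' @param seed optional integer seed (Monte-Carlo method).
#' @return The smallest admissible N found on the search grid.
#' @export
required_sample_size <- function(p, delta, eps,
                                 method = c("monte-carlo", "union-bound"),
                                 reps = 400L, n_max = 2^26, relative = FALSE,
                                 seed = NULL) {
  method <- match.arg(method)
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    bn_stop("invalid_argument", "`p` must be a normalized probability vector")
  if (delta <= 0) bn_stop("invalid_argument", "`delta` must be positive")
  if (eps <= 0 || eps >= 1)
    bn_stop("invalid_argument", "`eps` must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  dev <- function(N) if (relative) delta * N else delta
  ok <- function(N) max_dev_prob(N, p, dev(N), method, reps) < eps
  N <- 1L
  if (ok(N)) return(N)
  repeat {                              # doubling phase
    lo <- N
    N <- N * 2L
    if (N > n_max)
      bn_stop("bound_not_attained",
              "constraint not met within the search cap N = %d", n_max)
    if (ok(N)) break
  }
  hi <- N
  while (hi - lo > 1L) {                # bisection phase
    mid <- lo + (hi - lo) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}
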