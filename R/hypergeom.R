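#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing at least `k` successes in `n` draws made
#' without replacement from a population of `N` items of which `K` are
#' successes:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.}
#'
#' This is the statistic used to score a gene's connectivity to a seed set:
#' a gene with `n` network neighbours of which `k` fall inside a seed set of
#' size `K`, drawn from a universe of `N` genes, is scored by how surprising
#' `k` is under random draws.
#'
#' The sum is evaluated in log space from log-gamma binomial coefficients, so
#' tail probabilities far below `1e-300` are computed accurately; request
#' `log.p = TRUE` to recover them without underflow.
#'
#' @param k Number of observed successes (non-negative integer, vectorised).
#' @param n Number of draws.
#' @param K Number of successes in the population.
#' @param N Population size.
#' @param log.p If `TRUE`, return the natural log of the tail probability.
#' @return Numeric vector of tail probabilities in `(0, 1]` (or their logs).
#'   Arguments are recycled to a common length.
#' @examples
#' hypergeometric_upper_tail(3, 5, 10, 100)
#' hypergeometric_upper_tail(40, 60, 56, 20000, log.p = TRUE) / log(10)
#' @export
hypergeometric_upper_tail <- function(k, n, K, N, log.p = FALSE) {
  len <- max(length(k), length(n), length(K), length(N))
  if (len == 0L) return(numeric(0))
  k <- rep_len(as.numeric(k), len)
  n <- rep_len(as.numeric(n), len)
  K <- rep_len(as.numeric(K), len)
  N <- rep_len(as.numeric(N), len)
  bad <- function(cond, ineq) {
    if (any(cond)) {
      i <- which(cond)[1L]
      abort_domain(sprintf(
        "hypergeometric bounds violated: %s (k=%g, n=%g, K=%g, N=%g).",
        ineq, k[i], n[i], K[i], N[i]))
    }
  }
  intish <- function(x) is.na(x) | x != floor(x)
  if (any(intish(c(k, n, K, N)))) abort_domain("k, n, K, N must be integers.")
  bad(N < 0, "N >= 0")
  bad(K < 0 | K > N, "0 <= K <= N")
  bad(n < 0 | n > N, "0 <= n <= N")
  bad(k < 0 | k > pmin(n, K), "0 <= k <= min(n, K)")

  logp <- vapply(seq_len(len), function(i) {
    hyper_tail_log(k[i], n[i], K[i], N[i])
  }, numeric(1))
  if (log.p) logp else exp(logp)
}

# log P(X >= k) for scalar arguments; bounds already validated.
hyper_tail_log <- function(k, n, K, N) {
  if (k <= 0) return(0)
  hi <- min(n, K)
  i <- k:hi
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lg)
  min(m + log(sum(exp(lg - m))), 0)
}

# log P(X >= k) for every k in 0..min(n,K) at once (reverse cumulative
# log-sum-exp over the PMF); used by the per-gene test loop.
hyper_tail_log_all <- function(n, K, N) {
  hi <- min(n, K)
  i <- 0:hi
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  out <- numeric(hi + 1L)
  acc <- -Inf
  for (j in rev(seq_along(lg))) {
    a <- max(acc, lg[j])
    acc <- a + log(exp(acc - a) + exp(lg[j] - a))
    out[j] <- acc
  }
  out[1L] <- 0
  pmin(out, 0)
}
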