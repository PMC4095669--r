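# Exact-integer oracle for the hypergeometric tail, independent of the
# package's log-space implementation.
#
# All integers involved for population sizes N <= 60 fit below C(60,30)
# ~ 1.2e17, which exceeds the 2^53 exact-integer range of a double, so each
# value is carried as an error-free double-double pair (hi, lo) with
# hi + lo equal to the exact integer (the pair carries ~106 bits, enough
# for every integer arising up to N = 100). Binomial coefficients come from the
# Pascal recurrence using error-free addition; PMF terms use error-free
# multiplication; tails are reverse cumulative sums. Only the final division
# by C(N, n) rounds, leaving relative error at machine precision.

dd_quick_two_sum <- function(a, b) {
  s <- a + b
  list(hi = s, lo = b - (s - a))
}

dd_two_sum <- function(a, b) {
  s <- a + b
  bb <- s - a
  list(hi = s, lo = (a - (s - bb)) + (b - bb))
}

dd_split <- function(a) {
  t <- 134217729 * a  # 2^27 + 1
  hi <- t - (t - a)
  list(hi = hi, lo = a - hi)
}

dd_two_prod <- function(a, b) {
  p <- a * b
  A <- dd_split(a)
  B <- dd_split(b)
  e <- ((A$hi * B$hi - p) + A$hi * B$lo + A$lo * B$hi) + A$lo * B$lo
  list(hi = p, lo = e)
}

dd_add <- function(x, y) {
  s <- dd_two_sum(x$hi, y$hi)
  dd_quick_two_sum(s$hi, s$lo + x$lo + y$lo)
}

dd_mul <- function(x, y) {
  p <- dd_two_prod(x$hi, y$hi)
  dd_quick_two_sum(p$hi, p$lo + x$hi * y$lo + x$lo * y$hi)
}

dd_value <- function(x) x$hi + x$lo

# binomial_table(nmax)[[n + 1]] is a dd vector pair for C(n, 0..n).
oracle_binomial_table <- function(nmax) {
  tab <- vector("list", nmax + 1L)
  tab[[1L]] <- list(hi = 1, lo = 0)
  for (n in seq_len(nmax)) {
    prev <- tab[[n]]
    left <- list(hi = c(0, prev$hi), lo = c(0, prev$lo))
    right <- list(hi = c(prev$hi, 0), lo = c(prev$lo, 0))
    tab[[n + 1L]] <- dd_add(left, right)
  }
  tab
}

.oracle_binom <- oracle_binomial_table(100L)

oracle_choose <- function(n, k) {
  row <- .oracle_binom[[n + 1L]]
  list(hi = row$hi[k + 1L], lo = row$lo[k + 1L])
}

# Exact tails P(X >= k) for every k in 0..min(n, K).
oracle_hyper_tails <- function(n, K, N) {
  stopifnot(N <= 100, K <= N, n <= N)
  hi <- min(n, K)
  lo_i <- max(0L, n - (N - K))
  terms <- lapply(0:hi, function(i) {
    if (i < lo_i) return(list(hi = 0, lo = 0))
    dd_mul(oracle_choose(K, i), oracle_choose(N - K, n - i))
  })
  acc <- list(hi = 0, lo = 0)
  tails <- vector("list", hi + 1L)
  for (i in rev(seq_len(hi + 1L))) {
    acc <- dd_add(acc, terms[[i]])
    tails[[i]] <- acc
  }
  denom <- dd_value(oracle_choose(N, n))
  vapply(tails, dd_value, numeric(1)) / denom
}

oracle_hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  oracle_hyper_tails(n, K, N)[k + 1L]
}
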