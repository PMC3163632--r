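# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the code paths they check: p-values come from direct
# pmf summation, regions from scanning those p-values, and the signed-rank
# null distribution from explicit enumeration of sign assignments.

bf_two_sided_p <- function(k, n, p0) {
  pmf <- dbinom(0:n, n, p0)
  lower <- sum(pmf[seq_len(k + 1)])
  upper <- sum(pmf[(k + 1):(n + 1)])
  min(1, 2 * min(lower, upper))
}

bf_region <- function(n, p0, alpha) {
  pv <- vapply(0:n, bf_two_sided_p, numeric(1), n = n, p0 = p0)
  ks <- 0:n
  lo <- ks[pv <= alpha & ks < n * p0]
  hi <- ks[pv <= alpha & ks > n * p0]
  list(k_low = if (length(lo)) max(lo) else NA_integer_,
       k_high = if (length(hi)) min(hi) else NA_integer_)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# on the mid-ranks of |d| (zeros must already be removed).
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

make_record <- function(increments, id = "S1", type = "core_biopsy", round = 1L) {
  counting_record(id, type, round, increments)
}

# Record with a prescribed number of positives in a prefix window and in
# the remainder, spread as evenly as integer 10-cell increments allow.
spread_counts <- function(total, n_increments) {
  base <- total %/% n_increments
  extra <- total %% n_increments
  inc <- rep(base, n_increments)
  if (extra > 0) inc[seq_len(extra)] <- inc[seq_len(extra)] + 1L
  stopifnot(all(inc <= 10), sum(inc) == total)
  as.integer(inc)
}
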