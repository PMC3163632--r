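#' Exact two-sided binomial p-value
#'
#' Exact two-sided p-value for observing `k` successes in `n` Bernoulli
#' trials under H0: success probability `p0`. The default convention is the
#' central (doubled smaller tail) definition
#' `min(1, 2 * min(P[X <= k], P[X >= k]))`, which has monotone tails and is
#' the convention used throughout the sequential classifier. The
#' minimum-likelihood convention (sum of all outcomes no more probable than
#' `k`, as in [stats::binom.test()]) is available for comparison, since
#' published rejection boundaries computed under it can differ by one count
#' at a few sample sizes.
#'
#' @param k Observed success count(s); vectorized, each in `0..n`.
#' @param n Number of trials (scalar).
#' @param p0 Null success probability, strictly between 0 and 1.
#' @param convention `"central"` (default) or `"minlik"`.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' exact_binom_two_sided_p(2, 12, 0.5)   # 0.039: the exact McNemar kernel
#' exact_binom_two_sided_p(20, 100, 0.2) # 1: observed fraction equals p0
#' @export
exact_binom_two_sided_p <- function(k, n, p0, convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("'n' must be a single positive integer", call. = FALSE)
  }
  if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1) {
    stop("'p0' must lie strictly between 0 and 1", call. = FALSE)
  }
  if (anyNA(k) || any(k != floor(k)) || any(k < 0) || any(k > n)) {
    stop("'k' must be whole numbers in [0, n]", call. = FALSE)
  }
  if (convention == "central") {
    lower <- stats::pbinom(k, n, p0)
    upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
  } else {
    pmf <- stats::dbinom(0:n, n, p0)
    # relative tolerance as in binom.test to absorb floating-point ties
    vapply(k, function(ki) {
      sum(pmf[pmf <= pmf[ki + 1L] * (1 + 1e-7)])
    }, numeric(1))
  }
}

#' Rejection region of the exact binomial test
#'
#' For a single test of H0: p = `p0` at `n` counted cells, finds the count
#' bounds `k_low` (largest count below `n * p0` with p-value `<= alpha`) and
#' `k_high` (smallest count above `n * p0` with p-value `<= alpha`). A count
#' `k <= k_low` or `k >= k_high` rejects the null. Either bound can be
#' absent (`NA`) when no count on that side reaches significance, which
#' happens routinely for the lower tail at small `n`. The scan over all
#' `k = 0..n` is exact.
#'
#' @inheritParams exact_binom_two_sided_p
#' @param alpha Per-test significance level, in (0, 1).
#' @return A list with integer components `k_low` and `k_high` (`NA` when
#'   absent).
#' @examples
#' rejection_region(100, 0.2, 0.012)
#' rejection_region(10, 0.2, 0.012)  # no lower bound exists
#' @export
rejection_region <- function(n, p0 = 0.2, alpha = 0.012,
                             convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  k <- 0:n
  p <- exact_binom_two_sided_p(k, n, p0, convention)
  sig <- p <= alpha
  lo <- k[sig & k < n * p0]
  hi <- k[sig & k > n * p0]
  list(k_low = if (length(lo)) max(lo) else NA_integer_,
       k_high = if (length(hi)) min(hi) else NA_integer_)
}

#' Build the sequential rejection table
#'
#' Tabulates the exact binomial rejection bounds at every cell count of the
#' sequential testing grid (by default 100, 110, ..., 400 cells against
#' H0: 20% positivity at per-test level 0.012). The bounds are stored as
#' integer counts -- the primitive the cumulative test actually sees -- with
#' the fraction bounds `k / n` derived alongside. In fraction terms the
#' non-rejection band straddles `p0` at every `n` and narrows as `n` grows,
#' so the table is the tabular form of the classifier's funnel-shaped
#' acceptance region.
#'
#' @inheritParams rejection_region
#' @param n_start First tested cell count (default 100).
#' @param n_max Last tested cell count (default 400).
#' @param step Grid step in cells (default 10, one increment).
#' @return A data frame of class `"rejection_table"` with columns `n`,
#'   `k_low`, `k_high`, `frac_low`, `frac_high` and attributes `p0`,
#'   `alpha`, `convention` and `conf_level` (the `100 * (1 - alpha)` percent
#'   confidence level; 98.8 under the defaults).
#' @examples
#' tab <- build_rejection_table()
#' head(tab)
#' @export
build_rejection_table <- function(p0 = 0.2, alpha = 0.012, n_start = 100,
                                  n_max = 400, step = 10,
                                  convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  if (length(step) != 1L || step < 1 || step != floor(step)) {
    stop("'step' must be a positive integer", call. = FALSE)
  }
  if (n_start < step || n_max < n_start || (n_max - n_start) %% step != 0) {
    stop("invalid grid: need n_start >= step, n_max >= n_start, ",
         "and step dividing n_max - n_start", call. = FALSE)
  }
  grid <- as.integer(seq(n_start, n_max, by = step))
  bounds <- lapply(grid, rejection_region, p0 = p0, alpha = alpha,
                   convention = convention)
  k_low <- vapply(bounds, `[[`, integer(1), "k_low")
  k_high <- vapply(bounds, `[[`, integer(1), "k_high")
  tab <- data.frame(n = grid, k_low = k_low, k_high = k_high,
                    frac_low = k_low / grid, frac_high = k_high / grid)
  structure(tab, p0 = p0, alpha = alpha, convention = convention,
            conf_level = 100 * (1 - alpha),
            class = c("rejection_table", "data.frame"))
}

#' @export
print.rejection_table <- function(x, ...) {
  cat(sprintf(
    "Sequential rejection table: H0 p = %g, per-test alpha = %g (%s), %g%% CI\n",
    attr(x, "p0"), attr(x, "alpha"), attr(x, "convention"), attr(x, "conf_level")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Plot the non-rejection band of a rejection table
#'
#' Shades, in fraction terms, the region of observed positive fractions for
#' which the null proportion cannot be rejected at each tested cell count.
#'
#' @param x A [build_rejection_table()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rejection_table <- function(x, ...) {
  p0 <- attr(x, "p0")
  lo <- ifelse(is.na(x$frac_low), 0, x$frac_low)
  hi <- ifelse(is.na(x$frac_high), 1, x$frac_high)
  graphics::plot(range(x$n), range(c(lo, hi, p0)), type = "n",
                 xlab = "cells evaluated", ylab = "Ki67-positive fraction", ...)
  graphics::polygon(c(x$n, rev(x$n)), c(lo, rev(hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$n, lo, type = "s")
  graphics::lines(x$n, hi, type = "s")
  graphics::abline(h = p0, lty = 2)
  invisible(x)
}

#' Classify a sample by the sequential counting rule
#'
#' Walks the cumulative positive count along the testing grid. At the first
#' grid point where the count falls in the rejection region the sample is
#' classified `"high"` (count above `n * p0`) or `"low"` (count below) and
#' counting stops. If no grid point through `n_max` rejects, the sample is
#' `"unclassifiable"` -- the procedure has no early acceptance stop, by
#' design, so only rejection or exhaustion of the 400-cell budget terminate
#' it. Records that end before `n_max` are classified as far as their data
#' allow; if no tested grid point rejects, the result is unclassifiable at
#' the last tested grid point and flagged incomplete. A trailing partial
#' increment is never tested.
#'
#' @param record A [counting_record()] with at least `n_start / 10`
#'   increments.
#' @param table A [build_rejection_table()] result.
#' @return An object of class `"sequential_decision"`: a list with `status`
#'   (`"high"`, `"low"` or `"unclassifiable"`), `stop_n` (cells evaluated at
#'   the decision), `fraction_at_stop`, `complete` (`FALSE` when the record
#'   ended before `n_max` without rejection), and `sample_id`.
#' @examples
#' tab <- build_rejection_table()
#' hot <- counting_record("S-hot", "core_biopsy", 1, rep(10L, 40))
#' sequential_classify(hot, tab)
#' @export
sequential_classify <- function(record, table = build_rejection_table()) {
  stopifnot(inherits(record, "counting_record"), inherits(table, "rejection_table"))
  if (any(table$n %% 10 != 0)) {
    stop("rejection-table grid must align with 10-cell increments", call. = FALSE)
  }
  avail <- total_cells(record)
  if (avail < min(table$n)) {
    stop(sprintf("record '%s' has %d cells; at least %d are needed before testing",
                 record$sample_id, avail, min(table$n)), call. = FALSE)
  }
  cum <- cumulative_positives(record)
  testable <- which(table$n <= avail)
  p0 <- attr(table, "p0")
  for (i in testable) {
    n <- table$n[i]
    count <- cum[n / 10L]
    k_low <- table$k_low[i]
    k_high <- table$k_high[i]
    if (!is.na(k_low) && count <= k_low) {
      return(new_sequential_decision("low", n, count / n, TRUE, record$sample_id, p0))
    }
    if (!is.na(k_high) && count >= k_high) {
      return(new_sequential_decision("high", n, count / n, TRUE, record$sample_id, p0))
    }
  }
  last_n <- table$n[max(testable)]
  new_sequential_decision("unclassifiable", last_n, cum[last_n / 10L] / last_n,
                          complete = last_n == max(table$n), record$sample_id, p0)
}

new_sequential_decision <- function(status, stop_n, fraction, complete, sample_id, p0) {
  structure(list(status = status, stop_n = as.integer(stop_n),
                 fraction_at_stop = fraction, complete = complete,
                 sample_id = sample_id, p0 = p0),
            class = "sequential_decision")
}

#' @export
print.sequential_decision <- function(x, ...) {
  cat(sprintf("<sequential_decision> %s: %s at %d cells (observed %.1f%%)%s\n",
              x$sample_id, x$status, x$stop_n, 100 * x$fraction_at_stop,
              if (!x$complete) " [record ended before the full grid]" else ""))
  invisible(x)
}

#' Classify a batch of counting records
#'
#' Applies [sequential_classify()] to each record and collects the
#' decisions into a data frame, one row per record.
#'
#' @param records List of [counting_record()] objects.
#' @inheritParams sequential_classify
#' @return A data frame with columns `sample_id`, `sample_type`, `round`,
#'   `status`, `stop_n`, `fraction_at_stop`, `complete`.
#' @export
classify_records <- function(records, table = build_rejection_table()) {
  stopifnot(is.list(records))
  if (length(records) == 0L) {
    return(data.frame(sample_id = character(), sample_type = character(),
                      round = integer(), status = character(), stop_n = integer(),
                      fraction_at_stop = numeric(), complete = logical()))
  }
  rows <- lapply(records, function(r) {
    d <- sequential_classify(r, table)
    data.frame(sample_id = r$sample_id, sample_type = r$sample_type,
               round = r$round, status = d$status, stop_n = d$stop_n,
               fraction_at_stop = d$fraction_at_stop, complete = d$complete,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
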