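#' Exact achieved size of a single binomial test
#'
#' Probability, under H0, that a single exact two-sided binomial test at
#' `n` cells rejects at level `alpha`: the binomial tail mass over the
#' rejection region. Used as the analytic cross-check for the Monte-Carlo
#' machinery on a one-point grid.
#'
#' @inheritParams rejection_region
#' @return The achieved size (a probability, usually well below `alpha`
#'   because of discreteness).
#' @export
achieved_size <- function(n, p0 = 0.2, alpha = 0.012,
                          convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  b <- rejection_region(n, p0, alpha, convention)
  lo <- if (is.na(b$k_low)) 0 else stats::pbinom(b$k_low, n, p0)
  hi <- if (is.na(b$k_high)) 0 else stats::pbinom(b$k_high - 1, n, p0, lower.tail = FALSE)
  lo + hi
}

# Smallest p-value attained across the grid, one value per simulated
# replicate of homogeneous Bernoulli(p0) counting. The per-replicate minimum
# p-value is the sufficient statistic for the whole calibration curve:
# the procedure rejects at level alpha iff min_p <= alpha.
simulate_min_p <- function(p0, n_grid, replicates, seed,
                           convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  n_grid <- sort(unique(as.integer(n_grid)))
  if (length(n_grid) == 0L || any(n_grid < 1L)) {
    stop("'n_grid' must contain at least one positive cell count", call. = FALSE)
  }
  if (replicates < 1) stop("'replicates' must be >= 1", call. = FALSE)
  set.seed(seed)
  steps <- diff(c(0L, n_grid))
  acc <- integer(replicates)
  min_p <- rep(1, replicates)
  for (j in seq_along(n_grid)) {
    acc <- acc + stats::rbinom(replicates, steps[j], p0)
    pv <- exact_binom_two_sided_p(0:n_grid[j], n_grid[j], p0, convention)
    min_p <- pmin(min_p, pv[acc + 1L])
  }
  min_p
}

new_calibration_result <- function(alpha, estimate, replicates, seed, p0,
                                   n_grid, convention, target = NULL,
                                   curve = NULL, at_boundary = FALSE) {
  structure(
    list(alpha_per_test = alpha,
         overall_alpha_estimate = estimate,
         mc_se = sqrt(estimate * (1 - estimate) / replicates),
         replicates = as.integer(replicates), seed = as.integer(seed),
         p0 = p0, n_grid = n_grid, convention = convention,
         target_overall = target, curve = curve, at_boundary = at_boundary),
    class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "Sequential test calibration (p0 = %g, grid %d-%d, %s convention)\n",
    x$p0, min(x$n_grid), max(x$n_grid), x$convention))
  cat(sprintf("  per-test alpha: %g\n  overall type-I error: %.4f (MC SE %.4f, %d replicates, seed %d)\n",
              x$alpha_per_test, x$overall_alpha_estimate, x$mc_se,
              x$replicates, x$seed))
  if (!is.null(x$target_overall)) {
    cat(sprintf("  target overall level: %g%s\n", x$target_overall,
                if (x$at_boundary) " (no grid value met the target; smallest reported)" else ""))
  }
  invisible(x)
}

#' Monte-Carlo overall type-I error of the sequential procedure
#'
#' Simulates homogeneous counting under the null -- every cell an
#' independent Bernoulli(`p0`) draw -- and applies the sequential exact
#' binomial test at each grid cell count, estimating the probability that
#' the procedure rejects at any test. Because each test is carried out at
#' level `alpha` on overlapping cumulative counts, the overall level
#' exceeds any single test's achieved size but stays well below the
#' Bonferroni sum; simulation is the practical way to pin it down.
#'
#' @inheritParams rejection_region
#' @param n_grid Cell counts at which tests occur (default 100, 110, ...,
#'   400).
#' @param replicates Number of simulated counting runs (default 100000,
#'   giving a Monte-Carlo standard error near 0.0007 at an estimate of
#'   0.05).
#' @param seed RNG seed; identical seed and parameters reproduce the
#'   estimate exactly.
#' @return A `"calibration_result"`: per-test `alpha_per_test`, the
#'   `overall_alpha_estimate`, its Monte-Carlo standard error `mc_se`,
#'   `replicates` and `seed`.
#' @examples
#' simulate_overall_type1(replicates = 2000, seed = 7)
#' @export
simulate_overall_type1 <- function(p0 = 0.2, alpha = 0.012,
                                   n_grid = seq(100L, 400L, 10L),
                                   replicates = 1e5, seed = 1,
                                   convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  if (length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("'alpha' must lie in (0, 1]", call. = FALSE)
  }
  min_p <- simulate_min_p(p0, n_grid, replicates, seed, convention)
  est <- mean(min_p <= alpha)
  new_calibration_result(alpha, est, replicates, seed, p0,
                         sort(unique(as.integer(n_grid))), convention)
}

#' Calibrate the per-test level to a target overall level
#'
#' Searches a grid of nominal per-test levels for the largest one whose
#' simulated overall type-I error does not exceed `target_overall`
#' (conservative choice: the overall level is preserved at or below the
#' target). All grid points share one set of simulated counting runs
#' (common random numbers), so the estimated calibration curve is monotone
#' in `alpha` by construction and the selection is not blurred by
#' between-point Monte-Carlo noise.
#'
#' @inheritParams simulate_overall_type1
#' @param target_overall Desired overall significance level (default 0.05).
#' @param alpha_grid Ascending grid of candidate per-test levels (default
#'   0.001 to 0.050 in steps of 0.001).
#' @return A `"calibration_result"` whose `alpha_per_test` is the selected
#'   level; `curve` holds the full calibration curve as a data frame with
#'   columns `alpha`, `estimate`, `mc_se`. If no grid value meets the
#'   target the smallest is returned with `at_boundary = TRUE` and a
#'   warning.
#' @examples
#' calibrate_alpha(replicates = 2000, seed = 7)
#' @export
calibrate_alpha <- function(p0 = 0.2, target_overall = 0.05,
                            alpha_grid = seq(0.001, 0.050, by = 0.001),
                            n_grid = seq(100L, 400L, 10L),
                            replicates = 1e5, seed = 1,
                            convention = c("central", "minlik")) {
  convention <- match.arg(convention)
  if (is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("'alpha_grid' must be strictly ascending", call. = FALSE)
  }
  if (length(target_overall) != 1L || target_overall <= 0 || target_overall > 1) {
    stop("'target_overall' must lie in (0, 1]", call. = FALSE)
  }
  min_p <- simulate_min_p(p0, n_grid, replicates, seed, convention)
  est <- vapply(alpha_grid, function(a) mean(min_p <= a), numeric(1))
  curve <- data.frame(alpha = alpha_grid, estimate = est,
                      mc_se = sqrt(est * (1 - est) / replicates))
  ok <- est <= target_overall
  if (any(ok)) {
    i <- max(which(ok))
    at_boundary <- FALSE
  } else {
    i <- 1L
    at_boundary <- TRUE
    warning("no candidate level met the target overall level; ",
            "reporting the smallest grid value", call. = FALSE)
  }
  new_calibration_result(alpha_grid[i], est[i], replicates, seed, p0,
                         sort(unique(as.integer(n_grid))), convention,
                         target = target_overall, curve = curve,
                         at_boundary = at_boundary)
}
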