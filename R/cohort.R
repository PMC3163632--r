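#' Paired t-test on the linear (percentage-point) scale
#'
#' Paired comparison of core-biopsy and surgical Ki67 percentages via a
#' classical paired t-test on the differences biopsy minus surgical, so a
#' positive `mean_diff` means the biopsy reads higher.
#'
#' @param biopsy,surgical Numeric vectors of Ki67 percentages, matched by
#'   position (one tumor per position).
#' @return List with `mean_diff` (percentage points), `ci95` (length-2
#'   vector), `p` (two-sided), `df`, and `n`.
#' @export
paired_t_linear <- function(biopsy, surgical) {
  check_pairs(biopsy, surgical)
  d <- biopsy - surgical
  if (stats::sd(d) == 0) {
    stop("all pairwise differences identical; paired t-test is degenerate",
         call. = FALSE)
  }
  tt <- stats::t.test(d)
  list(mean_diff = unname(tt$estimate), ci95 = as.numeric(tt$conf.int),
       p = tt$p.value, df = unname(tt$parameter), n = length(d))
}

#' Paired t-test on the log (multiplicative) scale
#'
#' Tests the per-pair ratio surgical / biopsy via a paired t-test on log
#' values and reports the geometric-mean ratio with a back-transformed 95%
#' confidence interval. The multiplicative scale suits Ki67 data whose
#' spread grows with the mean, but ratios are unstable for very low
#' percentages and undefined at zero; `zero_policy` controls what happens
#' to pairs containing a zero (or negative) value:
#' `"exclude"` drops such pairs (the number dropped is reported and
#' messaged), `"error"` refuses, `"continuity"` adds half a positive cell
#' to every value (requires `n_cells` to convert 0.5 cells into percent).
#'
#' When every ratio is identical the point estimate is still reported, with
#' `degenerate = TRUE` and `NA` inference, since no variance is available
#' to test against.
#'
#' @inheritParams paired_t_linear
#' @param zero_policy `"exclude"` (default), `"error"`, or `"continuity"`.
#' @param n_cells Cells per evaluation; required for
#'   `zero_policy = "continuity"`.
#' @return List with `gm_ratio`, `ci95`, `p`, `n`, `n_excluded`,
#'   `degenerate`.
#' @export
paired_t_log <- function(biopsy, surgical,
                         zero_policy = c("exclude", "error", "continuity"),
                         n_cells = NULL) {
  zero_policy <- match.arg(zero_policy)
  check_pairs(biopsy, surgical)
  z <- apply_zero_policy(biopsy, surgical, zero_policy, n_cells)
  lr <- log(z$surgical / z$biopsy)
  if (length(lr) < 2L) {
    stop("fewer than 2 usable pairs on the log scale", call. = FALSE)
  }
  if (stats::sd(lr) <= 1e-10) {
    warning("all ratios identical; reporting the point estimate without inference",
            call. = FALSE)
    return(list(gm_ratio = exp(mean(lr)), ci95 = c(NA_real_, NA_real_),
                p = NA_real_, n = length(lr), n_excluded = z$n_excluded,
                degenerate = TRUE))
  }
  tt <- stats::t.test(lr)
  list(gm_ratio = exp(unname(tt$estimate)), ci95 = exp(as.numeric(tt$conf.int)),
       p = tt$p.value, n = length(lr), n_excluded = z$n_excluded,
       degenerate = FALSE)
}

check_pairs <- function(biopsy, surgical) {
  if (length(biopsy) != length(surgical)) {
    stop("'biopsy' and 'surgical' must have equal length", call. = FALSE)
  }
  if (length(biopsy) < 2L) stop("at least 2 pairs are required", call. = FALSE)
  if (anyNA(biopsy) || anyNA(surgical)) {
    stop("missing values in paired percentages", call. = FALSE)
  }
  invisible(TRUE)
}

apply_zero_policy <- function(biopsy, surgical, zero_policy, n_cells) {
  bad <- biopsy <= 0 | surgical <= 0
  n_excluded <- 0L
  if (any(bad)) {
    if (zero_policy == "error") {
      stop(sum(bad), " pair(s) contain non-positive values; log scale undefined",
           call. = FALSE)
    }
    if (zero_policy == "continuity") {
      if (is.null(n_cells)) {
        stop("'n_cells' is required for the continuity zero policy", call. = FALSE)
      }
      add <- 100 * 0.5 / n_cells  # half a positive cell, in percent
      biopsy <- biopsy + add
      surgical <- surgical + add
    } else {
      n_excluded <- sum(bad)
      message(n_excluded, " pair(s) with non-positive values excluded from the log scale")
      biopsy <- biopsy[!bad]
      surgical <- surgical[!bad]
    }
  }
  list(biopsy = biopsy, surgical = surgical, n_excluded = n_excluded)
}

#' Wilcoxon matched-pairs signed-rank test
#'
#' Two-sided signed-rank test of symmetry of the paired differences about
#' zero. Zero differences are dropped (the classical convention); absolute
#' differences are mid-ranked, so ties are handled exactly. For up to
#' `exact_limit` nonzero differences the null distribution of the rank sum
#' is computed exactly by dynamic programming over the (doubled, hence
#' integer) mid-ranks and the p-value is the doubled smaller tail, capped
#' at 1. Beyond that a normal approximation with tie correction and
#' continuity correction is used.
#'
#' @inheritParams paired_t_linear
#' @param exact_limit Largest number of nonzero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(biopsy, surgical = NULL, exact_limit = 25L) {
  d <- if (is.null(surgical)) biopsy else {
    check_pairs(biopsy, surgical)
    biopsy - surgical
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    stop("all differences are zero; signed-rank test is degenerate", call. = FALSE)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of 2W over sign assignments; mid-ranks doubled to integers
    r2 <- as.integer(round(2 * r))
    dist <- signed_rank_distribution(r2)
    w2 <- as.integer(round(2 * w))
    lower <- sum(dist[seq_len(w2 + 1L)])
    upper <- sum(dist[(w2 + 1L):length(dist)])
    min(1, 2 * min(lower, upper))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    2 * stats::pnorm(-abs(z))
  }
}

# Exact null pmf of twice the positive-rank sum, indexed 0..sum(r2),
# by convolving one (1 + x^r)/2 factor per difference.
signed_rank_distribution <- function(r2) {
  total <- sum(r2)
  pmf <- numeric(total + 1L)
  pmf[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), pmf[seq_len(total + 1L - ri)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Dichotomize Ki67 percentages at a cut-off
#'
#' Labels each value `"high"` when strictly above the cut-off, `"low"`
#' otherwise. Values exactly at the cut-off therefore fall on the low side
#' -- conservative toward low proliferation -- and are flagged: their
#' positions are attached as the `"boundary"` attribute and reported via a
#' message.
#'
#' @param percent Numeric vector of Ki67 percentages (0--100).
#' @param cutoff Cut-off percentage, strictly between 0 and 100 (default
#'   20).
#' @return Factor with levels `low`, `high` and attribute `boundary`.
#' @export
dichotomize <- function(percent, cutoff = 20) {
  if (length(cutoff) != 1L || cutoff <= 0 || cutoff >= 100) {
    stop("'cutoff' must lie strictly between 0 and 100", call. = FALSE)
  }
  if (anyNA(percent) || any(percent < 0) || any(percent > 100)) {
    stop("'percent' values must lie in [0, 100]", call. = FALSE)
  }
  at_cut <- which(percent == cutoff)
  if (length(at_cut)) {
    message("value(s) exactly at the ", cutoff,
            "% cut-off classified as low: position(s) ",
            paste(at_cut, collapse = ", "))
  }
  out <- factor(ifelse(percent > cutoff, "high", "low"), levels = c("low", "high"))
  attr(out, "boundary") <- at_cut
  out
}

#' Exact McNemar test on discordant pair counts
#'
#' Tests whether the two kinds of discordant pairs (biopsy high / surgical
#' low versus the reverse) are equally likely: an exact central binomial
#' test of `min(b, c)` successes in `b + c` trials at probability one half.
#' Returns 1 when there is no discordance.
#'
#' @param b,c Discordant counts from the paired 2x2 table.
#' @return Two-sided exact p-value.
#' @examples
#' mcnemar_exact(10, 2)  # 0.039
#' mcnemar_exact(4, 4)   # 1
#' @export
mcnemar_exact <- function(b, c) {
  if (length(b) != 1L || length(c) != 1L || b < 0 || c < 0 ||
      b != floor(b) || c != floor(c)) {
    stop("'b' and 'c' must be single non-negative integers", call. = FALSE)
  }
  if (b + c == 0) return(1)
  exact_binom_two_sided_p(min(b, c), b + c, 0.5)
}

#' Concordance table of dichotomized pairs
#'
#' Cross-classifies biopsy status against surgical status at the cut-off.
#' The off-diagonal cells are the discordant counts that feed
#' [mcnemar_exact()].
#'
#' @inheritParams paired_t_linear
#' @param cutoff Dichotomization cut-off percentage (default 20).
#' @return A 2x2 table, biopsy status in rows, surgical status in columns.
#' @export
concordance_table <- function(biopsy, surgical, cutoff = 20) {
  check_pairs(biopsy, surgical)
  b_lab <- dichotomize(biopsy, cutoff)
  s_lab <- dichotomize(surgical, cutoff)
  table(biopsy = b_lab, surgical = s_lab)
}

#' Discordant counts of a concordance table
#'
#' @param tab A 2x2 table from [concordance_table()].
#' @return Named vector `c(b = biopsy-high/surgical-low, c =
#'   biopsy-low/surgical-high)`.
#' @export
discordant_counts <- function(tab) {
  stopifnot(is.table(tab) || is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  c(b = unname(tab["high", "low"]), c = unname(tab["low", "high"]))
}

#' Bland-Altman agreement analysis
#'
#' Agreement between the paired Ki67 readings on the chosen scale. On the
#' linear scale the per-pair difference biopsy minus surgical is related to
#' the pair mean; bias is the mean difference and the 95% reference limits
#' are bias +/- 1.96 SD of the differences. On the log scale the per-pair
#' ratio surgical / biopsy is related to the pair geometric mean and the
#' bias and limits are back-transformed onto the ratio scale. The linear
#' bias therefore equals the [paired_t_linear()] mean difference, and the
#' log bias equals the [paired_t_log()] geometric-mean ratio.
#'
#' @inheritParams paired_t_log
#' @param scale `"linear"` or `"log"`.
#' @return An object of class `"bland_altman"`: `scale`, `bias`, `lower`,
#'   `upper` (reference limits), and per-pair `means` and `values`
#'   (differences or ratios) for plotting.
#' @export
bland_altman <- function(biopsy, surgical, scale = c("linear", "log"),
                         zero_policy = c("exclude", "error", "continuity"),
                         n_cells = NULL) {
  scale <- match.arg(scale)
  zero_policy <- match.arg(zero_policy)
  check_pairs(biopsy, surgical)
  if (scale == "linear") {
    d <- biopsy - surgical
    s <- stats::sd(d)
    out <- list(scale = scale, bias = mean(d), lower = mean(d) - 1.96 * s,
                upper = mean(d) + 1.96 * s, means = (biopsy + surgical) / 2,
                values = d)
  } else {
    z <- apply_zero_policy(biopsy, surgical, zero_policy, n_cells)
    lr <- log(z$surgical / z$biopsy)
    s <- stats::sd(lr)
    out <- list(scale = scale, bias = exp(mean(lr)),
                lower = exp(mean(lr) - 1.96 * s),
                upper = exp(mean(lr) + 1.96 * s),
                means = sqrt(z$biopsy * z$surgical), values = exp(lr))
  }
  structure(out, class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  lab <- if (x$scale == "linear") "difference (biopsy - surgical, %)" else
    "ratio (surgical / biopsy)"
  cat(sprintf("Bland-Altman (%s scale): bias %.3g, 95%% reference limits [%.3g, %.3g], %s\n",
              x$scale, x$bias, x$lower, x$upper, lab))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  ylab <- if (x$scale == "linear") "difference (biopsy - surgical, %)" else
    "ratio (surgical / biopsy)"
  xlab <- if (x$scale == "linear") "pair mean (%)" else "pair geometric mean (%)"
  graphics::plot(x$means, x$values, xlab = xlab, ylab = ylab,
                 log = if (x$scale == "log") "y" else "", ...)
  graphics::abline(h = x$bias, lty = 2)
  graphics::abline(h = c(x$lower, x$upper))
  invisible(x)
}

#' Dilution contrast: hotspot window versus the remainder
#'
#' Compares, within each fully counted sample, the Ki67 fraction over the
#' first `split_cells` cells (the hotspot-first window) with the fraction
#' over the remaining cells, and tests the mean within-sample difference
#' with a paired t-test. A positive mean difference is the signature of the
#' dilution effect: proliferation read in the hotspot exceeds what the rest
#' of the sheet adds. Records shorter than 1000 cells are excluded with a
#' message.
#'
#' @param records List of [counting_record()] objects (1000-cell sheets).
#' @param split_cells Where to split, a multiple of 10 strictly inside
#'   (0, 1000); default 200.
#' @return List with `mean_first`, `mean_last`, `mean_diff` (all percent),
#'   `p` (paired t; `NA` with fewer than 2 usable records or zero
#'   variance), `n_used`, `n_excluded`.
#' @export
dilution_contrast <- function(records, split_cells = 200) {
  stopifnot(is.list(records))
  if (split_cells %% 10 != 0 || split_cells <= 0 || split_cells >= 1000) {
    stop("'split_cells' must be a multiple of 10 strictly inside (0, 1000)",
         call. = FALSE)
  }
  full <- vapply(records, function(r) total_cells(r) == 1000L, logical(1))
  if (any(!full)) {
    message(sum(!full), " record(s) shorter than 1000 cells excluded from the dilution contrast")
  }
  records <- records[full]
  if (length(records) == 0L) stop("no 1000-cell records available", call. = FALSE)
  m <- split_cells / 10
  first <- vapply(records, function(r) 100 * sum(r$increments[1:m]) / split_cells,
                  numeric(1))
  last <- vapply(records, function(r)
    100 * sum(r$increments[(m + 1):100]) / (1000 - split_cells), numeric(1))
  d <- first - last
  p <- if (length(d) >= 2L && stats::sd(d) > 0) stats::t.test(d)$p.value else NA_real_
  list(mean_first = mean(first), mean_last = mean(last), mean_diff = mean(d),
       p = p, n_used = length(d), n_excluded = sum(!full))
}

#' Repeatability of duplicate evaluations
#'
#' Mean and standard deviation of the second-minus-first differences of
#' duplicate Ki67 reads of the same slides, with a paired-t p-value for a
#' systematic shift between rounds. When all differences are identical the
#' estimates are returned with `degenerate = TRUE` and no p-value.
#'
#' @param round1,round2 Numeric vectors of Ki67 percentages from the two
#'   evaluation rounds, matched by position.
#' @return List with `mean_diff`, `sd_diff`, `p_shift`, `n`, `degenerate`.
#' @export
repeatability <- function(round1, round2) {
  if (length(round1) != length(round2)) {
    stop("rounds must have equal length and matched order", call. = FALSE)
  }
  d <- round2 - round1
  if (length(d) < 2L || stats::sd(d) == 0) {
    return(list(mean_diff = mean(d), sd_diff = if (length(d) >= 2L) 0 else NA_real_,
                p_shift = NA_real_, n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(mean_diff = mean(d), sd_diff = stats::sd(d), p_shift = tt$p.value,
       n = length(d), degenerate = FALSE)
}

#' Compare round-to-round shifts between sample types
#'
#' Welch two-sample t-test on the per-sample round differences of two
#' groups (e.g. core biopsies versus surgical samples), asking whether the
#' systematic shift between duplicate reads differs by sample type.
#'
#' @param diffs1,diffs2 Numeric vectors of per-sample round-2 minus round-1
#'   differences for the two groups.
#' @return List with `mean1`, `mean2`, `p`.
#' @export
compare_shifts <- function(diffs1, diffs2) {
  if (length(diffs1) < 2L || length(diffs2) < 2L) {
    stop("each group needs at least 2 differences", call. = FALSE)
  }
  tt <- stats::t.test(diffs1, diffs2)
  list(mean1 = mean(diffs1), mean2 = mean(diffs2), p = tt$p.value)
}

#' Leave-one-out sensitivity of the paired t-test
#'
#' Re-runs [paired_t_linear()] excluding each pair in turn, exposing how
#' influential single pairs are instead of committing to a hard outlier
#' rule.
#'
#' @inheritParams paired_t_linear
#' @return Data frame with columns `excluded`, `mean_diff`, `p`.
#' @export
loo_sensitivity <- function(biopsy, surgical) {
  check_pairs(biopsy, surgical)
  n <- length(biopsy)
  if (n < 3L) stop("leave-one-out needs at least 3 pairs", call. = FALSE)
  rows <- lapply(seq_len(n), function(i) {
    r <- paired_t_linear(biopsy[-i], surgical[-i])
    data.frame(excluded = i, mean_diff = r$mean_diff, p = r$p)
  })
  do.call(rbind, rows)
}

#' Full paired comparison report for a cohort
#'
#' Runs the whole core-biopsy versus surgical-sample battery at one window
#' size: paired t on the linear and log scales, Wilcoxon signed-rank,
#' dichotomization at the cut-off with concordance table and exact McNemar
#' test, Bland-Altman on both scales, and the leave-one-out sensitivity of
#' the linear t-test.
#'
#' @param pairs List of [sample_pair()] objects.
#' @param n_cells Evaluation window in cells (typically 200 or 1000).
#' @param cutoff Dichotomization cut-off percentage (default 20).
#' @param zero_policy Zero handling for the log scale; see [paired_t_log()].
#' @return An object of class `"cohort_report"`.
#' @export
cohort_report <- function(pairs, n_cells = 200, cutoff = 20,
                          zero_policy = c("exclude", "error", "continuity")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.list(pairs), length(pairs) >= 2L)
  ok <- vapply(pairs, function(p)
    total_cells(p$biopsy) >= n_cells && total_cells(p$surgical) >= n_cells,
    logical(1))
  if (any(!ok)) {
    message(sum(!ok), " pair(s) with fewer than ", n_cells, " cells excluded")
    pairs <- pairs[ok]
  }
  biopsy <- vapply(pairs, function(p) proliferation_at(p$biopsy, n_cells), numeric(1))
  surgical <- vapply(pairs, function(p) proliferation_at(p$surgical, n_cells), numeric(1))
  tab <- concordance_table(biopsy, surgical, cutoff)
  dc <- discordant_counts(tab)
  structure(
    list(n_pairs = length(pairs), n_cells = n_cells, cutoff = cutoff,
         zero_policy = zero_policy, n_excluded = sum(!ok),
         pair_ids = vapply(pairs, `[[`, character(1), "pair_id"),
         biopsy = biopsy, surgical = surgical,
         t_linear = paired_t_linear(biopsy, surgical),
         t_log = paired_t_log(biopsy, surgical, zero_policy, n_cells),
         wilcoxon_p = wilcoxon_signed_rank(biopsy, surgical),
         table2x2 = tab, mcnemar = list(b = dc[["b"]], c = dc[["c"]],
                                        p = mcnemar_exact(dc[["b"]], dc[["c"]])),
         bland_altman_linear = bland_altman(biopsy, surgical, "linear"),
         bland_altman_log = bland_altman(biopsy, surgical, "log", zero_policy, n_cells),
         loo = if (length(pairs) >= 3L) loo_sensitivity(biopsy, surgical),
         conventions = list(two_sided = "central", cutoff_rule = "high iff > cutoff")),
    class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Paired Ki67 comparison, %d pairs at %d cells (cut-off %g%%)\n",
              x$n_pairs, x$n_cells, x$cutoff))
  cat(sprintf("  t-test, linear scale: mean difference %.2f%% (95%% CI %.2f to %.2f), p = %.3g\n",
              x$t_linear$mean_diff, x$t_linear$ci95[1], x$t_linear$ci95[2], x$t_linear$p))
  if (!is.null(x$loo)) {
    loo_range <- range(x$loo$mean_diff)
    cat(sprintf("  leave-one-out mean difference range: %.2f%% to %.2f%%\n",
                loo_range[1], loo_range[2]))
  }
  if (isTRUE(x$t_log$degenerate)) {
    cat(sprintf("  t-test, log scale: geometric-mean ratio %.3g (degenerate, no inference)\n",
                x$t_log$gm_ratio))
  } else {
    cat(sprintf("  t-test, log scale: geometric-mean ratio %.3g (95%% CI %.3g to %.3g), p = %.3g\n",
                x$t_log$gm_ratio, x$t_log$ci95[1], x$t_log$ci95[2], x$t_log$p))
  }
  cat(sprintf("  Wilcoxon signed-rank: p = %.3g\n", x$wilcoxon_p))
  cat(sprintf("  dichotomy at %g%%: %d discordant (%d + %d), McNemar p = %.3g\n",
              x$cutoff, x$mcnemar$b + x$mcnemar$c, x$mcnemar$b, x$mcnemar$c,
              x$mcnemar$p))
  print(x$table2x2)
  ba <- x$bland_altman_linear
  cat(sprintf("  Bland-Altman (linear): bias %.2f%%, limits [%.2f, %.2f]\n",
              ba$bias, ba$lower, ba$upper))
  ba <- x$bland_altman_log
  cat(sprintf("  Bland-Altman (ratio): bias %.3g, limits [%.3g, %.3g]\n",
              ba$bias, ba$lower, ba$upper))
  invisible(x)
}
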