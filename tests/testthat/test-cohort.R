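test_that("proliferation values are exact window fractions", {
  expect_equal(proliferation_at(make_record(rep(2L, 20)), 200), 20)
  expect_equal(proliferation_at(make_record(rep(10L, 100)), 1000), 100)
  # 51 positives over the first 200 cells reads 25.5%
  rec <- make_record(c(spread_counts(51L, 20L), rep(2L, 80)))
  expect_equal(proliferation_at(rec, 200), 25.5)
  expect_error(proliferation_at(make_record(rep(2L, 10)), 200), "only 100 cells")
  expect_error(proliferation_at(make_record(rep(2L, 20)), 205), "multiple of 10")
})

test_that("paired t-test (linear scale) matches the reference routine and closed forms", {
  set.seed(4)
  b <- runif(20, 5, 40)
  s <- b + rnorm(20, -2, 5)
  got <- paired_t_linear(b, s)
  ref <- t.test(b, s, paired = TRUE)
  expect_equal(got$mean_diff, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(got$ci95, as.numeric(ref$conf.int), tolerance = 1e-10)
  # symmetric differences cancel
  expect_equal(paired_t_linear(c(10, 20, 14, 16), c(12, 18, 15, 15))$mean_diff, 0)
  # two pairs with differences 1 and 3: t = 2 on 1 df
  two <- paired_t_linear(c(11, 23), c(10, 20))
  expect_equal(two$mean_diff, 2)
  expect_equal(two$p, 2 * pt(2, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(paired_t_linear(c(10, 20), c(8, 18)), "identical")
})

test_that("log-scale paired t reports geometric-mean ratios with correct inference", {
  set.seed(8)
  b <- exp(rnorm(25, 3, 0.5))
  s <- b * exp(rnorm(25, log(0.81), 0.3))
  got <- paired_t_log(b, s)
  ref <- t.test(log(s / b))
  expect_equal(log(got$gm_ratio), unname(ref$estimate), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  expect_equal(log(got$ci95), as.numeric(ref$conf.int), tolerance = 1e-10)
  # a constant ratio is reported but flagged degenerate
  expect_warning(deg <- paired_t_log(c(10, 20, 30), c(8.1, 16.2, 24.3)), "identical")
  expect_equal(deg$gm_ratio, 0.81, tolerance = 1e-12)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("zero Ki67 values follow the declared log-scale policy", {
  b <- c(0, 10, 20, 30)
  s <- c(5, 8, 18, 24)
  expect_error(paired_t_log(b, s, zero_policy = "error"), "non-positive")
  expect_message(ex <- paired_t_log(b, s, zero_policy = "exclude"), "excluded")
  expect_identical(ex$n, 3L)
  expect_identical(ex$n_excluded, 1L)
  cc <- suppressMessages(paired_t_log(b, s, zero_policy = "continuity", n_cells = 200))
  add <- 100 * 0.5 / 200
  ref <- t.test(log((s + add) / (b + add)))
  expect_equal(log(cc$gm_ratio), unname(ref$estimate), tolerance = 1e-12)
  expect_error(paired_t_log(b, s, zero_policy = "continuity"), "n_cells")
})

test_that("signed-rank p-values agree with full sign enumeration for n <= 10", {
  set.seed(15)
  for (rep_i in 1:12) {
    n <- sample(3:10, 1)
    d <- sample(c(-6:-1, 1:6), n, replace = TRUE)  # ties and signs both common
    expect_equal(wilcoxon_signed_rank(d), enum_wilcoxon_p(d), tolerance = 1e-12)
  }
  # tie-free case also matches the standard exact routine
  d <- c(3.2, -1.1, 4.8, 2.2, -0.7, 5.5, 1.9)
  expect_equal(wilcoxon_signed_rank(d), wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)
  # a single nonzero difference can never be significant
  expect_equal(wilcoxon_signed_rank(c(0, 4), c(0, 1)), 1)
  expect_error(wilcoxon_signed_rank(c(5, 5), c(5, 5)), "zero")
})

test_that("large-sample signed-rank approximation tracks the exact tail", {
  set.seed(23)
  d <- rnorm(40, 0.4, 1)
  approx_p <- wilcoxon_signed_rank(d)             # n > exact_limit
  exact_p <- wilcoxon_signed_rank(d, exact_limit = 40L)
  expect_equal(approx_p, exact_p, tolerance = 0.01)
})

test_that("dichotomization is strict-greater with a boundary flag", {
  expect_identical(as.character(dichotomize(c(20.5, 19.5))), c("high", "low"))
  expect_message(lab <- dichotomize(c(20, 25)), "cut-off")
  expect_identical(as.character(lab), c("low", "high"))
  expect_identical(attr(lab, "boundary"), 1L)
})

test_that("exact McNemar reproduces published discordance p-values and is symmetric", {
  expect_equal(round(mcnemar_exact(10, 2), 3), 0.039)
  expect_equal(mcnemar_exact(4, 4), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  for (b in 0:12) for (cc in 0:12) {
    expect_identical(mcnemar_exact(b, cc), mcnemar_exact(cc, b))
  }
})

test_that("concordance table reproduces the published 2x2 layouts", {
  # 200-cell panel: 19 low/low, 10 biopsy-high/surgical-low,
  # 2 biopsy-low/surgical-high, 19 high/high
  b200 <- c(rep(10, 19), rep(30, 10), rep(10, 2), rep(30, 19))
  s200 <- c(rep(10, 19), rep(10, 10), rep(30, 2), rep(30, 19))
  tab <- concordance_table(b200, s200, 20)
  expect_identical(as.integer(tab), c(19L, 10L, 2L, 19L))
  dc <- discordant_counts(tab)
  expect_identical(sum(dc), 12L)
  expect_identical(dc, c(b = 10L, c = 2L))
  # 1000-cell panel: 29 low/low, 4 + 4 discordant, 13 high/high
  b1000 <- c(rep(10, 29), rep(30, 4), rep(10, 4), rep(30, 13))
  s1000 <- c(rep(10, 29), rep(10, 4), rep(30, 4), rep(30, 13))
  tab2 <- concordance_table(b1000, s1000, 20)
  expect_identical(as.integer(tab2), c(29L, 4L, 4L, 13L))
  expect_identical(sum(tab2), 50L)
})

test_that("off-diagonal count equals the number of label-discordant pairs", {
  set.seed(31)
  b <- runif(60, 0, 45)
  s <- runif(60, 0, 45)
  tab <- concordance_table(b, s, 20)
  direct <- sum((b > 20) != (s > 20))
  expect_identical(sum(discordant_counts(tab)), as.integer(direct))
})

test_that("Bland-Altman bias and limits behave on both scales", {
  # constant difference: limits collapse onto the bias
  b <- c(12, 22, 30, 18)
  s <- b - 3
  ba <- bland_altman(b, s, "linear")
  expect_equal(ba$bias, 3)
  expect_equal(ba$lower, 3)
  expect_equal(ba$upper, 3)
  # linear bias is the paired-t mean difference by construction
  set.seed(44)
  b <- runif(30, 5, 45); s <- b + rnorm(30, -2, 4)
  expect_equal(bland_altman(b, s, "linear")$bias, paired_t_linear(b, s)$mean_diff)
  # log-scale bias is the geometric-mean ratio
  s_pos <- pmax(s, 0.5)
  expect_equal(bland_altman(b, s_pos, "log")$bias, paired_t_log(b, s_pos)$gm_ratio)
})

test_that("Bland-Altman reference limits cover about 95% of lognormal pairs", {
  set.seed(52)
  b <- exp(rnorm(4000, 3, 0.4))
  s <- b * exp(rnorm(4000, -0.2, 0.3))
  ba <- bland_altman(b, s, "log")
  inside <- mean(ba$values >= ba$lower & ba$values <= ba$upper)
  expect_equal(inside, 0.95, tolerance = 0.015)
})

test_that("dilution contrast computes exact window means and detects decay", {
  # one synthetic sheet: 51/200 positives up front, 162/800 after
  rec <- make_record(c(spread_counts(51L, 20L), spread_counts(162L, 80L)))
  one <- dilution_contrast(list(rec, rec), 200)
  expect_equal(one$mean_first, 25.5)
  expect_equal(one$mean_last, 20.25)
  expect_equal(one$mean_diff, 5.25)
  # short records are excluded, not fatal
  expect_message(
    mix <- dilution_contrast(list(rec, rec, make_record(rep(2L, 20))), 200),
    "excluded")
  expect_identical(mix$n_used, 2L)
  expect_identical(mix$n_excluded, 1L)
})

test_that("dilution contrast is null under homogeneous counting and positive under decay", {
  params_h <- generator_params(p_hot = 0.25, p_bg = 0.25, seed = 7)
  set.seed(7)
  recs <- replicate(60, generate_record(params_h), simplify = FALSE)
  res <- dilution_contrast(recs, 200)
  # homogeneous truth: mean difference within 3 SEs of zero
  se <- sd(vapply(recs, function(r) proliferation_at(r, 200), numeric(1))) / sqrt(60)
  expect_lt(abs(res$mean_diff), 3 * sqrt(se^2 * 2) + 1)
  params_d <- generator_params(seed = 8)
  set.seed(8)
  recs_d <- replicate(60, generate_record(params_d), simplify = FALSE)
  expect_gt(dilution_contrast(recs_d, 200)$mean_diff, 0)
})

test_that("repeatability summarizes duplicate reads and flags degeneracy", {
  expect_true(repeatability(c(10, 20, 30), c(10, 20, 30))$degenerate)
  const <- repeatability(c(10, 20, 30), c(12, 22, 32))
  expect_equal(const$mean_diff, 2)
  expect_equal(const$sd_diff, 0)
  expect_true(const$degenerate)
  set.seed(61)
  r1 <- runif(30, 5, 40)
  r2 <- r1 + rnorm(30, 2.5, 3)
  res <- repeatability(r1, r2)
  ref <- t.test(r2 - r1)
  expect_equal(res$p_shift, ref$p.value, tolerance = 1e-12)
  expect_error(repeatability(1:3, 1:4), "equal length")
})

test_that("between-type shift comparison is a two-sample t on round differences", {
  set.seed(71)
  d1 <- rnorm(25, 2.6, 5.7)
  d2 <- rnorm(25, 1.8, 5.6)
  got <- compare_shifts(d1, d2)
  expect_equal(got$p, t.test(d1, d2)$p.value, tolerance = 1e-12)
})

test_that("leave-one-out sensitivity matches explicit exclusion", {
  set.seed(81)
  b <- runif(12, 5, 40); s <- b + rnorm(12, -2, 6)
  loo <- loo_sensitivity(b, s)
  expect_identical(nrow(loo), 12L)
  i <- 5L
  expect_equal(loo$mean_diff[i], paired_t_linear(b[-i], s[-i])$mean_diff)
  expect_equal(loo$p[i], paired_t_linear(b[-i], s[-i])$p)
})

test_that("cohort report assembles a consistent battery", {
  params <- generator_params(n_pairs = 30, seed = 5)
  pairs <- generate_cohort(params, n_cells = 200)
  rep200 <- suppressMessages(cohort_report(pairs, n_cells = 200))
  expect_s3_class(rep200, "cohort_report")
  expect_identical(sum(rep200$table2x2), 30L)
  expect_identical(rep200$mcnemar$b + rep200$mcnemar$c,
                   sum(discordant_counts(rep200$table2x2)))
  expect_equal(rep200$bland_altman_linear$bias, rep200$t_linear$mean_diff)
  expect_identical(nrow(rep200$loo), 30L)
  expect_output(print(rep200), "geometric-mean ratio")
})
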