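---
title: "Sequential counting for Ki67 classification: model, calibration, and the paired-sample battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential counting for Ki67 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ki67seq)
```

## The counting model and its assumptions

Manual Ki67 scoring records, in counting order, the number of positively
stained nuclei in consecutive blocks of 10 tumor cells, beginning in the
hotspot. `ki67seq` treats such a counting sheet as the realization of a
Bernoulli process: under the working assumption of *homogeneous* staining,
the cumulative positive count after `n` cells is Binomial(`n`, `p`), and
the clinically relevant question — is `p` above or below the 20% cut-off? —
becomes a two-sided test of `H0: p = 0.2`.

The sequential rule tests this null with an exact binomial test at 100
cells and again after every further 10 cells, up to 400. The first
rejection classifies the sample `high` or `low` and stops counting; if no
test rejects by 400 cells the sample is `unclassifiable`. Two asymmetries
of the rule are deliberate and follow from the counting protocol itself:

* **There is no early "acceptance" stop.** An observed fraction near 20%
  at 150 cells is compatible both with `p = 0.2` and with a `p` that the
  remaining looks could still resolve, so the procedure only ever stops on
  rejection or on exhausting the 400-cell budget.
* **The budget stops at 400 cells, not 1000.** Counting further cells
  would keep adding power, but hotspots are typically exhausted within a
  few hundred cells, after which the homogeneity assumption degrades and
  the cumulative fraction is diluted by lower-proliferation tissue. The
  cap trades power against that dilution.

The lower and upper rejection bounds at each grid point are stored as
*integer counts* (`build_rejection_table()`), because the test operates on
cumulative integers; the fraction bounds `k/n` shown in plots and exports
are derived, never primary. A count exactly at the null mode has a central
p-value of 1 by construction, so samples pinned at 20% can never reject
and no tie-break is needed.

### Two-sided convention

Exact two-sided binomial p-values are not unique. The package defaults to
the **central** (doubled smaller tail, capped at 1) convention:
`min(1, 2 min(P[X <= k], P[X >= k]))`. It is simple, has monotone tails
(so rejection regions are contiguous and the sequential walk well
defined), and reproduces the standard exact McNemar p-values. The
minimum-likelihood convention used by `binom.test()` is available via
`convention = "minlik"` everywhere it matters; boundary counts can differ
by one at a few `n`, and the calibrated per-test level may legitimately
shift by about 0.001 between conventions. The convention in force is
recorded in table attributes and report headers.

## Calibrating the per-test level

Each of the 31 looks is an exact test at level `alpha`, but the looks are
strongly dependent (overlapping cumulative counts), so the overall
type-I error is far below `31 * alpha` and has no convenient closed form.
`simulate_overall_type1()` estimates it by direct simulation of
homogeneous Bernoulli(0.2) counting; `calibrate_alpha()` searches a grid
of nominal levels for the largest whose estimated overall error stays at
or below the 5% target — the conservative reading of "the overall level is
preserved".

Numerical choices:

* **100,000 replicates** by default: the Monte-Carlo standard error at an
  estimate of 0.05 is about 0.0007, an order of magnitude below the 0.001
  grid resolution of the calibration search.
* **Common random numbers**: one set of simulated counting runs is shared
  by every candidate level, summarized per replicate by the *minimum
  p-value across the grid* (the procedure rejects at level `alpha` iff
  that minimum is `<= alpha`). The estimated calibration curve is then
  monotone in `alpha` by construction, so the search cannot be confused by
  between-point simulation noise.
* **Cross-checks**: on a one-point grid the simulated size must match the
  analytic achieved size `achieved_size(n, p0, alpha)` (a binomial tail
  sum), and the sequential estimate must fall between the largest
  single-look size and the Bonferroni sum; both are asserted in the test
  suite.

With the defaults the calibration selects `alpha = 0.012` per test
(a 98.8% exact confidence interval at each look) for an estimated overall
level of about 0.049.

## The paired-sample battery

`cohort_report()` runs the comparison battery for matched core-biopsy /
surgical-sample cohorts at a chosen window (200 or 1000 cells):
paired t on the percentage scale, paired t on the log scale reported as a
geometric-mean ratio, the Wilcoxon signed-rank test, dichotomization at
the cut-off with the exact McNemar test on the discordant pairs, and
Bland–Altman agreement on both scales. Conventions that the underlying
problem leaves open were fixed as follows:

* **Direction.** Linear-scale differences are biopsy minus surgical
  (positive numbers mean the biopsy reads higher); ratios are
  surgical over biopsy. With this pairing the Bland–Altman linear bias
  equals the paired-t mean difference and the log bias equals the
  geometric-mean ratio, so the agreement plot and the tests cannot
  disagree about the estimate.
* **Exactly at the cut-off** counts as `low` (strict-greater defines
  `high`) — conservative toward low proliferation — and such values are
  flagged by position, since a fraction sitting exactly on the threshold
  deserves a second look rather than silent assignment.
* **Zeros on the log scale.** Policy options are `exclude` (default; the
  number of dropped pairs is reported), `error`, and `continuity` (half a
  positive cell added to every value, which requires the window size to
  convert cells to percent).
* **Wilcoxon variant.** Zero differences are dropped and absolute
  differences mid-ranked. The exact null distribution of the rank sum is
  computed by dynamic programming over the doubled mid-ranks for up to 25
  nonzero differences — this handles ties exactly, which the standard
  exact routine cannot — with a tie-corrected, continuity-corrected normal
  approximation beyond. The two-sided p is the doubled smaller tail,
  capped at 1, matching the binomial convention above.
* **McNemar** is the exact central binomial test of `min(b, c)` in
  `b + c` trials at probability one half, not the chi-square
  approximation; with no discordant pairs the p-value is 1.
* **Outliers.** Rather than hard-coding an exclusion rule for influential
  pairs, the report carries a leave-one-out sensitivity sweep of the
  linear t-test (`loo_sensitivity()`), exposing how much any single pair
  moves the estimate.
* **Repeatability.** Duplicate reads are summarized by the mean and SD of
  the round differences with a paired-t p for a systematic shift;
  between-type comparison of shifts uses a Welch two-sample t on the
  per-sample round differences.
* **Dilution contrast.** `dilution_contrast()` compares each full
  1000-cell sheet's first-`s` window with the remainder (default
  `s = 200`) and runs a paired t across samples. A positive mean
  difference is the quantitative signature of hotspot dilution.

Degenerate inputs are handled explicitly: zero-variance differences error
on the linear scale, while a constant ratio returns its point estimate
flagged `degenerate` with no inference (the estimate is meaningful even
when no variance is available to test against).

## What the generator emulates — and what it does not

`generate_cohort()` produces paired counting sheets with the three
structural features the analyses depend on:

1. **Hotspot-first counting with decay.** Each cell is Bernoulli with a
   probability profile that holds a hotspot rate for `hotspot_cells`,
   decays to a background rate over `decay_cells`, and stays there. The
   decay shape is unobservable from cumulative counts alone; `linear` is
   the default because the expected window means are then simple
   integrals (the test suite checks the simulated first-200 minus
   last-800 contrast against that closed form), with `step` and
   `exponential` available.
2. **Between-tumor spread.** The biopsy hotspot rate is logit-normal,
   centred so that roughly one third of tumors exceed the 20% cut-off —
   the regime in which a 20% threshold is clinically interesting
   (defaults `qlogis(0.16)`, SD 0.6 on the logit scale).
3. **Multiplicative biopsy-to-surgical coupling.** The surgical hotspot
   rate is the biopsy rate times a lognormal factor with geometric mean
   `ratio_gm` (default 0.81, i.e. surgical samples reading ~19% lower)
   and log-SD `ratio_sd_log` (default 0.6, chosen so the spread of
   observed log ratios at a 200-cell window is of the order implied by a
   50-pair confidence interval roughly 0.65–1.0 wide). Multiplicative
   coupling matches the log-scale analysis; proliferation offsets between
   sampling modalities act on rates, not percentage points.

Default profile rates (`p_hot = 0.255`, `p_bg = 0.202` with a 200-cell
hotspot and 300-cell decay) put the first-200 versus last-800 contrast
near five percentage points for a mid-20s hotspot — a realistic dilution
magnitude for breast-cancer material. Re-read variability
(`generate_duplicate_counts()`) redraws counts around the same profile
plus a per-record observer effect, Normal(`shift = 0.02`,
`reread_sd = 0.04`) on the rate scale; these are order-of-magnitude
choices, since duplicate-read summaries constrain them only loosely.

The generator models the *counting sequence*, not the microscopy: there
is no 2-D tissue geometry, no field selection, no staining artifacts, and
the observer effect is a level shift rather than cell-level
disagreement. Passing tests therefore demonstrate correctness of the
statistics under the stated stochastic model — binomial counting with a
smooth rate profile — not robustness to every failure mode of real
slides, where proliferation can be patchy on scales the profile does not
represent.

## Problem sizes used by the test suite

The packaged tests run the calibration at its default 100,000 replicates,
verify the binomial kernel against brute-force pmf summation for every
count at every `n` up to 400, recover a generated geometric-mean ratio of
0.81 from 40 cohorts of 50 pairs, check 95% CI coverage over 200 cohorts,
and estimate the paired-t size from 2,000 zero-offset cohorts — sizes at
which every Monte-Carlo tolerance used (three standard errors) is small
relative to the effects being checked, while the whole suite stays fast
enough to run routinely.

## Known limitations

* The homogeneity assumption behind both the binomial test and the
  calibration is exactly the assumption the dilution effect violates past
  the hotspot; the 400-cell cap limits, but does not remove, that
  tension. The rejection table is honest only as far as the counted
  window is hotspot-like.
* Calibration is simulation-based; no analytic expression for the
  sequential procedure's overall size is provided beyond the single-look
  cross-check.
* The battery treats pairs as exchangeable; covariates (receptor status,
  grade) are out of scope.
* CSV is the only interchange format — manual counting sheets have no
  domain standard — and counts are always stored per increment, never
  cumulatively, to keep a single source of truth.
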