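# ki67seq

Sequential exact binomial scoring of Ki67 proliferation counting sheets,
with the paired core-biopsy versus surgical-sample comparison battery and a
synthetic counting-data generator.

## The problem

The Ki67 index — the fraction of positively stained tumor nuclei — is a
standard proliferation marker in breast cancer, usually dichotomized at a
20% cut-off. Manual scoring counts cells in consecutive 10-cell increments,
starting in the *hotspot* (the region of visibly elevated proliferation).
Two practical questions follow:

1. **How many cells must be counted** to call a sample high or low with
   controlled error? Counting a fixed 1000 cells is laborious, and counting
   past the hotspot *dilutes* the estimate as lower-proliferation tissue
   enters the denominator.
2. **Do core biopsies and surgical resections agree** on Ki67, given that
   treatment decisions are increasingly made from the biopsy alone?

`ki67seq` implements a sequential answer to the first question and the full
statistical battery for the second, for biostatisticians and pathology
groups designing or evaluating Ki67 counting protocols.

## The model

Under homogeneous staining, the cumulative number of positive cells `K_n`
among `n` counted cells is Binomial(`n`, `p`). The null `H0: p = 0.2` is
tested with an exact central two-sided binomial test,

    p(k, n) = min(1, 2 * min(P[X <= k], P[X >= k])),  X ~ Bin(n, 0.2),

first at `n = 100` cells and then every 10 cells up to `n = 400`. Counting
stops at the first rejection — classifying the sample **high** or **low** —
otherwise the sample is **unclassifiable** at 400 cells. Because the tests
are repeated on overlapping cumulative counts, each test is run at a
calibrated per-test level `alpha = 0.012` (a 98.8% exact confidence
interval), which Monte-Carlo simulation shows preserves the overall
type-I error of the whole procedure at approximately 5%.

Around the classifier the package provides paired t-tests on the linear and
log (geometric-mean ratio) scales, the exact Wilcoxon signed-rank test,
dichotomization with the exact McNemar test, Bland–Altman agreement limits,
repeatability of duplicate reads, a hotspot-dilution contrast (first 200
versus last 800 cells), and a generator producing realistic hotspot-first
counting sheets for paired cohorts.

## Worked example

```r
library(ki67seq)

tab <- build_rejection_table()       # p0 = 0.2, alpha = 0.012, 100..400 cells
head(tab, 3)
#>    n k_low k_high  frac_low frac_high
#>  100    10     32 0.1000000 0.3200000
#>  110    11     34 0.1000000 0.3090909
#>  120    13     36 0.1083333 0.3000000

params <- generator_params(n_pairs = 50, seed = 42)
cohort <- generate_cohort(params)    # 50 biopsy/surgical pairs, 1000 cells each

sequential_classify(cohort[[1]]$biopsy, tab)
#> <sequential_decision> P001: high at 110 cells (observed 33.6%)

recs <- unlist(lapply(cohort, function(p) list(p$biopsy, p$surgical)),
               recursive = FALSE)
table(classify_records(recs, tab)$status)
#>           high            low unclassifiable
#>             22             57             21

cohort_report(cohort, n_cells = 200)
#> Paired Ki67 comparison, 50 pairs at 200 cells (cut-off 20%)
#>   t-test, linear scale: mean difference 0.95% (95% CI -1.98 to 3.88), p = 0.518
#>   leave-one-out mean difference range: 0.52% to 1.45%
#>   t-test, log scale: geometric-mean ratio 0.78 (95% CI 0.618 to 0.985), p = 0.0371
#>   Wilcoxon signed-rank: p = 0.385
#>   dichotomy at 20%: 16 discordant (8 + 8), McNemar p = 1
#> ...

simulate_overall_type1(replicates = 1e5, seed = 1)
#> Sequential test calibration (p0 = 0.2, grid 100-400, central convention)
#>   per-test alpha: 0.012
#>   overall type-I error: 0.0485 (MC SE 0.0007, 100000 replicates, seed 1)
```

The first block is the rejection table: at 100 cells, 10 or fewer positives
(10%) reject downward and 32 or more (32%) reject upward; the band narrows
toward 20% as counting proceeds. The classifier calls the first biopsy
*high* after only 110 cells. In the simulated cohort report the surgical
samples read about 22% lower than the biopsies on the multiplicative scale
(geometric-mean ratio 0.78, near the generator's target of 0.81), while the
linear-scale difference of 0.95 percentage points is not significant —
the two scales genuinely answer different questions when the spread grows
with the mean. The last block confirms the calibration: testing at 0.012
per look keeps the whole sequential procedure's false-positive rate at
about 5%.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ki67count.R", package = "ki67seq"))')" \
    region-table --alpha 0.012 -o table.csv
```

with subcommands `region-table`, `classify`, `calibrate`, `cohort-compare`
and `simulate`.

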