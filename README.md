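# emadhere

Adherence analysis for smartphone-based ecological momentary assessment
(EMA) recording.

Observational mHealth apps that prompt their users several times a day — the
motivating case is tinnitus monitoring with a seven-item momentary
questionnaire — lose most users within days. `emadhere` is for analysts who
want to quantify that loss and ask what predicts it. It implements, as a
tested R pipeline:

1. **Adherence metrics.** A user has an *EMA entry* on a day if they
   answered at least one item of one prompt. Within an `N = 30` day horizon
   of interaction days, the package computes per user the interaction
   duration `Duration_u = max_j n_{u,j}` (days with entries, breaks
   allowed), the continuity measure `FirstDays_u = max_j FirstDays_{u,j}`
   (initial run of adjacent days until the first break), the dichotomous
   `Return_u = Yes ⇔ Duration_u > FirstDays_u` (did the user resume after
   the first break?), and the horizon-free `NumDays`.
2. **Return-after-break classification.** Per EMA item and per
   `FirstDays = k` stratum (`k = 1..9` plus a pooled `≥10`), equal-length
   early time series are classified into returners vs. non-returners with
   1-nearest-neighbour rules under elastic distances — Euclidean, dynamic
   time warping (squared local cost, unconstrained), derivative DTW,
   complexity-invariant distance, move–split–merge — plus a Gaussian naive
   Bayes baseline; models are retained only if they beat the stratum's
   majority-class prior by `τ_improve = 8` percentage units under a seeded
   2:1 stratified holdout.
3. **Registration rules.** Hot-spot style classification-rule induction for
   `Return = Yes` over the MiniTF and TSCHQ registration questionnaires
   (and the `NumDays` feature), with support ≥ 0.01, antecedent length ≤ 2,
   precision-gain pruning, `support/precision/lift` reporting and a
   one-sided exact significance filter at α = 0.05 (uncorrected).
4. **A synthetic cohort generator** with plantable ground truth (item
   effects on the return odds, registration antecedents with target support
   and precision), so the whole chain is validated end to end.

## Worked example

```r
library(emadhere)
library(dplyr)

g <- generate_cohort(synth_config(n_users = 800, seed = 1))
profiles <- adherence_profiles(g$cohort$recordings)
head(profiles[1:5], 4)
#> # A tibble: 4 × 5
#>   user_id duration first_days return num_days
#>   <chr>      <int>      <int> <fct>     <int>
#> 1 u00001         4          3 Yes           4
#> 2 u00002         3          3 No            3
#> 3 u00003         1          1 No            1
#> 4 u00004         1          1 No            1

head(duration_histogram(profiles), 5)
#> # A tibble: 5 × 2
#>   duration n_users
#>      <int>   <int>
#> 1        1     247
#> 2        2      90
#> 3        3      74
#> 4        4      67
#> 5        5      60
```

A third of the cohort never records a second day (247 of 800 users have
duration 1), and the count falls away quickly — the right-skewed engagement
profile this kind of app shows in the wild. Overall `30.1%` of users return
after their first break. Building the per-item strata on the users with more
than one recording and evaluating the classifier battery:

```r
rec <- g$cohort$recordings
counts <- table(rec$user_id)
rec <- rec[rec$user_id %in% names(counts)[counts > 1], ]
strata <- build_strata(daily_series(rec))
format_strata_summary(strata)[1:2, 1:5]
#> # A tibble: 2 × 5
#>   item  `1`               `2`              `3`              `4`
#>   <chr> <chr>             <chr>            <chr>            <chr>
#> 1 q1    9 vs. 109 (0.92)  60 vs. 60 (0.50) 34 vs. 24 (0.59) 34 vs. 25 (0.58)
#> 2 q2    13 vs. 110 (0.89) 58 vs. 59 (0.50) 34 vs. 24 (0.59) 36 vs. 21 (0.63)

grid <- run_grid(strata)
glance(grid)
#> # A tibble: 1 × 6
#>   n_entries n_evaluated n_skipped n_retained retained_fraction max_improvement
#>       <int>       <int>     <int>      <int>             <dbl>           <dbl>
#> 1       420         399        21         35            0.0877            16.9
```

Each cell of the stratum summary reads "No vs. Yes (majority prior)": after
a one-day run most users come back (prior 0.92 towards `Yes`), after two
days the classes are balanced, and beyond that the majority flips to
quitting for good. Of 420 (algorithm, item, stratum) combinations, 21 are
skipped with recorded reasons (one-class strata, series too short for
derivative DTW), and — on this effect-free cohort — only 8.8% of evaluated
models clear the 8-point improvement bar, which is the false-retention level
the filter is designed to keep low. `improvement_filter(grid)` lists the
retained entries, `grid_table(grid)` renders the algorithm-by-stratum table,
and `autoplot(grid)` draws it.

Rule mining runs the same way from a cohort:
`run_rules(g$cohort)$minitf` returns the mined `ema_rules` tibble (here
empty to a handful of chance rules, since nothing is planted), and
`tidy()`/`glance()` give broom-style views of any result object.

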