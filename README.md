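# methtier

Three-tier classification of *MGMT* promoter methylation from
pyrosequencing, with survival-informed cut-offs.

## The problem

*MGMT* promoter methylation is the one positive predictive biomarker for
alkylating chemotherapy (temozolomide) in glioblastoma, yet laboratories
using quantitative pyrosequencing of CpGs 76–79 disagree on where to cut the
continuous percent-methylation scale. `methtier` implements a principled,
two-sided answer for biostatisticians and molecular pathologists working
with such data:

- **Unsupervised cut-off** — mean methylation is strongly bimodal on the log
  scale. A two-component normal mixture
  `f(x) = π₁ N(x; μ₁, σ₁²) + π₂ N(x; μ₂, σ₂²)` is fitted to
  `x = log(mean % methylation)` by EM, and the cut-off is the intersection
  point of the weighted component densities,
  `π₁ N(x*; μ₁, σ₁²) = π₂ N(x*; μ₂, σ₂²)` — a quadratic in `x*` solved in
  closed form and back-transformed to percent. Values at or above it are
  "methylated".
- **Supervised cut-off** — integer candidate thresholds `c = 1..25%` are
  scanned; at each, a log-logistic accelerated failure time (AFT) model
  `log T = β₀ + β_meth·1(meth > c) + β_age·(age−60)/10 + β_ps·PS +
  β_res + σW` (W standard logistic) is refit under 5-fold cross-validation
  and scored by Harrell's concordance index on the held-out folds; the
  candidate with the highest mean out-of-fold C wins. Values at or below it
  are "truly unmethylated".
- **Gray zone** — the interval strictly between the two cut-offs, where
  treatment benefit is uncertain.

The three tiers are then compared with Kaplan–Meier curves, median overall
survival, fixed-horizon survival rates and pairwise log-rank tests. Because
clinical registry cohorts are rarely shareable, the package includes a
seeded synthetic-cohort generator with the same statistical structure
(bimodal log-normal methylation with per-CpG noise, realistic covariate
marginals, log-logistic survival, administrative censoring), which also
powers the test suite.

## Worked example

```r
library(methtier)

sim <- simulate_cohort(sim_config(n = 451, seed = 42))
fit <- fit_bnmm(sim$cohort$mean_meth, seed = 1)
cut <- intersection_cutoff(fit)
print(fit); print(cut)
#> Two-component normal mixture on log methylation
#>   n = 451, loglik = -698.810, 15 EM iterations, converged: TRUE
#> # A tibble: 2 × 5
#>   component    weight mean_log sd_log median_pct
#>   <chr>         <dbl>    <dbl>  <dbl>      <dbl>
#> 1 unmethylated  0.615     1.01  0.626       2.74
#> 2 methylated    0.385     3.71  0.566      40.7
#> unsupervised methylation cut-off: 11.867% (rounded: 12%)

scan <- scan_thresholds(sim$cohort, cv_seed = 1)
rule <- derive_three_tier(cut, supervised_cutoff(scan))
print(rule)
#> Three-tier rule: unmethylated <= 5%, gray zone (5, 12)%, methylated >= 12%

three_tier_survival_report(sim$cohort, rule)
#> # A tibble: 3 × 4
#>   tier             n n_events median_os
#>   <fct>        <int>    <dbl>     <dbl>
#> 1 unmethylated   231      224      11.8
#> 2 gray_zone       45       44      20.8
#> 3 methylated     175      146      31.3
#> # A tibble: 3 × 4
#>   group_a      group_b    chi_square  p_value
#>   <chr>        <chr>           <dbl>    <dbl>
#> 1 unmethylated gray_zone        9.92 1.63e- 3
#> 2 unmethylated methylated      77.9  1.07e-18
#> 3 gray_zone    methylated       7.01 8.10e- 3
```

Reading the output: the mixture puts 61.5% of tumors in a mode with median
methylation 2.7% and the rest around 41%, crossing at 11.9% (the
unsupervised "methylated" threshold). The survival-informed scan picks 5% as
the best "truly unmethylated" boundary on this simulated cohort; patients
between the two cut-offs form the gray zone, whose survival (median 20.8
months) falls between the unmethylated (11.8) and methylated (31.3) tiers,
with all pairwise log-rank tests significant. Because the simulator drives
survival through the latent methylation class rather than a sharp threshold
on measured methylation, the supervised cut-off fluctuates across seeds
within the low-density region between the two modes; the mixture cut-off is
much more stable.

`run_pipeline()` chains all of the above (plus the per-CpG vs mean
comparison and a serializable JSON report), and
`autoplot()`/`tidy()`/`glance()` methods are available for every fitted
object. A thin command-line front end ships at `inst/cli/methtier`
(subcommands `simulate`, `fit-mixture`, `scan-threshold`, `run-all`).

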