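# mnarsens

Sensitivity analysis for outcome data **missing not at random (MNAR)**
in two-arm pre/post randomized trials, plus a differential-attrition
meta-analysis engine for study-level 2×2 dropout tables.

Mobile-health RCTs with waitlist controls typically lose many more
participants from the active arm than from the control arm. When the
chance that a posttest is missing depends on the unobserved outcome
itself, MI- and ML-based analyses are biased, and no test can detect it.
`mnarsens` quantifies how conclusions depend on explicit MNAR
assumptions:

* **Pattern-mixture offset analysis** — multiply impute the missing
  posttests (proper Bayesian linear regression, default m = 100), shift
  the imputed values by `delta × SD_model` (the residual SD of the
  completers ANCOVA `posttest ~ pretest + arm`), re-fit the ANCOVA per
  completed dataset, and pool by Rubin's rules with Barnard–Rubin
  degrees of freedom, across `delta ∈ {0, 0.2, 0.5, 0.8, 1.1, 1.4}`.
  `delta = 0` is ordinary MI under MAR; the table shows where the
  treatment effect stops being distinguishable from zero.
* **Fixed-value replacement analysis** — compute residualized change
  (observed minus pretest-predicted posttest, completers, no group
  term), replace each missing subject's residual with a fixed scenario
  value (`small`/`medium`/`large` = mean + 0.2/0.5/0.8 SD,
  `worst_case` = worst observed residual), and compare arms with a
  tie-corrected two-sample rank-sum test (exact for small tie-free
  groups).
* **Attrition meta-analysis** — per-study log odds ratios of dropout
  (standard, with an all-cells +0.5 continuity correction for zero-cell
  studies, or Peto `(O−E)/V`), REML/DL random-effects pooling with
  Q-profile I² intervals, classic fixed-effect Peto pool, leave-one-out,
  CI-overlap outlier detection, and mixed-effects meta-regression.
  A table of attrition counts for 36 smartphone-intervention RCTs with
  waitlist controls ships with the package (`attrition_fixture()`).
* **Synthetic trials** — `simulate_trial()` / `simulate_study_table()`
  generate data with configurable MCAR/MAR/MNAR missingness and a
  pattern-mixture `mnar_shift`, so every stage is testable end to end.

## Worked example

Pooling the packaged 36-study table:

```r
library(mnarsens)
tab <- attrition_fixture()
eff <- compute_log_or(tab, correct = TRUE)  # +0.5 on zero-cell studies
pool_random_effects(eff)
#> Pooled log OR (random-REML, k = 36)
#>   mu = 0.6635 [0.4049, 0.9220], OR = 1.94 [1.50, 2.51], p = 4.93e-07
#>   tau^2 = 0.2459, I^2 = 53.85% [19.46, 71.09]
```

Dropping out is about twice as likely in active arms (OR 1.94), with
moderate between-study heterogeneity (I² ≈ 54%). `detect_outliers()`
flags 4 studies whose CIs miss the pooled CI; re-pooling without them
gives OR 1.91, so the result is not driven by them.

A sensitivity analysis on a synthetic trial that mimics such a study
(228/115 allocation, missingness 60% vs 42%, true effect −0.34 on a
z-scaled outcome, MNAR selection plus a 0.5-SD worsening of the hidden
outcomes):

```r
d <- simulate_trial(mechanism = "MNAR_on_posttest", mnar_shift = 0.5, seed = 42)
run_sensitivity(d, m = 50, seed = 42)
#>   delta estimate    se   df       p
#> 1   0.0   -0.355 0.120 75.6 0.00403
#> 2   0.2   -0.328 0.120 75.9 0.00768
#> 3   0.5   -0.288 0.121 78.1 0.01970
#> 4   0.8   -0.248 0.123 82.4 0.04735
#> 5   1.1   -0.207 0.126 88.6 0.10344
#> 6   1.4   -0.167 0.130 96.7 0.20159
```

Read the rows as increasingly pessimistic assumptions about the
dropouts: the MAR estimate (−0.36, p = .004) stays significant through
a large assumed deviation (delta = 0.8) and dissolves beyond it — the
effect is robust to small-to-large MNAR deviations but not extreme
ones. The fixed-value analysis of the same data (`run_scenarios(d)`)
tells a harsher story, as it should — its replacement values ignore the
group-specific improvement MI builds in:

```r
run_scenarios(d)[, c("scenario", "group", "n", "mean_rank", "p")]
#>         scenario   group   n mean_rank        p
#> 1  complete_case  active  83     64.81 0.002874
#> 2  complete_case passive  64     85.92       NA
#> 3     worst_case  active 228    179.83 0.022128
#> 4     worst_case passive 115    156.47       NA
#> 5          small  active 228    162.64 0.006361
#> 6          small passive 115    190.55       NA
#> 7         medium  active 228    165.75 0.068485
#> 8         medium passive 115    184.39       NA
```

Lower mean rank = larger decline. Completers favour the active arm
(p = .003); the worst-case scenario *reverses* the direction
(active 179.8 vs passive 156.5); significance survives the small
scenario only. Reporting this whole trajectory, rather than one MAR
estimate, is the point of the package.

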