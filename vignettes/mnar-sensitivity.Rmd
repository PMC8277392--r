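---
title: "Sensitivity analysis for outcome data missing not at random"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensitivity analysis for outcome data missing not at random}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnarsens)
```

## The problem

Randomized trials of mobile-health interventions that use a waitlist or
no-treatment control routinely lose far more participants from the
active arm than from the control arm. Across the 36 trials in the
packaged attrition table, active participants were roughly twice as
likely to miss the posttreatment assessment. Differential attrition of
this kind raises the possibility that the outcome data are *missing not
at random* (MNAR): the probability that a posttest is missing may depend
on the unobserved posttest itself — for instance if participants who
benefit less are the ones who stop responding. Multiple imputation (MI)
and maximum likelihood handle data that are missing (completely) at
random, but neither can remove MNAR bias, and MNAR can never be
confirmed or refuted from the observed data. What *can* be done is a
sensitivity analysis: re-estimate the treatment effect under a spectrum
of explicit assumptions about how bad the missing outcomes were, and
report where the conclusion starts to change.

`mnarsens` implements two such analyses for the common two-arm
pre/post design with a continuous outcome, a meta-analysis engine for
quantifying differential attrition across studies, and a synthetic-data
generator against which every stage is validated.

## The pattern-mixture offset analysis

Write the analysis model as the ANCOVA

$$ Y_{\text{post}} = \beta_0 + \beta_1 Y_{\text{pre}} + \beta_2\,
\text{active} + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2), $$

where $\beta_2$ is the treatment effect of interest. The procedure
(`run_sensitivity()`) is:

1. **Impute.** `multiple_impute()` fills the missing posttests by proper
   Bayesian linear regression on pretest, arm and any covariates: for
   each of the $m$ completed datasets it draws the residual variance
   from its scaled inverse-$\chi^2$ posterior, the coefficients from
   their conditional normal posterior, and each missing value from the
   predictive normal. With a single incomplete variable these conjugate
   draws are exact, so there is no Markov chain and nothing to tune or
   monitor for convergence. The default is $m = 100$.
2. **Shift.** `apply_offset()` adds $\delta \times SD_{\text{model}}$ to
   the *imputed* entries only, where $SD_{\text{model}}$ is the residual
   SD of the completers ANCOVA *with* the group term
   (`fit_outcome_model()`). The shift is added for lower-is-better
   outcomes (distress) and subtracted for higher-is-better outcomes, so
   it always encodes "the dropouts did worse than MI assumes". The
   default grid $\delta \in \{0, 0.2, 0.5, 0.8, 1.1, 1.4\}$ walks from
   the MAR assumption through small, medium and large deviations in the
   familiar effect-size convention.
3. **Analyze and pool.** Each completed dataset is analyzed with the
   ANCOVA above, and the $m$ estimates of $\beta_2$ are combined by
   Rubin's rules (`pool_rubin()`): total variance = mean within-imputation
   variance $+ (1 + 1/m)\times$ between-imputation variance, with the
   Barnard–Rubin degrees-of-freedom adjustment using the complete-data
   df $n - 3$.

Two genuinely open choices were resolved as follows. The offset is
applied to the imputed values of **both arms**: the defining equation of
the method does not condition on arm, and because far more actives are
missing, a common shift still moves the contrast against the active arm
(an arm-specific variant would be easy to add but is not the default).
And all offsets reuse the **same** set of imputation draws: shifting
after imputation is what the procedure prescribes, and reusing draws
removes spurious Monte-Carlo jitter between rows of the sensitivity
table, so the attenuation in $\delta$ is exactly monotone for a
lower-is-better benefit. Re-imputation per $\delta$ is available via
`reuse_draws = FALSE`.

## The fixed-value replacement analysis

MI propagates a large imputation variance when the predictors explain
little, which can make even heavily shifted scenarios look
uncertain rather than bad. The second analysis therefore abandons
distributions altogether. `compute_residualized_change()` regresses the
posttest on the pretest among completers — **without** the group term
this time — and takes the residual as each completer's residualized
change. Missing subjects are then assigned a single fixed residual per
scenario (`replace_missing()`):

* `complete_case` — missing excluded (the MCAR reading);
* `small`, `medium`, `large` — mean residual $+\;0.20, 0.50, 0.80$
  observed residual SDs (sign flipped for higher-is-better outcomes);
* `worst_case` — the worst residual actually observed among completers
  (the maximum for lower-is-better outcomes).

The with/without-group-term asymmetry between the two analyses is
deliberate and worth a warning label: the residual SD without the group
term is larger, so offsets built from it are harsher, and the choice can
flip a borderline significance call. We keep the group term in the
pattern-mixture scale (the more conservative choice there, since an
effective intervention inflates the pooled SD) and drop it from the
residualized-change scale, where the residual is meant to be a
model-free description of change given baseline.

Scenario comparisons use a two-sample rank-sum test
(`rank_sum_test()`). The single-imputation pitfall — treating a fixed
replacement as an observed value inside a parametric test and thereby
deflating the SE — is avoided by testing ranks. Two notes: first,
although this comparison is sometimes loosely called a signed-rank test
in applied reports, the groups are independent, so the correct procedure
is the Mann–Whitney/Wilcoxon *rank-sum* test and that is what is
implemented. Second, the per-group mean rank, SD of ranks and
SE $= SD/\sqrt{n}$ are reported alongside $p$ because that is the
summary practitioners tabulate; applied reports that print such an SE
column rarely define it, and $SD/\sqrt{n}$ is the definition used here.

Ties get midranks, which preserves the total rank sum $N(N+1)/2$ — an
invariant the tests check. The p-value uses the exact rank-sum
distribution (`stats::pwilcox`) when there are no ties and both groups
have at most 50 observations, and the tie-corrected normal
approximation otherwise; with the fixed replacements every missing
subject shares one value, so real scenario tables are tied and use the
corrected approximation. `worst_case` uses the maximum over *completers*
only — a definition over post-replacement values would be circular.

## The differential-attrition meta-analysis engine

Each study contributes a 2×2 table of dropouts by arm.
`compute_log_or()` forms the standard log odds ratio
$y_i = \log\{(d_a/c_a)\,/\,(d_p/c_p)\}$ with variance
$1/d_a + 1/c_a + 1/d_p + 1/c_p$; a zero cell makes this undefined, and
`continuity_correct()` then adds 0.5 to **all four cells of the
offending studies only**. `compute_peto_log_or()` offers the Peto
alternative $(O-E)/V$ with hypergeometric variance, which tolerates a
single zero cell without correction (a study with no dropouts at all
carries no information for either estimator). The Peto estimator is
accurate near OR = 1 and increasingly underestimates large effects —
the property suite asserts both the near-null agreement with the
standard log OR and the far-from-null breakdown.

`pool_random_effects()` pools by inverse variance with weights
$1/(v_i + \tau^2)$. The $\tau^2$ estimator defaults to REML (the default
of the standard R meta-analysis software this engine wraps), with
DerSimonian–Laird behind a flag; CIs and p-values are Wald-type, with no
small-sample (Knapp–Hartung) adjustment — the most widely used
configuration in applied meta-analyses of this kind. Heterogeneity is reported as
$I^2 = 100\,\tau^2/(\tau^2 + \tilde v)$ with a Q-profile CI. Influence
diagnostics are `leave_one_out()` and `detect_outliers()`, the latter
flagging studies whose individual 95% CI is disjoint from the pooled
95% CI. `meta_regress()` adds a fixed moderator slope (log-OR units per
moderator unit) over a random study intercept. A classic fixed-effect
Peto pool (`pool_peto_fixed()`, $\sum(O_i-E_i)/\sum V_i$) is also
exposed: random-effects pooling of per-study Peto effects and the
classic Peto pool are distinct analyses that can differ noticeably when
large studies carry large effects, and having both makes that
difference visible rather than hidden behind one label.

Moderator coding for the packaged table: `used_ml_or_mi` is 1 only for
an explicit "yes" on MI or ML ("unclear" counts as 0);
`detected_diff` is defined only among studies that tested for
differential attrition, so regressions on it automatically run on that
subset.

## The synthetic-data generator

`simulate_trial()` draws `pretest ~ N(0, 1)` and
`posttest = b·pretest + effect·active + N(0, residual_sd)`, with `b`
chosen from the pre/post correlation. The defaults emulate the
illustrative 343-subject meditation-app trial: 228/115 allocation,
z-scaled distress outcome with residual SD 0.65 and pre/post correlation
0.76 (so the marginal outcome SD is ≈ 1), marginal posttest missingness
60.1% vs 41.7%, treatment effect −0.34. Missingness is MCAR, logistic in
the pretest (MAR) or logistic in the to-be-hidden posttest (MNAR); the
logistic intercept is solved numerically (`uniroot`) within each arm's
realized sample so the marginal rates hit their targets exactly in
expectation. Orthogonally, `mnar_shift = c` worsens the latent outcome
of the selected dropouts by `c·residual_sd` before masking — the exact
generative counterpart of the pattern-mixture offset. The pre-masking
outcomes are kept in the `latent_posttest` attribute so validation
studies can compare against the full-data fit.

That correspondence gives the toolkit its headline validation loop:
data generated with MCAR selection plus `mnar_shift = c`, analyzed at
`delta = c`, recover the full-data ANCOVA estimand without bias, while
the MAR analysis (`delta = 0`) overstates the benefit by about
`c · 0.65 · (0.601 − 0.417)` — detectably, once `c` reaches moderate
size. With selection logistic in the posttest the offset model no
longer matches the generative truth exactly, and `delta = c` recovery
is only approximate; the acceptance checks therefore use the MCAR+shift
form, and the monotone-attenuation checks use the logistic MNAR form.
What the generator does *not* emulate: longitudinal (3+ timepoint)
designs, cluster randomization, non-normal outcomes, and covariates
that genuinely predict missingness — so passing tests say nothing about
multilevel MNAR structure in real data.

## Numerical choices, sizes, degenerate inputs

* Validation problem sizes: the monotone-attenuation checks run one
  synthetic trial of n = 2000 with m = 50 imputations; the two
  unbiasedness loops run 200 replicates of the default 343-subject
  configuration with m = 20 each (bias is assessed against 2 Monte-Carlo
  SEs); rank-sum exactness is enumerated for groups of up to 8.
* `pool_random_effects()` with one study returns that study's effect
  with $\tau^2 = 0$; with identical effects, $\tau^2 = I^2 = 0$
  (estimators truncate at zero).
* Imputation requires at least as many completers as model parameters;
  datasets with every posttest missing, empty arms, constant
  moderators, unknown scenario names, or dropout counts exceeding the
  ITT size all raise named errors rather than propagating nonsense.
* All randomness flows through explicit integer seeds; identical
  `(data, m, seed, deltas)` reproduce the sensitivity table to the last
  bit.
* Subjects with a missing pretest are excluded with a warning — both
  analyses condition on the pretest throughout.

## Limitations

The pattern-mixture offset and the fixed-value replacement bracket MNAR
in one direction (dropouts did worse); best-case scenarios can be
explored by reversing the declared outcome direction, but asymmetric
mechanisms (worse for actives, better for controls) are out of scope, as
are selection models, indices of local sensitivity, longitudinal
pattern-mixture models, weighting-based nonignorable imputation, and
publication-bias machinery (trim-and-fill, funnel tests) on the
meta-analytic side. The replacement analysis assigns the same fixed
value in both arms; if dropout means something different per arm, that
assumption — like MAR itself — is untestable from the data.
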