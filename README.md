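# shapecox

Shape-restricted Cox regression for continuous biomarkers, built for the
question of where to place the estrogen-receptor (ER) positivity cutoff in
HER2-negative breast cancer.

## The problem

ER expression is reported as a percentage of stained tumor cells (0–100).
Guidelines dichotomize it at 1% to allocate endocrine therapy, yet patients
with 1% ≤ ER < 10% repeatedly behave like ER-negative patients. Modelling
continuous ER in a standard Cox model forces a linear effect on the log
hazard — an assumption that fails proportional-hazards diagnostics — while
binning it presupposes the cutoffs under investigation.

`shapecox` implements the middle road: a Cox model

```
lambda(t | x, z) = lambda0(t) * exp(beta' z) * r(x),    psi = log r non-increasing,
```

in which the covariates `z` (age, race, grade, stage, lymphovascular
invasion, radiation, pCR) act as usual, and the ER effect `psi(x)` is a
nonparametric step function on the observed ER values, constrained only by
the monotonicity everyone accepts — higher ER never raises the hazard —
and anchored at `psi = 0` for the lowest observed value. The constrained
partial-likelihood maximizer is computed by block coordinate ascent: Newton
steps for `beta` alternate with iterative-convex-minorant steps for `psi`
(a diagonal quadratic approximation projected onto the monotone cone by
weighted pooled-adjacent-violators, with step-halving to guarantee ascent).
Standard errors for `beta` come from a nonparametric bootstrap (200
replicates by default); the clinical cutoff is read off the fitted curve by
two-segment least-squares knee detection.

Around the core estimator the package provides the full analysis pipeline
of the motivating study: Kaplan–Meier curves and log-rank tests by ER
category (cutpoints 1/10/20, lower-inclusive), standard Cox fits with
Grambsch–Therneau PH diagnostics, backward variable selection, categorical
ER models, endocrine-therapy subgroup and interaction models, and a
synthetic cohort generator that emulates the study population (n = 3055,
862 recurrence events, 659 deaths) for fully reproducible testing — the
registry data themselves are not shareable.

## Worked example

```r
library(shapecox)

cohort <- generate_cohort(synthetic_config(seed = 1))
cohort
#> er_cohort: 3055 records ( synthetic(seed=1, n=3055) )
#>   TTR events: 888   OS events: 677
#>   ER quartiles: 0 / 0 / 59.2 / 82 / 100

fit <- bootstrap_inference(cohort, "ttr",
                           z = c("age", "race", "grade", "stage", "lvi",
                                 "radiation", "pcr"),
                           n_boot = 200, seed = 1, round_x = TRUE)
fit
#> Shape-restricted Cox fit ( TTR ): n = 3055 , events = 888
#>   log partial likelihood: -6042.215 (converged in 7 sweeps)
#> Monotone non-increasing log-hazard curve: 100 support points on [ 0 , 100 ]
#>   total drop: 2.009 log-hazard units (HR 0.134 at the top of the range)
#>   covariates (bootstrap inference,  200  replicates):
#>             term   coef    se    hr ci_lower ci_upper        p
#>              age -0.017 0.003 0.983    0.977    0.990 8.85e-07
#>        raceBlack -0.009 0.092 0.991    0.828    1.186 9.22e-01
#>     raceHispanic -0.367 0.094 0.693    0.576    0.834 1.01e-04
#>  raceAsian/other -0.466 0.166 0.627    0.453    0.869 5.07e-03
#>        gradeI/II -0.302 0.075 0.740    0.638    0.857 6.21e-05
#>          stageII -0.779 0.071 0.459    0.399    0.527 3.14e-28
#>              lvi  0.756 0.071 2.130    1.852    2.449 2.83e-26
#>        radiation -0.688 0.076 0.503    0.433    0.583 1.15e-19
#>              pcr -1.568 0.136 0.208    0.160    0.272 5.54e-31

detect_threshold(fit$curve)
#> Threshold estimate ( two_segment ): cutoff = 10 (curve flat beyond the cutoff)

curve_hr(fit, 0, 10)
#> [1] 0.4885027
```

Reading the output: the covariate hazard ratios behave as in any adjusted
Cox model (e.g. pathological complete response multiplies the recurrence
hazard by 0.21), while the ER effect is the whole fitted curve rather than
one coefficient. This synthetic cohort was generated with a true log-hazard
drop of 1.0 spread over ER 0→10% and flat beyond; the fitted curve's knee
is detected at exactly 10, and the fitted hazard ratio between ER = 0 and
ER = 10 (0.49, true value `exp(-1)` ≈ 0.37) recovers the drop up to the
sampling noise of the sparsely populated 1–10% range. The log-rank test by
ER category tells the same story from the categorical side:

```r
log_rank_test(cohort$ttr_time, cohort$ttr_event, assign_er_category(cohort$er))
#> Log-rank test: chi-squared = 64.747 on 3 df, p = 5.68e-14
#>       observed expected
#> <1         350   244.49
#> 1-10        55    54.77
#> 10-20       20    25.19
#> >=20       463   563.55
```

`run_all(analysis_config(...))` executes the entire pipeline (descriptives,
KM/log-rank, standard Cox + PH test, shape-restricted fit + bootstrap,
threshold detection, categorical/subgroup/interaction models) and writes
CSV tables, threshold JSON, figures and a run log to an output directory;
`inst/scripts/run-analysis.R` wraps it for the shell.

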