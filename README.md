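# serialfoe

Serial dependence between form and motion focus-of-expansion percepts:
simulation, trial-history regression, and permutation inference.

## The problem

In visual psychophysics, a *serial dependence* is a bias of the current
trial's perceptual report toward (attractive) or away from (repulsive) a
feature seen on the previous trial. A paradigm for studying it across
feature domains alternates two display types, one judged feature per trial:

* **Form displays** — Glass patterns of dot pairs whose pairwise
  orientations converge on one screen point, the *form focus of expansion*
  (FoE); its horizontal angle is the form orientation.
* **Motion displays** — translational optic flow through a 3D dot cloud;
  all image-motion trajectories emanate from the *motion FoE*, whose
  horizontal angle is the heading / motion direction.

Observers report the perceived horizontal FoE angle after every display.
Because trials strictly alternate (form, motion, form, …), the previous
trial's feature is always from the *other* modality, so the design measures
cross-feature serial dependence: does the previously seen form orientation
pull the current motion-direction percept, and vice versa? Manipulating the
displays' dot density (reliability) and comparing coefficients between
density conditions asks whether that pull behaves like (partial) Bayesian
reliability weighting.

`serialfoe` is for researchers who want this analysis as a tested,
reproducible pipeline: a configurable synthetic observer to generate trial
sequences with known ground truth, the regression and permutation machinery
to analyze them (or real trial logs in the same CSV dialect), and display
generators whose FoE geometry is verifiable to numerical precision.

## The model

For motion trials (equation 1), the perceived motion direction is fitted by
ordinary least squares as

θ̂_FL = b_curr·θcurr_FL + b_pre·θpre_FM + b_next·θnext_FM + ε

where θcurr_FL is the current motion direction and θpre_FM, θnext_FM are
the form orientations of the previous and next trial (all in degrees).
Equation 2 mirrors this for form trials. Interpretation:

* `b_curr` < 1 (CI excluding 1) — center bias: reports compressed toward 0°;
* `b_pre` > 0 and significant — attractive serial dependence; < 0 — repulsive;
* `b_next` — causality control; must be null.

To compare a coefficient between low- and high-density conditions, a
shuffle-and-split permutation test pools both conditions' regression rows,
permutes the response and the previous/next predictor columns, re-splits
the rows into pseudo-conditions of the original sizes, refits both, and
uses the coefficient difference to build a null distribution; the
two-tailed p is the proportion of null differences exceeding the observed
|b_low − b_high|.

## Worked example

Simulate a 17-participant cohort of 1,320-trial sessions (660 per
modality) with a center-biased, serially dependent observer, then fit the
motion-direction equation:

```r
library(serialfoe)

cohort <- simulate_cohort(17, session_config(), observer_params(), seed = 1)
rows   <- build_design_rows(cohort, "motion")
fit    <- fit_serial_model(rows, "eq1_motion")
fit
#> <serial_fit> eq1_motion (perceived motion direction), n = 11203 rows, residual SD = 8 deg
#>          term estimate std_error conf_low conf_high statistic  p_value stars
#>        b_curr  0.78200   0.00287  0.77600   0.78700   272.000 0.00e+00   ***
#>   b_pre_other  0.01680   0.00286  0.01120   0.02240     5.870 4.54e-09   ***
#>  b_next_other  0.00306   0.00286 -0.00254   0.00867     1.070 2.84e-01
#>           eps -0.02410   0.07560 -0.17200   0.12400    -0.318 7.50e-01

interpret_fit(fit)
#> # A tibble: 1 × 4
#>   equation   center_bias serial_dependence next_trial_null
#>   <chr>      <lgl>       <chr>             <lgl>
#> 1 eq1_motion TRUE        attractive        TRUE
```

The generative truth here was `b_curr = 0.78`, `b_pre = 0.0094`,
`b_next = 0`: the fit recovers the compression toward straight ahead
(`b_curr` well below 1, so center bias), an attractive cross-feature pull
of the right order (~0.01–0.02 — a previous form orientation of 40° drags
the perceived motion direction by roughly half a degree), and a null
next-trial control.

A two-condition density experiment end to end, including the permutation
comparison (the `exp2_motion_density` preset varies the motion display's
density, the manipulation under which the serial pull of form on motion
differs between conditions):

```r
plan <- experiment_plan("exp2_motion_density", n_iter = 2000, seed = 7)
res  <- run_experiment(plan, out_dir = "exp2_run")
res$comparison
#> # A tibble: 4 × 7
#>   equation   coefficient  b_low  b_high  obs_diff p_two_tailed significant
#>   <chr>      <chr>        <dbl>   <dbl>     <dbl>        <dbl> <lgl>
#> 1 eq1_motion b_curr      0.650  0.708   -0.0572          0     TRUE
#> 2 eq1_motion b_pre_other 0.0214 0.00476  0.0167          0     TRUE
#> 3 eq2_form   b_curr      0.738  0.725    0.0133          0.001 TRUE
#> 4 eq2_form   b_pre_other 0.0155 0.0157  -0.000261        0.953 FALSE
```

The serial-pull difference is detected exactly where it was generated
(`eq1_motion` / `b_pre_other`, generative 0.024 vs 0.0091), while the form
equation's serial pull (generative 0.016 vs 0.015) shows none — the
asymmetry pattern. A p of 0 means no null difference among the 2,000
shuffles reached the observed one (reported as `< 1/n_iter` by the
printer). `autoplot()` on a fit or a permutation result gives diagnostic
figures; `tidy()` and `glance()` give broom-style tables.

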