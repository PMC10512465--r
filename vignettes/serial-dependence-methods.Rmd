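---
title: "Models and methods: cross-feature serial dependence between form and motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cross-feature serial dependence between form and motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialfoe)
```

## The experimental design being modelled

A session alternates two display types, one judged feature per trial:
Glass-pattern *form* displays whose dot-pair orientations converge on a
form focus of expansion (FoE), and translational optic-flow *motion*
displays whose image trajectories emanate from a motion FoE. The observer
reports the perceived horizontal FoE angle after every display. Sessions
start with a form trial and alternate strictly, so the previous and next
trials of any given trial are always the *other* modality — the design
isolates cross-feature trial history. True FoE angles are drawn uniformly
from a 1° grid on [−45°, 45°]; the default session has 1,320 trials (660
per modality). Stimulus reliability is manipulated through dot density:
high density is 90 dots (45 pairs), low is 28 dots (14 pairs), i.e. 0.01
vs 0.003 dots/deg² over the 112° × 80° field.

## The regression model

For motion trials, the perceived motion direction is modelled as a linear
function of the current motion direction and the form orientations of the
neighbouring trials:

$$\hat\theta_{FL} = b_{curr}\,\theta^{curr}_{FL} + b_{pre}\,\theta^{pre}_{FM}
  + b_{next}\,\theta^{next}_{FM} + \varepsilon ,$$

and symmetrically for form trials. All angles are in degrees; no circular
statistics are used because the range spans only ±45°, far from wrap-around
— the model is deliberately linear, matching how such data are analysed.
The terms carry the scientific content:

* $b_{curr}$ — accuracy of the current-feature read-out. Values below 1
  mean compression toward 0° (center bias). Its deviation from 1, not the
  raw response error, carries the center-bias interpretation; regressing
  on history *jointly* with the current feature avoids misattributing
  center-bias residuals to serial dependence.
* $b_{pre}$ — the serial-dependence coefficient. Positive = attractive
  pull toward the previous other-modality feature.
* $b_{next}$ — a causality control: the future cannot influence the
  present, so a non-null $b_{next}$ flags artefacts in the design matrix.
* $\varepsilon$ — a free intercept (a constant response offset). It is
  estimated, not constrained to zero.

`build_design_rows()` keeps only target-modality trials that have *both*
neighbours; in a 1,320-trial session each equation therefore uses 659 rows
per participant (one boundary trial is lost at each end). Trials ineligible
as responses still serve as neighbours for the other equation.

**Group-level fitting.** All participants' rows are pooled into one OLS
fit, which yields a single coefficient/SE/CI triplet per condition — the
form in which such results are reported. A per-participant fit is possible
(pass one participant's rows) but is a diagnostic, not the pipeline.
Standard errors are plain OLS at $n-4$ residual degrees of freedom;
confidence intervals use the Student-t critical value at that df rather
than 1.96, which matters only for small simulated data sets; p-values are
two-sided t tests. No robust or clustered standard errors are offered:
matching the plain-OLS convention of the reported tables is the contract,
and the generative model is homoscedastic by construction.

## The synthetic observer

`observer_params()` defines the generative inverse of the regression:

$$\theta_{perceived} = b_{curr}\theta_{curr} + b_{pre}\theta_{prev\_other}
  + \varepsilon + \mathcal N(0, \sigma^2),$$

with separate parameter sets for motion-trial and form-trial responses and
*no* dependence on the next trial (causality is built in, so the fitted
$b_{next}$ has truth exactly 0). Choices worth stating:

* **The pull acts on the previous trial's true feature**, not the previous
  percept, because the measurement model regresses on presented features;
  `pull_on_perceived = TRUE` switches to percept-based pull for
  sensitivity analyses, off by default.
* **Noise is additive Gaussian in degrees and homoscedastic across
  angles** — the assumption under which the OLS standard errors are exact.
  The default SD of 8° is a calibration choice: at a 17-participant cohort
  it puts the simulated coefficient SEs near the ~0.004 scale of the
  reported group-level tables. It is not an empirically measured value.
* **Default slopes** are the baseline high-density estimates
  (`b_curr` 0.78/0.77, `b_pre` 0.0094/0.010); ε defaults to 0 since no
  nonzero constant is reported.
* **FoE draws are independent across trials** (uniform on the grid, no
  counterbalancing), and density conditions change only labels and, via
  the experiment presets, the generative slopes — the package does not
  hard-code a density→noise law, because the mapping from reliability to
  slope values is exactly what the experiments measure.

What the generator deliberately does not emulate: motor/probe noise
distinct from perceptual noise, lapse trials, drift or fatigue across the
session, per-participant heterogeneity in slopes, and any dependence
beyond lag 1. Passing tests therefore show that the *analysis machinery*
is correct and calibrated under the stated model — not that real observers
satisfy the model.

## Stimulus geometry

Displays are constructed on a planar screen at 0.2 m viewing distance with
tan-based (gnomonic) angle↔screen conversion, per axis. This convention
makes two properties exact rather than approximate, and both are enforced
as invariants with 1e−9 tolerances:

* **Form collinearity** — every dot pair is laid out along the
  screen-plane direction from its (uniformly sampled) center to the FoE
  point, so the infinite line through each pair passes through the FoE.
* **Flow convergence** — motion dots live in a 3D cloud (depth uniform in
  [0.2, 5] m, image position uniform over the field at frame 1) and are
  translated by `speed * (sin h, 0, cos h) * dt` per 120 Hz frame with
  planar reprojection; under pure translation every frame-to-frame image
  displacement's supporting line passes through the projected heading
  point. `estimate_motion_foe()` recovers the FoE as the least-squares
  intersection of all displacement lines and returns the worst line
  distance as a certificate.

Dots that cross the near depth bound or leave the field are recycled to a
fresh uniform image position and depth; recycled transitions are flagged
and excluded from the flow invariant (a re-entry jump is not a flow
vector). The initial-sampling and recycling rules are implementation
decisions — common optic-flow practice — since only the depth range is
specified by the design; over a 0.5 s display they do not affect the FoE
geometry, which the invariant checks regardless. The vertical FoE
coordinate is fixed at 0 because responses are collected along the
horizontal line. Dot diameter and luminance are metadata only; nothing is
rasterized.

## The permutation test

To compare a coefficient between low- and high-density conditions, the
observed statistic is $b_{low} - b_{high}$ from separate per-condition
fits. The null is generated by shuffle-and-split, 10,000 iterations by
default: pool both conditions' design rows; shuffle; randomly partition
the pooled rows into pseudo-conditions of the original sizes; refit both;
record the difference. The two-tailed p-value is the plain proportion of
null differences at least as large in magnitude as the observed one — no
+1 smoothing, so a p of exactly 0 is displayed as `< 1/n_iter`.
Significance is read at 0.05.

Decisions where the procedure was genuinely open:

* **Shuffle granularity is the design row**, and `x_curr` stays attached
  to its row, so the current-stimulus structure being split is preserved.
* **What exactly gets shuffled is a strategy switch**, because verbal
  descriptions of this procedure ("randomize the response and the
  previous/next features, then split in half") do not pin down the
  coupling. The default, `shuffle = "serial"`, permutes the previous-other
  and next-other predictor columns independently and leaves the response
  attached to its current stimulus. This choice is dictated by
  calibration: the pseudo-fit residual variance then equals the real
  one, so under a shared generative process the null distribution matches
  the sampling distribution of the observed difference and p-values are
  uniform (verified by simulation in the test suite). Permuting the
  response column as well (`"all_columns"`, or `"joint"` for one shared
  permutation) decouples the response from the current stimulus and
  inflates the pseudo-fit residual variance several-fold — with center
  bias ~0.78 and predictors spanning ±45°, the explained variance
  dwarfs the response noise — which widens the null by a factor ~2.5 and
  makes the test severely conservative (near-zero rejection under the
  null *and* under real effects several standard errors large). Those
  variants are retained as options for sensitivity analysis, as is pure
  label permutation (`"none"`), the other calibrated choice.
* **Pooling is across the whole group**, consistent with group-level
  fitting; there is no within-participant shuffling mode.
* **Split sizes follow the original condition sizes**; for the standard
  equal-sized design this is the half/half split.
* Pooled rows are canonically ordered by (participant, trial index)
  before shuffling, so relabelling which condition is "low" exactly
  negates the observed difference and, for equal-sized conditions with the
  same seed, leaves the null sample and p-value identical. With unequal
  sizes the invariance is approximate (the split sizes swap).

No analytic (asymptotic z) test for the coefficient difference is
provided; the permutation scheme *is* the method.

## Experiment presets and what they demonstrate

`experiment_plan()` ships three presets whose generative slopes are set to
the corresponding group-level estimates: `"exp1"` (17 participants,
baseline), `"exp2_form_density"` and `"exp2_motion_density"` (18
participants per condition, varying one display's density). Running the
motion-density preset end to end demonstrates the asymmetry signature out
of the box: the serial pull of form on motion differs between conditions
(generative 0.024 vs 0.0091) and the permutation test detects it, while
the form-equation serial coefficient (generative 0.016 vs 0.015) does not
differ. These are *qualitative* reproductions — simulated observers with
the reported coefficients, not the original human data, which is not
publicly deposited.

## Numerical and testing choices

* OLS is computed by `stats::lm` (QR); the test suite checks it against an
  independent normal-equations solve to 1e−8 on random full-rank designs,
  and checks residual orthogonality to the design columns at machine
  precision. Rank-deficient designs and fewer than 5 rows are refused.
* The permutation loop uses `stats::.lm.fit` on a pre-built pooled design
  matrix for speed; it computes the same OLS coefficients as the
  user-facing fit.
* Calibration is verified by simulation: across 200 replicate null data
  sets (6 participants × 400 trials per condition, 1,000 shuffles) the
  rejection rate at α = 0.05 must land in [0.02, 0.09] and the p-value
  sample must pass a Kolmogorov–Smirnov uniformity check at α = 0.01.
  Power at the full design size (18 × 1,320 per condition) for the
  motion-density serial contrast is high (analytically ≈ 0.95+ given the
  ~0.004 coefficient SEs); the suite requires a majority of 50 replicates
  to reject at 1,000 shuffles. These replicate counts and the reduced
  shuffle count are the package's own verification sizes, chosen to keep
  the checks statistically meaningful.
* Degenerate inputs: zero-residual (noise-free) fits yield NaN p-values,
  which interpretation treats as non-significant; a form-pair center
  falling exactly on the FoE (probability zero on the continuous sampler)
  is given a horizontal orientation.
* Determinism: every stochastic function takes a seed; cohorts and
  multi-stage runs derive independent sub-seeds from one master seed, so a
  plan plus seed reproduces a byte-identical report bundle (timestamps
  live only in the run log).

## Known limitations

* The linear-in-degrees model is only sensible for feature ranges well
  inside ±90°; nothing guards against wrap-around.
* Group-level pooling ignores participant heterogeneity; the SEs are
  valid under the homogeneous generative model but would understate
  uncertainty for heterogeneous real observers (a mixed-effects extension
  is explicitly out of scope).
* The permutation null assumes exchangeability of rows across conditions
  after the column shuffles; strong within-participant autocorrelation
  beyond lag 1 would violate it.
* The observer has no lapse, drift, or probe-noise components, so
  parameter-recovery results bound the machinery's correctness, not the
  realism of any particular data set.
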