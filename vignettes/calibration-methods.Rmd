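---
title: "Calibrating classifier scores to the probability of disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating classifier scores to the probability of disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(probcal)
library(dplyr)
```

## The problem

Statistical classifiers in clinical decision support — CAD scores in
imaging, genomic risk scores, combined clinical predictors — usually emit a
score on an arbitrary scale. The score ranks patients, but "score = 55"
carries no probability meaning, and two devices printing 55 may mean very
different things. `probcal` transforms such scores to the probability-of-disease
scale, with a pointwise 95% confidence interval, using three methods that
share a single assumption and differ in how much structure they impose.

The shared assumption is **rationality**: the score is a monotonically
increasing function of the probability of disease — equivalently, of its own
likelihood ratio $LR(y) = f(y\mid D{=}1)/f(y\mid D{=}0)$. Under rationality,
calibration is a monotone transformation, so it cannot change AUC or any
other rank-based measure of discrimination: there is no
calibration–discrimination trade-off. The often-quoted ceiling of
AUC $= 0.83$ for a perfectly calibrated model (`diamond_uniform_auc()`
returns its exact value, $5/6$) is an artifact of assuming the calibrated
scores are uniformly distributed over the population; `gaussian_world()` and
`perfect_calibration_params()` embody the counter-example, a linear
classifier on multivariate normal biomarkers that is perfectly calibrated at
*any* AUC in $(0.5, 1)$.

## The three calibrators

All three take a data frame with columns `score` and `truth` (0/1) and
return a fit whose `tidy()` is the calibration curve: distinct training
scores with `prob`, `lo95`, `hi95`.

**Parametric** (`cal_parametric()`) fits the sigmoid
$P(D{=}1\mid y) = 1/(1+\exp(Ay+B))$ by maximum likelihood with shrunken
(Platt) targets $1/(N_0+1)$ and $(N_1+1)/(N_1+2)$ rather than 0/1, which
regularizes the fit and keeps perfectly separated data finite. The optimizer
is Newton's method with a backtracking line search on the cross-entropy;
when the objective reaches its floating-point floor before the gradient
tolerance (`tol = 1e-10`, max 100 iterations), a full Newton step is still
accepted if it contracts the gradient. No sign constraint is imposed on $A$:
an anti-rational orientation ($\hat A > 0$) is reported with a warning
rather than hidden. The covariance of $(\hat A,\hat B)$ is the inverse
analytic Hessian, and the standard error of $\hat P(y)$ follows by the delta
method with $\partial P/\partial A = -y P(1-P)$,
$\partial P/\partial B = -P(1-P)$; the 95% interval is Wald on the
probability scale, clipped to $[0,1]$.

**Semi-parametric** (`cal_semiparametric()`) assumes only that the score is
monotonically related to a latent rational decision variable. The latent
model places class 0 at $N(0,1)$ and class 1 at $N(m, s^2)$ and uses
$u(z) = \log LR(z) = z^2/2 - (z-m)^2/(2s^2) - \log s$ as the decision axis,
which guarantees a proper (convex) ROC curve. Scores are reduced to
truth-state-run bins — maximal runs of same-truth subjects after sorting,
with mixed-truth ties forming their own bins — and the per-class bin counts
are a multinomial in $(m, \log s)$ and the $I-1$ latent bin boundaries.
After maximum likelihood, every distinct score receives a *complementary
value* $\tilde u$: within each bin's latent interval, sub-boundaries are
placed so the pooled-mixture mass of each sub-interval matches its empirical
share of the bin, and $\tilde u$ is the median of the pooled mixture on the
score's sub-interval (the arithmetic midpoint is available as
`rule = "midpoint"`; the run-length phrase "median value between $u_{i-1}$
and $u_i$" admits either reading, and the mixture median extends naturally
to the unbounded outer bins, so it is the default). Because the latent axis
*is* the log-likelihood-ratio axis, $LLR(y) = \tilde u$, and Bayes' theorem
converts it to a posterior at an assumed prevalence $\eta$ (default: the
sample prevalence):
$P(D{=}1\mid y) = \eta e^{LLR} / (\eta e^{LLR} + 1 - \eta)$.

**Non-parametric** (`cal_nonparametric()`) solves the isotonic least-squares
problem $\min_z \sum_i (D_i - z(y_i))^2$ over non-decreasing $z$ by the
pool-adjacent-violators algorithm; the unique solution is a step function
whose block values are the observed disease fractions of the pooled blocks.
Tied scores are pre-averaged into one weighted point, since an isotonic
function of the score cannot separate them. The 95% band is a balanced
bootstrap: `B` copies of the subject indices are concatenated, permuted once
under a user-supplied seed, and sliced into `B` resamples, so every subject
appears exactly `B` times overall; each resample is refitted and evaluated
at the original distinct scores, and the pointwise 2.5/97.5 percentiles
(linear interpolation between order statistics) form the band. The band is
widened, where necessary, to contain the point estimate so that the exported
curve satisfies `lo95 <= prob <= hi95`.

## Prediction on new scores and prevalence transport

The parametric calibration function is a formula and is evaluated exactly at
new scores. The semi- and non-parametric functions are defined on the
distinct training scores; `apply_curve()` (used by `predict()`) linearly
interpolates `prob`, `lo95` and `hi95` between the bracketing training
scores and clamps outside the training range — extrapolating a probability
beyond the observed scores has no support under any of the three models.

A calibrated probability is specific to the training prevalence.
`rescale_prevalence()` transports it to another prevalence through the
odds-ratio factor $\kappa$; the map is exact because the likelihood ratio of
a score does not depend on prevalence.

## Uncertainty of the semi-parametric LLR

The standard error of $\tilde u$ is the sum of two delta-method terms:

1. the MLE covariance of $(m, \log s)$ (inverse observed information,
   finite-difference Hessian of the analytic gradient, with eigenvalue
   flooring at $10^{-10}$ when inverting) propagated through the map by
   central finite differences with relative step $10^{-4}$; and
2. the binomial uncertainty of the score's empirical pooled cumulative
   fraction $\hat q$, propagated through the inverse pooled CDF:
   $\hat q(1-\hat q)/N \big/ f_{pooled}(\tilde u)^2$.

The second term stands in for the boundary-parameter covariance. For run
binning of continuous scores most bins hold a single subject, so the Wald
variances of individual boundary parameters are badly approximated and do
not shrink with $n$; contracting them directly overstates the
probability-scale standard error several-fold relative to the Monte-Carlo
variability of the fitted curve (we measured 0.19 versus 0.036 at 100
subjects per class), whereas the quantile form tracks it closely (0.032
versus 0.036 at 100 per class; 0.018 versus 0.018 at 300 per class). The
cross-covariance between $\hat q$ and $(\hat m, \hat s)$ is neglected. The
95% interval is Wald on the LLR scale, $\tilde u \pm 1.96\,se$, transformed
through the posterior formula, which keeps it inside $(0,1)$ without
clipping.

## Fitting engines for the latent model

The multinomial likelihood has $I + 1$ parameters. Up to `joint_limit`
(default 2000) bins, all of them are maximized jointly by L-BFGS in an
unconstrained parameterization ($m$, $\log s$, first boundary, log-gaps),
with the boundary part of the gradient analytic and the $(m, \log s)$ part
by central differences, from a deterministic rank-based initialization —
refitting identical data gives identical results. Beyond that limit (run
binning of, say, $10^5$ subjects per class yields on the order of $10^5$
bins) the package switches to a profile engine: at every objective
evaluation the boundaries are re-anchored at the pooled-mixture $u$-quantiles
of their empirical cumulative fractions and the likelihood is maximized over
$(m, \log s)$ alone. Re-anchoring *inside* the objective matters: with
boundaries frozen at the quantiles of a wrong $(m, s)$, that wrong value is
a self-consistent stationary point. The two engines agree on moderate data
(differences well within sampling noise), and the profile engine recovers
the generating $(m, s)$ of binormal data at $10^5$ subjects per class to
within 0.01–0.02.

## What the simulators emulate

`normal_model()` draws equal-variance binormal scores
($N(0,1)$ versus $N(1.2,1)$, AUC $\Phi(1.2/\sqrt2) \approx 0.80$) — the case
in which the parametric sigmoid is exactly the correct calibration model,
with perfect-calibration parameters $A = -1.2$, $B = 0.72$ at prevalence
0.5. `beta_model()` draws the rational beta pair
$f(y|0) = \beta(1-y)^{\beta-1}$, $f(y|1) = \alpha y^{\alpha-1}$ with
$\alpha = 1.1$, $\beta = 3.5$ (also AUC $\approx 0.80$), for which the
sigmoid is *not* the correct model — this is the misspecification probe.
Both are smooth, unimodal, tie-free score distributions; the generators do
not emulate discrete rating scales, heavy ties, mixture-shaped score
distributions or verification bias, so passing tests speak to those
idealized conditions, not to every real dataset. `true_posterior()` gives
the exact Bayes posterior, which is what makes the mean-squared-error
comparison below possible.

```{r}
m <- normal_model()
c(auc = model_auc(m), brier_inf = theoretical_brier(m))
```

`theoretical_brier()` integrates $P(y)(1-P(y))$ against the pooled density
by adaptive quadrature (absolute tolerance $10^{-7}$); its values for the
two study models, 0.1816 and 0.1771, are the infinite-training reference
lines of the evaluation suite.

## The evaluation suite

`evaluate_once()` draws a training set ($n$ per class, prevalence 0.5 by
design so that the posterior is driven by the likelihood ratio alone), fits
one calibrator, and reports the mean 95% CI width over training subjects
plus the Brier score and the MSE against the true posterior under
*resubstitution* (predict the training set) and *independent* (predict a
fresh equal-sized draw) protocols. `run_experiment()` repeats this over a
grid. Sub-draw seeds are derived deterministically (replicate $r$: data
`seed + r`, bootstrap `seed + 1e6 + r`, test draw `seed + 3e6 + r`), so any
single replicate can be reproduced in isolation.

Default scales are desk scale: 50 replicates and `B = 500` bootstrap
replicates inside experiments, with `B = 2000` the single-fit default.
These sizes reproduce the qualitative structure stably: CI width falls with
$n$ and is substantially larger for the non-parametric method at every $n$;
the non-parametric MSE is the largest of the three at every $n$, and on
binormal data the parametric MSE is the smallest (it is the correct model;
on beta data the parametric bias shows and its advantage disappears); the
resubstitution Brier score sits below the infinite-training reference and
the independent one above it, and the two converge as $n$ grows — while the
MSE is essentially protocol-free, because the true posterior is never used
in training, so nothing ties the fit to it on the training set. With 50
replicates the Monte-Carlo error of the plotted means is a few percent of
the effects, enough for orderings though not for smooth curves.

```{r, eval = FALSE}
ex <- run_experiment(normal_model(), n_grid = c(30, 100, 300),
                     reps = 50, seed = 1)
autoplot(ex)
```

## Numerical choices and degenerate inputs

* Bin probabilities are floored at $10^{-300}$ inside the multinomial
  likelihood so transient boundary configurations stay finite.
* $|s - 1| < 10^{-8}$ switches the latent geometry to the linear-in-$z$
  branch of $u$, avoiding catastrophic cancellation in the quadratic root
  finding; the two branches agree to $10^{-4}$ across the switch.
* Pooled-mixture quantiles are found by 60 bisection steps on a bracket
  containing all but $\sim 10^{-30}$ of the latent mass — far below any
  statistical resolution.
* A fit with $|{\hat m}| < 10^{-5}$ (constant likelihood ratio) is refused
  as "no discrimination signal"; one-class data are refused by every
  calibrator, and single-class bootstrap *resamples* are legal (their
  isotonic fit is constant).
* Mixed-truth score ties: one weighted point for PAVA, an own bin for run
  binning. A score set whose scores are all identical yields one bin and is
  refused (no ordering signal).
* `pava_oracle()` (exhaustive search over ordered partitions) is
  exponential and restricted to $N \le 12$; it exists to certify
  `fit_pava()` in tests.

## Known limitations

* The semi-parametric CI neglects the covariance between the empirical
  quantile anchor and the latent parameters; coverage is approximate,
  though it tracks Monte-Carlo variability closely at the sizes studied.
* Curves are defined on the observed score range only; clamping means a
  far-out-of-range score keeps the last observed probability and its
  interval.
* The Brier score mixes calibration and discrimination; calibration-slope
  or grouped goodness-of-fit summaries are out of scope here.
* Multi-class truth states, streaming input, and smoothing of the isotonic
  step function are not supported.
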