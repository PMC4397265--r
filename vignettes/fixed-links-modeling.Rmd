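---
title: "Fixed-links modeling of repeated-measures task performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-links modeling of repeated-measures task performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixedlinks)
```

## The problem: impurity of experimental performance measures

Performance on a cognitive task is never driven by a single process. A
working-memory task requires storing and manipulating items, but scores also
reflect sensory acuity, alertness, motivation and general processing speed.
When a single latent variable is extracted from several task conditions by
traditional confirmatory factor analysis (CFA), all of this common variance
is bundled into one factor, and correlations between that factor and an
external criterion (here: a fluid-intelligence factor measured by reasoning
composites) can overstate the contribution of the process the task was
designed to manipulate.

Fixed-links modeling addresses this for experimental repeated-measures
designs. When task demand increases systematically across conditions, the
influence of the manipulated process should follow that course, while
task-unspecific processes should contribute equally everywhere. Fixing the
factor loadings to predetermined *courses* lets two (or more) latent
variables coexist over the same five condition scores:

* a **constant latent variable** with unstandardized loadings fixed to
  (1, 1, 1, 1, 1), absorbing condition-independent processes, and
* a **dynamic latent variable** whose fixed loadings follow the hypothesized
  demand course, absorbing the experimentally manipulated process.

Because the loadings are fixed, the latent **variances** are freely
estimated and become the quantities of interest: a latent variable only
reflects a real process when its variance is significantly different from
zero (the `variance_z_test()`).

## Model family and estimation

All models live in the covariance-structure family

$$\Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda^{T} + \Theta$$

with loadings $\Lambda$, directed structural paths $B$ among latents, latent
(co)variances $\Psi$ and diagonal residual variances $\Theta$
(`model_spec()`, `implied_covariance()`). Each entry is either fixed or
free. Identification follows one of two scaling conventions: traditional
CFA fixes a latent variance to 1 and frees the loadings; fixed-links scaling
fixes the loadings and frees the variance. `validate_spec()` checks
identification, acyclicity of $B$, nonnegative degrees of freedom, and — the
pitfall specific to multi-latent fixed-links models — that no two fixed
loading courses over the same indicators are proportional, since
proportional courses make the latents inseparable.

Parameters are estimated by minimizing the normal-theory maximum-likelihood
discrepancy

$$F_{ML} = \ln|\Sigma(\theta)| - \ln|S| + \mathrm{tr}\!\left(S\,\Sigma(\theta)^{-1}\right) - p$$

(`ml_discrepancy()`, `fl_fit()`). The test statistic is $T = (n-1)
F_{\min}$; the multiplier is configurable (`"n"` or `"n-1"`) because the two
conventions differ by less than printing precision at the sample sizes this
design targets, and software packages disagree on it.

### Candidate loading courses

`loading_course()` provides the courses relevant to a five-condition task
whose demands increase monotonically (memory set sizes 2–6):

| course       | series                      | generating rule                  |
|--------------|-----------------------------|----------------------------------|
| constant     | 1, 1, 1, 1, 1               | all conditions weighted equally  |
| linear       | .1, .2, .3, .4, .5          | $k/10$                           |
| quadratic    | .01, .04, .09, .16, .25     | $(k/10)^2$                       |
| logarithmic  | .30, .48, .60, .70, .78     | $\log_{10}(k+1)$                 |
| inverted-u   | .36, .80, .99, .94, .64     | $f(x) = (-x^2+100)/100$ at $x = -8, -4.5, -1, 2.5, 6$ |

The published series for the logarithmic course comes without a generating
rule; we adopt $\log_{10}$ of the memory set size ($k+1$ dots in condition
$k$), which reproduces the printed two-decimal series exactly. This is an
inference, not a documented fact, and is confined to `loading_course()`.
Named courses are stored at two-decimal precision exactly as printed rather
than at full generator precision, so that fits of the bundled matrix
reproduce the published table; `custom` courses are kept unrounded. The
inverted-u course encodes the hypothesis that the hardest conditions exceed
most participants' capacity, so variance (and hence loading) first rises
with demand and then falls.

### Numerical choices

* Optimizer: BFGS on the unconstrained free parameters with symmetric
  finite-difference gradients. The finite-difference step is set to `1e-7`
  (the `optim()` default of `1e-3` caps attainable precision well above
  what metric-invariance properties of the standardized solution require).
  Relative tolerance `1e-10`, at most 5000 evaluations, plus up to three
  warm restarts until successive minima agree within `1e-8`.
* Starting values: free loadings at half the indicator SD, variances at
  half the (mean) observed variance, structural paths at 0. For models with
  at most eight indicators this is robust; non-convergence is reported via
  the `converged` flag, never silently replaced by a best-so-far solution.
* Implied matrices outside the positive-definite cone receive a large
  finite penalty, keeping the line search inside the feasible region
  without hard constraints.
* Negative variance estimates (Heywood cases) are *permitted* and flagged
  (`heywood`), matching common SEM-software behaviour; bounding them at
  zero would hide misspecification.
* Sign indeterminacy of free-loading latents is resolved by making the
  first nonzero loading of each latent nonnegative. Latents with fixed
  courses are orientation-pinned by the course itself.
* Standard errors come from the inverse observed information of
  $T(\theta)/2$; standard errors of standardized coefficients use the delta
  method with numerical gradients.

### Robust scaling

Hit rates are bounded and often non-normal, which inflates the ML
chi-square. `satorra_bentler_scale()` computes the classical scaling factor
$c = \mathrm{tr}(U\Gamma)/df$ from fourth-order sample moments of the raw
data and reports $T/c$. Point estimates are untouched. Under multivariate
normality $c \to 1$; positive excess kurtosis gives $c > 1$. Robust
*standard errors* are deliberately out of scope — only the statistic is
rescaled.

### Fit evaluation and model comparison

`fit_indices()` reports the chi-square p-value, CFI (against the
closed-form independence baseline, `baseline_model()`), RMSEA
$=\sqrt{\max(T-df,0)/(df\,(n-1))}$, SRMR over the $p(p+1)/2$ nonduplicated
standardized residuals, and AIC in the $T - 2\,df$ convention. That AIC
convention is deliberate: for comparisons on the same data it orders models
identically to $-2\ln L + 2q$, and it is the convention that reproduces the
published table values. `compare_models()` implements the joint rule —
model A beats model B only when its AIC is lower *and* its CFI is more than
.01 higher — plus the substantive rejection rule: a fixed-links model whose
dynamic-variance z-test fails is rejected regardless of fit, because its
dynamic latent does not reflect a meaningful process.

### The structural models

`build_wmc_model()` constructs the full family: the congeneric one-factor
model (Model 1), the four constant + dynamic fixed-links models
(Models 2–5), and two structural models in which a Reasoning factor
(measured by figural, numerical and verbal composites) is regressed either
on the traditional WMC factor or on both fixed-links latents. The Reasoning
factor is scaled by fixing its first composite loading to 1 and freeing the
disturbance; standardized solutions are invariant to this choice, and all
reported paths are standardized. `wald_constraint_test()` tests a
hypothesized value for a standardized path either by the delta method or by
a penalized constrained refit.

## What the synthetic-data generator emulates

`population_model()` + `generate_wmc_data()` produce participant-level data
with exactly the structure the analysis assumes: two uncorrelated latents
behind the five hit-rate conditions, and a unit-variance criterion factor —
regressed on both latents — behind three unit-variance composites.
Calibration mirrors the bundled study: latent variances .0120 and .0121,
inverted-u dynamic course, condition means .88/.77/.77/.61 and total SDs
.18/.21/.19/.23 for conditions 1–4, standardized criterion paths .45
(constant) and .48 (dynamic), and composite loadings solved from the target
inter-composite correlations .58/.40/.42 under a one-factor structure.
Residual SDs are derived from the target totals as
$\theta_i = SD_i^2 - \psi_c - g_i^2\psi_d$ (erroring when a target SD
cannot accommodate the latent contribution). The descriptives available for
calibration stop at condition 4; condition 5's mean .55 and SD .24 continue
the observed difficulty trend and are an explicit extrapolation,
overridable in the constructor.

Non-normality is available through a scaled-$t$ error family with $df > 4$,
implemented as an *elliptical* scale mixture: all of an observation's latent
and residual shocks share one $\chi^2_{df}$ mixing draw, so every marginal
is a scaled $t_{df}$ and all second moments match the normal family
exactly. The common mixing draw matters. If instead each shock were an
independent $t$ draw, all excess kurtosis would fall inside the fitted
model's tangent space — each shock's variance (two latent variances, five
residuals) is a free parameter — and the asymptotic Satorra–Bentler
scaling factor would be exactly 1, i.e. the chi-square would not be
inflated at all; this is verifiable from the closed-form fourth-moment
algebra of independent sums. The elliptical mixture places excess kurtosis
in every fourth-moment direction, including the residual directions the
scaling factor integrates over, which is what makes it the right stressor
for the Satorra–Bentler machinery (and the standard design in robust-SEM
simulation work). Hit-rate clipping to
$[0,1]$ is off by default so that moment-level oracles are exact; switching
it on mimics bounded data at the price of deliberate, mild model
misspecification.

What the generator does **not** emulate: trial-level responses, serial
position effects, floor/ceiling shapes beyond optional clipping, and any
dependence between the reasoning residuals and the task residuals. Passing
recovery tests therefore show that the estimator recovers its own model's
parameters under realistic effect sizes — not that real dot-span data
satisfy the model.

`parameter_recovery_study()` wraps the loop: generate, refit the structural
fixed-links model, record estimates, and refit the four dynamic-course
candidates to tally which course wins. The selection rule is "lowest AIC
among the candidates whose dynamic-variance z-test is significant",
mirroring how the rejection rule and parsimony rule combine in the
pipeline; replications where no candidate passes count as "none".
Per-replication seeds are derived from the master seed by a counter, so a
study is reproducible end to end.

## Correlation-matrix input: what is and is not recoverable

The bundled `wmc_study_moments()` is a published correlation matrix at
two-decimal precision. Two consequences, both surfaced by the pipeline as a
warning:

* Unstandardized fixed-links quantities are metric-dependent. Latent
  variances estimated from the correlation matrix live in the standardized
  metric and are *not* comparable to the published covariance-metric values
  (.0120/.0121); standardized outputs are the comparable quantities.
* Printed statistics were computed with robust scaling from raw data whose
  fourth moments are unpublished. Plain-ML statistics on rounded
  correlations track them approximately; z-tests of latent variances are
  attenuated relative to the published raw-data analysis. Quantities that
  *are* desk-reproducible — table arithmetic (AIC, RMSEA), the loading
  courses, and the standardized structural paths — are reproduced at their
  printed precision, and everything else is covered by simulation-based
  properties instead (recovery bias, scaling-factor behaviour, oracle
  equivalence against an independent ML factor-analysis fitter and
  exhaustive grid search).

The split-sample robustness check (`split_sample_robustness()`) refits a
fixed-links model on each leave-one-group-out subsample of a random 4-way
partition as a full refit — variances re-estimated, loadings still fixed —
since fixed loadings are the hypothesis under scrutiny, not an estimate to
freeze.

## Problem sizes used by the test suite

The package's own checks run the recovery study at the study's sample size
(n = 200, 200 replications), probe consistency at n = 100{,}000, verify the
scaling factor's null behaviour at n = 50{,}000, and validate moment
convergence of the generator at n = 200{,}000 — sizes chosen so every
stochastic assertion has comfortable margin while a full check completes on
a laptop in minutes.

## Known limitations

* No mean structures, missing-data (FIML) estimation, categorical-indicator
  estimators, or multi-group models; the model family is exactly the one
  the design needs.
* Robust corrections cover the test statistic, not the standard errors.
* The Wald constraint test treats the constraint on the *standardized*
  path; its delta-method variance is a large-sample approximation, and the
  penalized-refit variant is provided as a cross-check.
* Fit on a correlation matrix treats it as if it were a covariance matrix,
  the standard practice this package deliberately mirrors; exact
  correlation-structure standard errors are out of scope.
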