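---
title: "Stand growth-curve modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand growth-curve modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standgrowth)
```

## The problem

Tree height is expensive to measure in the field; diameter at breast height
(DBH) is cheap. Forest inventory analysis therefore leans on two families of
regressions: height-diameter (H-D) curves that predict height from DBH, and
age-diameter curves that predict DBH from stand age. `standgrowth`
implements the classical workflow around these curves for multi-species
inventory tables: fit a catalogue of candidate curve forms per species, pick
the best, ask whether site covariates (elevation, precipitation, temperature
extremes) improve it, validate everything on a random hold-out partition,
and benchmark against a small neural network. A seeded simulator generates
inventory tables with the statistical structure the workflow assumes, so the
entire pipeline is testable without access to any particular survey file.

## The curve catalogue

Eight basic forms, each a function of one predictor $x$ (DBH or age):

| form | equation | parameters | fitted by |
|---|---|---|---|
| linear | $y = b_0 + b_1 x$ | 2 | OLS |
| logarithmic | $y = b_0 + b_1 \ln x$ | 2 | OLS on $\ln x$ |
| reciprocal | $y = b_0 + b_1/x$ | 2 | OLS on $1/x$ |
| quadratic | $y = b_0 + b_1 x + b_2 x^2$ | 3 | OLS |
| cubic | $y = b_0 + \dots + b_3 x^3$ | 4 | OLS |
| S-curve | $y = e^{b_0 + b_1/x}$ | 2 | OLS of $\ln y$ on $1/x$ |
| growth | $y = e^{b_0 + b_1 x}$ | 2 | OLS of $\ln y$ on $x$ |
| logistic | $y = b_1/(1 + e^{-b_2(x - b_3)})$ | 3 | nonlinear LS |

The S-curve saturates at $e^{b_0}$ when $b_1 < 0$; the logistic has
asymptote $b_1$ and inflection at $x = b_3$ with $y(b_3) = b_1/2$. Each form
has a multivariate extension that appends additive covariate terms where the
curve is linear in its parameters: inside the exponent for S-curve/growth,
inside the denominator for the logistic, directly on the response otherwise.
Setting all covariate coefficients to zero recovers the basic curve exactly
— a reduction identity the test suite checks for all sixteen forms.

## Fitting conventions

**Transform fits.** The S-curve and growth forms are fitted by ordinary
least squares on $\ln y$ — the convention of classical curve-estimation
software, which is what practitioners' published tables come from. The
$R^2$/F/p of such a fit describe the log scale; every fit records its
`fit_scale` so the two scales are never silently mixed. `fit_nls()` can
re-fit any form on the original scale when residuals in measurement units
are wanted.

**Nonlinear backend.** `fit_nls()` minimizes the untransformed residual sum
of squares with a Levenberg-Marquardt trust-region solver (numeric
Jacobian; cost tolerance $10^{-10}$; at most 500 iterations). Starting
values are automatic: linearizable forms start at their transform fit; the
logistic starts at $b_1 = 1.05\max y$, $b_3 = \mathrm{median}(x)$, and $b_2$
from the slope of the logit linearization $\ln(b_1/y - 1)$ on $x$;
multivariate forms start at the basic fit with covariate coefficients at
zero. If the first run does not converge, three seeded, jittered restarts
are tried and the lowest-SSE result kept, flagged `converged = FALSE` if
still unsettled. Parameter points that produce non-finite predictions or a
non-positive logistic denominator (possible in the multivariate logistic,
whose printed form permits singularities) are penalized with a large
residual rather than crashing the solver.

**Reported statistics.** Every fit reports $R^2 = 1 - SSE/SS_{tot}$ and an
F statistic $(R^2/df_1)/((1-R^2)/df_2)$ with $df_1$ = number of
non-constant parameters and $df_2 = n - df_1 - 1$, the same formula for
linear and nonlinear fits so all candidates share one table layout. For the
logistic we use $df_1 = 2$ (the asymptote plays the constant's role);
published tables of this kind are inconsistent on that count, and we chose
one convention and document it rather than replicate the inconsistency.

**Selection.** `select_best()` ranks converged fits by the
degrees-of-freedom-adjusted $R^2$, $1 - (1-R^2)(n-1)/(n-k)$, breaking ties
toward fewer parameters and then catalogue order. Plain $R^2$ is available
(`statistic = "r2"`), but it is monotone under polynomial nesting — the
cubic can never lose to the linear form — so it cannot express the
parsimony that published model-comparison tables of this kind display
(their reported values do decrease from quadratic to cubic on the same
data, which plain $R^2$ cannot do). The adjusted statistic is the weakest
standard penalty that makes a nested truth selectable; heavier criteria
(AIC/BIC) are deliberately out of scope.

Even so, form identification has limits worth stating plainly: at survey
noise levels a cubic approximates a mild exponential or a short logistic
arc to within the noise floor, and fits on different scales (log-scale
transform fits vs original-scale polynomials) are not strictly comparable
when errors are additive. The test suite measures selection-recovery rates
on simulated data and treats them as a property of the conditions, not a
constant of the method.

## Covariate screening and collinearity

`screen_covariates()` computes the Pearson correlation of each covariate
with DBH, one covariate at a time. The default ranking is *signed* —
covariates are ordered by $r$ descending, so strong negative correlations
rank last. That mirrors observed practice in this literature (a screening
that keeps $+0.41$ over $-0.46$ is ranking by signed value, not magnitude);
`rule = "absolute"` gives the principled alternative. Ties break by
catalogue order. The selected covariates (default $k = 3$) pass through a
variance-inflation-factor check, $VIF_j = 1/(1 - R^2_j)$ from regressing
covariate $j$ on the others with intercept, flagged above 5. Exact
collinearity is an error naming the offending covariate.

## Hold-out validation

`split_table()` partitions rows with largest-remainder rounding (sizes
always sum to $n$; deterministic given the seed; optionally stratified by
species so each species keeps the global fractions — surveys are heavily
unbalanced, so the workflow stratifies by default). Validation uses four
indicators with residuals defined as predicted minus measured:
$ME = \overline{\hat y - y}$, $MRE = \overline{(\hat y - y)/y}$,
$RMSE = \sqrt{\sum(\hat y - y)^2 / (n - p)}$ with $p$ the number of
independent variables (1 basic, $1 + k$ multivariate), and
$R^2 = 1 - \sum(\hat y - y)^2/\sum(y - \bar y)^2$ using the hold-out mean.
Hold-out $R^2$ may legitimately be negative and is not clamped; RMSE is
nonnegative by construction. Predictions are always made on the original
measurement scale, whatever scale the curve was fitted on.

## The neural baseline

`train_nn()` is a single-hidden-layer feedforward network: 10 tanh units,
linear output, trained full-batch by Levenberg-Marquardt on the L2-penalized
squared loss (weight decay $0.001$ on connection weights, biases exempt).
The LM damping parameter is initialized at the configured learning rate
(default $0.01$) and adapted by factors of 10. The protocol of "LM with a
learning rate plus explicit weight decay" is an unusual hybrid as commonly
described; initializing the damping from the stated learning rate is our
reading, and a heavily damped LM step is exactly a small gradient step, so
the two readings coincide at the start of training. Features and response
are z-scored with training-split statistics (tanh saturates on raw DBH or
elevation scales). Data split 70/15/15; after every epoch the validation
loss is recorded and the best-validation weight snapshot is retained
(patience 20 epochs, cap 1000). Training is bitwise-deterministic given the
seed. Accuracy is reported per split both as the coefficient of
determination and as the Pearson correlation of predictions with
observations, because reports in this area are ambiguous about which of the
two their $R^2$ columns contain; the test set is the headline.

## The synthetic inventory generator

Each `species_profile()` is a generative truth: stand ages from a truncated
normal (mean/SD/range taken from published per-species inventory moments);
DBH from the species' published optimal age-DBH equation plus additive
Gaussian noise (non-positive draws resampled); height from the published
H-D equation likewise; covariates via a Gaussian copula,
$w = \rho z_{dbh} + \sqrt{1-\rho^2}\,\varepsilon$ scaled affinely into each
covariate's physical range, so the covariate-DBH correlation equals the
target $\rho$ by construction. Five built-in profiles cover a
spruce-dominated mountain conifer, two poplar groups, a riparian sand
jujube, and a heterogeneous mixed broadleaf group; targets
$\rho = (0.52, 0.41, 0.41)$ for elevation, precipitation and the cold
extreme of daily maxima, plus two negatively correlated temperature indices
$(-0.42, -0.46)$ so the signed and absolute screening rules genuinely
differ.

Design notes, in the order we had to decide them:

* The published "SE" columns on inventory means (e.g. 6.58 cm on a mean DBH
  of 20.47 cm at $n \approx 2193$) are treated as sample standard
  deviations — standard errors that large would imply absurd variance.
* Noise SDs default to 15% of the species' mean response, placing the true
  form's modelling-set $R^2$ in the 0.6-0.8 band typical of survey fits;
  they are plain profile fields and fully configurable.
* The mixed broadleaf group carries a two-component $\pm 2.5$ m intercept
  mixture on its height curve, emulating the species heterogeneity that
  makes that group's H-D correlation notoriously weak.
* Covariates are generated *conditionally on DBH* (correlation structure
  only); they do not causally drive growth. The screening and VIF stages
  only assume the correlation structure, so this is sufficient — but it
  means a multivariate fit on default synthetic data has no true covariate
  effect to find.
* One published covariate range is internally inconsistent in its source
  (a cold-extreme index whose printed mean lies outside its printed range);
  the generator uses the range and ignores that mean.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: multiplicative/heteroscedastic measurement
error (real size noise grows with the tree; ours is additive, which is
precisely why log-scale fits win less often on synthetic data than on real
surveys), spatial autocorrelation between neighbouring plots, repeated
measurements, age-height coupling beyond the age to DBH to height chain,
and any causal climate response. Note also that because the generating
curves are log-scale fits from a real survey, they predict conditional
medians, not means: composing the published curve with the published age
distribution yields a mean DBH a few percent below the published sample
mean (the smearing factor), which is visible in the simulator's output and
is a property of the inputs, not a bug in the sampler.

## Numerical choices

Largest-remainder rounding makes partition sizes deterministic and exactly
summing; remainder ties resolve by position. CSV round trips write numerics
with 17 significant digits so equality is exact. The NLS cost tolerance is
$10^{-10}$, restart jitter is 10% multiplicative plus 0.01 additive, and
the non-finite-prediction penalty is $10^6(1 + \max|y|)$. Degenerate
inputs follow the principle "flag, don't crash": a constant response makes
the logistic unidentifiable and is returned flagged; a constant covariate
screens as `NA` and is excluded from ranking; an empty split partition
warns. The zero-gradient return of the LM backend (exact interpolation of
zero-noise data) counts as convergence.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
zero-noise recovery uses $n = 100$ per curve, noisy recovery $n = 500$ at
5% noise, selection-consistency 50 replicates of $n = 400$ per species,
calibration checks $n = 10{,}000$, and the end-to-end script uses
per-species totals (3133/604/136/27/31) whose 70% modelling partitions
match the published per-species modelling sample sizes. These sizes are the
package's chosen study conditions and keep any single check in the seconds
range.

## Limitations

Form identification near the noise floor is intrinsically ambiguous (see
Selection above); screening is marginal Pearson correlation only, with no
stepwise or regularized selection; validation is a single random split, not
cross-validation; there are no confidence or prediction intervals on fitted
curves; and the neural baseline is a fixed small architecture, not a tuned
model. All are deliberate scope boundaries of the workflow this package
implements.
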