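---
title: "Discrete-time survival prediction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete-time survival prediction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtsurv)
```

## The model and its assumptions

`dtsurv` predicts subject-specific survival probabilities from
right-censored baseline data $(\tilde T_i, \delta_i, X_i)$, where
$\tilde T_i = \min(T_i, C_i)$ and $\delta_i = I(T_i \le C_i)$. Follow-up
on $(0, w]$ is divided into $J$ intervals $A_j = (t_{j-1}, t_j]$ and the
target of estimation is the discrete-time hazard
$$\lambda_j(x) = \Pr(T \in A_j \mid T > t_{j-1}, X = x),$$
a conditional probability (not a rate), from which the survival curve is
composed as $S(t \mid x) = \prod_{j: t_j \le t} (1 - \lambda_j(x))$.

Two assumptions are inherited from the framework:

* **noninformative censoring given covariates** — $T_i \perp C_i \mid
  X_i$. Both the likelihood factorization behind the person-period
  expansion and the IPCW metric estimators rely on it.
* **time-fixed baseline covariates** — every person-period row carries a
  copy of the subject's baseline $X_i$. Time-varying covariates, left
  truncation and competing risks are out of scope.

Expanding each subject into one row per interval at risk, with the
event-history indicator $d_{ij}$ that is 1 only in the event interval,
makes the discrete survival likelihood identical to a binomial likelihood
over rows. Nothing about that identity requires a linear model, which is
why any binary classifier can stand in for the hazard: link-based GLMs
give the continuation-ratio (logit) and grouped proportional-hazards
(cloglog) models, while the classifier contract admits forests, trees,
boosting, and so on. The cloglog model is exactly compatible with
continuous-time proportional hazards at *any* grid: if
$S(t|x) = S_0(t)^{\exp(\beta x)}$ then
$\operatorname{cloglog}\lambda_j(x) = \operatorname{cloglog}\lambda_{0j}
+ \beta x$, so its coefficient estimates the continuous-time log hazard
ratio. The test suite verifies this recovery at $n = 2000$, $J = 25$.

## The interval grid

Cut points are placed at the $1/J, \dots, (J-1)/J$ quantiles of the
*observed event times within the horizon*, with $t_0 = 0$ and $t_J = w$
forced, so each interval holds roughly the same number of failures and
every interval intercept is estimable. Two conventions are fixed
deliberately:

* **Quantile definition.** `stats::quantile(type = 4)` — linear
  interpolation of the empirical CDF. With event times $1,\dots,5$,
  horizon 5 and $J = 5$ this reproduces the unit grid $0,1,\dots,5$
  exactly, which the central-tendency interpolating types do not; exact
  order-statistic behaviour at small $n$ matters more here than
  smoothness, because the grid must place whole events into intervals.
* **Interval convention.** Left-open right-closed, $(t_{j-1}, t_j]$: an
  event at exactly $t_j$ belongs to $A_j$, and a subject censored at
  exactly $t_j$ has survived interval $j$ in full under every censoring
  specification.

Heavily tied event times can make requested quantiles coincide; duplicate
cut points are collapsed with a warning rather than an error (erroring
would make large $J$ unusable on tied data), and the realized $J$ is
reported in the grid object. Event times of exactly 0 are rejected at
load, since no left-open interval can contain them.

Administrative censoring at the horizon is applied before expansion:
subjects with follow-up beyond $w$ become event-free at $w$. This bounds
the person-period table and makes the horizon the explicit limit of
prediction — `predict()` refuses extrapolation beyond it.

## Censored subjects: three expansion rules

Event subjects always contribute rows $1,\dots,j_i$ with a terminal 1.
For censored subjects three rules are offered for which intervals count
as survived:

| rule | interval $j$ is included when | typical use |
|---|---|---|
| `observed` | $\tilde T > t_{j-1}$ (at risk at interval start) | default |
| `half` | $\tilde T \ge (t_{j-1}+t_j)/2$ | guards against downward hazard bias under heavy censoring |
| `full` | $\tilde T \ge t_j$ | mimics panel collection, where a dropout was last seen at $t_{j-1}$ |

The `observed` rule credits a censored subject with surviving an interval
they only partially entered, which biases hazards downward when intervals
are long or censoring heavy; `half` and `full` trade that bias against
discarding information. The rules affect censored subjects only; the
package keeps event subjects' contributions identical under all three.
(Whether an event in the first half of an interval should also be
reassigned under the stricter rules is not determined by the framework;
we treat events identically everywhere and regard this as the natural
reading, since the event interval is observed exactly.) A censored
subject whose rule yields zero intervals — e.g. censored at time 0 —
contributes no rows; such subjects are counted in the table's `dropped`
attribute rather than silently vanishing or erroring.

## Classifier engines

Engines see a numeric feature matrix: the encoded interval identifier
plus the covariates standardized by training means and standard
deviations. Two choices deserve comment:

* **Standardization constants are computed over subjects, not
  person-period rows.** Covariates are time-fixed, so row-level means
  would weight each subject by their follow-up length.
* **Interval encoding** defaults to one-hot (a factor identifying the
  interval, faithful to the saturated-in-time intercepts of the link
  models); an `ordinal` integer encoding is available and usually
  preferable for trees, which can then split follow-up time at
  data-driven points.

Link models are fit on the raw covariate scale so that coefficients stay
interpretable. No sample weights are used anywhere: each person-period
row counts once, which is exactly the binomial likelihood. Engine fits
are seeded through the contract and must be reproducible; `dtsurv()`
checks predicted probabilities and rejects contract violations.

Numerical safeguards: hazards are clipped to $[10^{-6}, 1-10^{-6}]$
before survival composition (a single overconfident classification would
otherwise collapse $S$ to 0 for all later times) and to
$[10^{-12}, 1-10^{-12}]$ inside the log-likelihood, with a warning when
clipping actually occurs. The log link requires valid starting values
(all $\eta < 0$); the fitter supplies them from the marginal failure
rate. An interval with no at-risk rows makes its intercept inestimable
and raises an error suggesting a smaller $J$.

## Censoring-adjusted metrics

All metrics consume only a matrix of predicted event probabilities
$p_i(t) = 1 - S_i(t)$, so discrete-time, continuous-time and external
models are scored identically. Censoring is handled by inverse
probability of censoring weighting with
$\hat G(u) = \Pr(C > u)$ estimated by Kaplan–Meier with the event and
censoring roles exchanged:

$$\hat W_i(t) = \frac{I(\tilde T_i > t)}{\hat G(t)} +
\frac{I(\tilde T_i \le t)\,\delta_i}{\hat G(\tilde T_i-)},$$

with $\tilde D_i(t) = I(\tilde T_i \le t, \delta_i = 1)$. Conventions we
fixed where the literature prints variants:

* $\hat G$ is evaluated at the **left limit** $\tilde T_i-$ for event
  subjects, the standard convention that keeps a subject's own censoring
  mass out of its weight when censoring and event times tie.
* The Brier estimator is normalized by $1/n$ with the weights as defined:
  $\widehat{BS}(t) = n^{-1}\sum_i \hat W_i(t)(\tilde D_i(t) - p_i(t))^2$.
  Without censoring it reduces exactly to the mean squared error, and the
  weighted case/control mass is consistent for $n$ (both tested).
* Tied predictions contribute **zero** to the AUC double sum (the strict
  inequality); a half-credit option exists but is off by default.
* $\hat G$ is estimated on the evaluation split by default; a
  training-split estimate can be passed explicitly.
* Evaluation at times where a positive weight would require
  $\hat G = 0$, or where there are no weighted cases or controls, fails
  loudly instead of returning 0.5 or an extrapolation.

$R^2(t) = 1 - BS(t)/BS_0(t)$ scales against the null model that assigns
every subject the marginal Kaplan–Meier event probability — by
construction the null predictor scores exactly 0 at every time. The
integrated Brier score uses the weight $W(t) = t/t^*$, i.e.
$(1/t^*)\int_0^{t^*} BS(s)\,ds$, computed by the trapezoidal rule with
constant extension beyond the first and last evaluated times; the
trapezoid is exact for the piecewise-linear curves the scorer produces
and agrees with fine Riemann refinement to $10^{-3}$ in the tests.

## Splitting, tuning and benchmarking

Splits are subject-level and stratified by event status (on by default),
using largest-remainder apportionment with a repair pass so that split
sizes are exact — a 60/20/20 holdout of 100 subjects is exactly
60/20/20, and 5 folds of 100 subjects are exactly 20 each — while strata
stay balanced to within one subject.

The number of intervals $J$ is a hyperparameter: the tuner rebuilds the
grid from the training events for every candidate $J$ and scores each
configuration (classifier hyperparameters $\times$ $J$) on the
validation split by the time-dependent Brier score at a single time, or
the integrated Brier score over several. The default candidate ceiling
is $J = 25$: beyond that the person-period table grows linearly while
per-interval event counts shrink, and prediction accuracy has saturated
in every setting we simulate. Grid search is the default (exactly
reproducible and monotone in the search space); random search with a
budget is available.

Under holdout, the tuned model is **refit on the training split only**,
keeping the validation objective an honest estimate; `refit =
"train_val"` refits on both, which uses more data but makes the recorded
objective optimistic. Under K-fold cross-validation each fold is held
out in turn, tuning uses an inner 75/25 split of the remaining folds,
the tuned configuration is refit on all remaining folds, and reported
metrics are arithmetic means across folds (audited against the per-fold
log in the tests). All randomness flows from a single root seed expanded
deterministically per component; two runs of `benchmark_dtsurv()` with
the same seed serialize byte-identically via `report_json()`. Wall-clock
timings are kept as a volatile attribute outside the canonical
serialization.

## The simulator and what passing tests mean

`simulate_survival()` generates the study conditions for every oracle
test: proportional-hazards event times (exponential, Weibull,
piecewise-constant baseline, or a natively discrete sequential-Bernoulli
generator), independent standard-normal covariates (optionally Bernoulli
factors), an optional threshold effect $\mathrm{effect}\cdot I(x > c)$
that a linear-in-$x$ model cannot represent, and independent censoring
(exponential, uniform or administrative) calibrated by root finding so
the expected censoring proportion given the realized event times hits
the target — realized rates land within $\pm 0.02$ at $n = 5000$,
covering the 30–86% censoring range typical of clinical survival data.
The object retains the latent uncensored times and the closed-form
$S(t|x)$, enabling the IPCW-consistency and parameter-recovery checks.

What the generator does **not** emulate: correlated or high-dimensional
covariates, non-proportional or time-varying effects, informative
censoring, measurement ties, and the covariate distributions of real
registries. Passing tests therefore demonstrate correctness of the
machinery (expansion, likelihood, composition, weighting, tuning
plumbing) and statistical behaviour under the stated generating models —
not relative performance claims on any particular clinical data set.

Problem sizes used in the checks are chosen to keep Monte-Carlo error
well below the asserted tolerances while running in seconds: $n = 2000$
with $J = 25$ over 10 seeds for coefficient recovery (mean absolute
error below 0.1), $n = 5000$ at 30% censoring for IPCW consistency of
the Brier score (within 0.01 of the uncensored oracle), $n = 1000$ for
chance-level AUC ($\pm 0.03$), and $n = 500$ with 5-fold
cross-validation for end-to-end determinism.

## Known limitations

* Hazards are modeled from the interval label only; numeric interval
  endpoints are not offered as classifier features. With the ordinal
  encoding trees recover most of that flexibility; smooth baseline
  hazards (splines in $j$) are a possible extension.
* Survival beyond the horizon is deliberately unpredictable
  (`predict()` errors), and metrics beyond the censoring support error
  rather than extrapolate.
* Confidence intervals for the metrics, calibration curves, competing
  risks, left truncation and missing-covariate imputation are out of
  scope; data with missing values are rejected at load.
* Large $J$ on small data concentrates few events per interval; the
  saturated intercepts then carry high variance, which is why tuning
  over $J$ with a modest ceiling is the recommended workflow rather
  than fixing a fine grid a priori.
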