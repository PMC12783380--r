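---
title: "IPCW classification and the adjusted jackknife: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IPCW classification and the adjusted jackknife: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcwjack)
```

## The model

For subjects $i = 1 \dots n$ we observe $(x_i, t_i, \delta_i)$: covariates, a
positive follow-up time $t_i = \min(t^*_i, c_i)$, and the event indicator
$\delta_i = I(t^*_i \le c_i)$, where $t^*$ is the latent event time and $c$
the latent censoring time, assumed conditionally independent given $x$. The
target of inference is the survival probability at a fixed horizon $\tau$,
$p_x = P(T^* \ge \tau \mid X = x)$, approached as a *classification* problem
on the dichotomized outcome $Y = I(T^* \ge \tau)$.

`dichotomize_at()` assigns $y_i = 1$ when $t_i \ge \tau$ (a subject censored
at or after $\tau$ is still known to have survived it; the boundary $t = \tau$
counts as surviving, matching the closed lower bound in $I(T^* \ge \tau)$),
$y_i = 0$ when an event occurred before $\tau$, and `NA` when censoring
precedes both — the subject's survival status at $\tau$ is genuinely unknown.

Discarding the unknowns would bias any classifier, because being uncensored
up to $\tau$ is informative about $T^*$. Instead, each record receives an
inverse-probability-of-censoring (IPC) weight,
$\tilde w_i = 1/\hat G(\tau)$ if $t_i \ge \tau$,
$\tilde w_i = 1/\hat G(t_i)$ for events before $\tau$, and $0$ for unknowns,
with $\hat G(u) = \hat P(C > u)$, followed by normalization
$w_i = \tilde w_i / \sum_k \tilde w_k$. A classifier minimizing the weighted
binary log loss $-\sum_i w_i (y_i \ln p_i + (1 - y_i)\ln(1 - p_i))$ then has
the true conditional survival probability as its population minimizer, so its
predictions are asymptotically unbiased.

### Estimating the censoring curve

$\hat G$ is the reverse Kaplan–Meier estimator: the product-limit estimate
with the roles of event and censoring swapped (`reverse_km()`, delegating to
`survival::survfit` on the flipped status). Two conventions matter and are
fixed here:

* **Evaluation is right-continuous**: the weight of an event at $t_i$ uses
  $\hat G(t_i) = \hat P(C > t_i)$ *including* any censoring jump at $t_i$.
* **Ties**: at a tied event/censoring time, events remain in the risk set for
  the censoring jump. Together these reproduce the closed-form weights of the
  tractable two-point model below exactly.

The curve is marginal (covariate-free). Covariate-conditional censoring
models $P(C > u \mid X = x)$ are a documented limitation: the weighting
formula would accept them, but no conditional estimator is implemented.

A useful consequence of the tie convention: an *estimated* $\hat G$ is always
strictly positive at every time where a weight needs it, because the record
being weighted is itself in every risk set up to that time. A user-supplied
curve that hits zero before $\tau$ raises an error rather than silently
capping the weight — the weights are simply undefined there.

## The adjusted jackknife

Prediction uncertainty is estimated non-parametrically from leave-one-out
refits. In the unweighted infinitesimal jackknife, the influence component of
observation $i$ is approximated by $(n-1)(\hat p - \hat p_{-i})$ and each
observation carries mass $1/n$. Under IPC weighting the empirical distribution
puts mass $w_i$ on record $i$ instead, and the influence approximation becomes
$(1/w_i - 1)(\hat p - \hat p_{-i})$ — an association that is exact for the
weighted mean and motivates the general estimator. Substituting both
adjustments gives

$$\widehat{\mathrm{Var}}(\hat p) = \sum_{i=1}^n (1 - w_i)\,
(\hat p - \hat p_{-i})^2,$$

implemented in `jackknife_se()`. The leave-one-out prediction $\hat p_{-i}$
refits the classifier with record $i$ removed and the remaining weights
renormalized by $1/(1 - w_i)$ (`loo_weights()`). Three deliberate choices:

* **Weights are fixed during jackknifing.** $\hat G$ is not re-estimated per
  leave-one-out sample. This follows the known-censoring-function
  simplification under which the estimator is derived, and it is what makes
  the weighted-mean identity below exact; re-estimating would break it.
* **Zero-weight records are skipped.** Removing a record the fit never saw
  cannot change the prediction, so $\hat p_{-i} = \hat p$ exactly and the
  term contributes 0 — verified, not assumed, by a test that deletes such a
  record and compares.
* **Warm starts.** Each weighted-logit refit starts from the full-sample
  coefficients; with the IRLS tolerance unchanged this cuts the sweep's cost
  roughly an order of magnitude without changing results beyond 1e-8-level
  convergence noise. All query patterns share one leave-one-out sweep.

A record with $w_i \ge 1 - 10^{-12}$ is an error (the renormalization
$1/(1-w_i)$ degenerates); it cannot occur once two records have positive
weight.

### The tractable example

With event times on $\{0.75, 1.25\}$ and censoring times on $\{0.5, 2\}$
(`two_point_sample()`), horizon $\tau = 1$: the $n - m$ records censored at
0.5 get weight 0 and the other $m$ records all get normalized weight $1/m$,
because $\hat G$ has its single jump at 0.5 with value $m/n$. For the
IPC-weighted mean $\hat p = \frac1m \sum y_i$ the adjusted jackknife then
collapses *algebraically* to the unbiased sample variance of a mean of $m$
i.i.d. observations,
$\frac{1}{m}\frac{1}{m-1}\sum_{i=1}^m (y_i - \hat p)^2$, and Greenwood's
single-jump variance $d(m-d)/m^3$ equals $\frac{m-1}{m}$ times it
(`greenwood_variance()`). Both identities are asserted to $10^{-12}$ in the
test suite on every simulated draw tried, and the unadjusted jackknife
$\frac{n-1}{n}\sum_i(\hat p - \hat p_{-i})^2$ differs by the factor
$\frac{m}{m-1}\frac{n-1}{n}$ exactly.

## Classifiers

* **Weighted mean** — no covariates; the baseline for which everything is
  closed-form.
* **Weighted logistic GLM** (`fit_weighted_logit()`) — IRLS (Newton with
  step-halving), relative coefficient-change tolerance $10^{-8}$, cap 100
  iterations, warm starts accepted. The linear predictor carries a fixed
  offset, by convention $-\ln\tau$, so that under a shape-1 log-logistic
  event-time model the fitted coefficients estimate the generating
  coefficients directly; fitting with offset 0 shifts only the intercept by
  $\ln\tau$ and leaves predictions unchanged (tested to $10^{-10}$).
  Separation or non-convergence is flagged, never silent; an aliased (e.g.
  all-zero) covariate column is resolved by a pseudo-inverse step, leaving
  its coefficient at zero.
* **Plugin adapter** (`classifier_spec(kind = "plugin")`) — any learner that
  accepts per-record non-negative weights and a seed. The contract is
  behavioural: doubling a record's raw weight must equal duplicating the
  record before normalization. The test suite runs this canary against
  `xgboost` with a weighted binary log loss, and against a deliberately
  weight-blind plugin, which fails it.
* **Log-logistic AFT comparator** (`fit_loglogistic_aft()`) — fitted by
  censored maximum likelihood via `survival::survreg`; uses the full
  $(t, \delta)$ information and needs no weights. Predictions
  $S(\tau\mid x) = (1 + (\tau/e^{b'(1,x)})^{a})^{-1}$ with shape
  $a = 1/\sigma$.

**Model-based standard errors** for the GLM and AFT use the delta method on
the coefficient covariance. For the AFT this is the usual inverse observed
information over $(b, \log\sigma)$. For the weighted GLM the covariance is
the inverse *weighted* observed information on the raw-weight scale — a
naive choice that ignores both the variability of the weights and the
estimation of $\hat G$. Under light censoring it tracks the sampling SD
well; under heavy censoring it visibly undershoots (the simulation's
empirical SDs rise with the censoring rate while this SE barely moves).
Influence-function-corrected covariances for IPCW-GLMs exist in the
literature but are out of scope here; the adjusted jackknife is the
recommended uncertainty estimate for the weighted classifiers, and the
package's coverage checks use it.

**Loss evaluation** clips probabilities to $[10^{-10}, 1 - 10^{-10}]$;
fitted predictions themselves are never clipped. `logit_ci()` clips a
degenerate $\hat p \in \{0, 1\}$ the same way, with a warning, so an extreme
but valid prediction still yields a usable interval; the Wald interval is
left unclipped on purpose to exhibit its out-of-range defect.

## The simulation harness

`scenario_config()` + `run_simulation()` + `summarize_ademp()` implement an
ADEMP-style study. The generating process the defaults encode: two
independent balanced binary covariates $x_1 \in \{-1, 1\}$,
$x_2 \in \{0, 1\}$; event times log-logistic with shape $a = 1$ and scale
$\exp(b_0 + b_1 x_1 + b_2 x_2)$, $b = (1, -0.5, 0.5)$ (drawn with
`flexsurv::rllogis`); censoring exponential with rate $\lambda$; horizon
$\tau = 5$. Rates $0.017$, $0.10$ and $0.27$ calibrate to on average 5%, 25%
and 50% of records receiving weight zero. The closed-form truths are
$p_{11} = e/(e+5) = 0.352$ and $p_{10} = 0.248$ (3 dp). This design has a
useful property: the dichotomized outcome exactly follows a logistic model
with offset $-\ln\tau$ *and* the event times exactly follow a parametric
survival model, so neither analysis method is handicapped by
misspecification.

What the generator deliberately does **not** emulate: non-linear or
non-additive covariate effects, more than two predictors, covariate-dependent
censoring, ties in observed times. Passing tests therefore demonstrate
correctness of the estimators under a clean, well-specified design — not
robustness to misspecification on real data.

Measures per (method, query pattern): replicate-mean prediction, empirical
SD (denominator $n_{\text{converged}} - 1$; undefined — reported `NA`, never
0 — with fewer than two converged replicates), mean adjusted-jackknife and
model-based SEs, empirical coverage of the 95% logit-scale CI against the
closed-form truth, and the mean IPC-weighted Brier score. Non-converged
replicates are excluded per measure with their count reported; coverage
denominators use converged replicates only.

**Brier normalization.** The score is implemented as
$\sum_i w_i (\hat p_i - y_i)^2$ with *normalized* weights. A literal
"$\frac1n\sum_i w_i(\cdot)^2$" with normalized weights would scale like
$1/n$; with *raw* weights the two forms coincide (the normalizing constant is
$\sum_k \tilde w_k \approx n$), and the implemented form is the one that
matches the reference values near $0.226$ — the large-$n$ limit is
$E[p(1-p)]$ averaged over the four covariate patterns, $\approx 0.2261$.

**Seeding.** The master seed draws one substream seed per replicate
(recorded in the output), so runs are bitwise reproducible and individual
replicates can be re-run in isolation.

**Problem sizes.** The package's reduced reproduction (tests and
`scripts/acceptance.R`) uses 500 replicates per cell at $n \in \{200,
1000\}$ with the 25% zero-weight rate; 500 replicates put the Monte-Carlo SE
of a mean prediction near $0.0014$ and of a coverage estimate near $0.009$,
small enough to separate correct behaviour from the failure modes the
estimators are tested for. The jackknife-bearing cell runs at $n = 200$,
where one replicate costs about 150 warm-started leave-one-out refits.

## Known limitations

* Marginal (covariate-free) censoring weights only.
* The weighted-GLM model-based SE is the naive weighted information (see
  above); use the adjusted jackknife for the weighted classifiers.
* No competing risks, time-dependent covariates, or interval censoring.
* Gradient boosting is supported only through the plugin contract; no tuned
  boosting configuration ships with the package, and boosting results are
  validated behaviourally (weight/duplication equivalence), not against
  reference values.
* Bagging with IPC-weighted bootstrap and a jackknife-after-bootstrap SE are
  natural extensions, not implemented.
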