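# ipcwjack

Prediction uncertainty for binary classifiers applied to right-censored
survival data.

## The problem

Clinical prediction models often need the probability that a patient survives
a fixed horizon τ (say, 5 years). Machine-learning classifiers can estimate
this by dichotomizing the event time into Y = I(T\* ≥ τ) — but under
right-censoring Y is unknown for subjects censored before both τ and their
event. Inverse-probability-of-censoring weighting (IPCW) fixes the resulting
bias: those subjects get weight 0, and every other subject i is up-weighted by

```
w̃_i = 1 / Ĝ(τ)    if t_i ≥ τ
w̃_i = 1 / Ĝ(t_i)  if the event occurred at t_i < τ
w̃_i = 0           if censored before both τ and the event
```

where Ĝ(u) = P̂(C > u) is the reverse Kaplan–Meier estimate of the censoring
survival function, and the weights are then normalized to sum to one. Any
classifier minimizing the IPC-weighted binary log loss yields asymptotically
unbiased predictions of P(T\* ≥ τ | X = x).

What has been missing is the **uncertainty** of such predictions. This package
implements an IPCW-adjusted infinitesimal jackknife estimator of the standard
error of a prediction p̂:

```
Var(p̂) = Σ_i (1 − w_i) (p̂ − p̂_{−i})²
```

where p̂\_{−i} is the prediction refitted after removing record i and
renormalizing the remaining weights by 1/(1 − w_i), with the censoring curve
held fixed. It is non-parametric, so it applies equally to a weighted mean, a
weighted logistic regression, or any machine-learning classifier that honours
per-record weights. For the IPC-weighted mean it reduces *exactly* to the
unbiased sample variance of the mean over the m records with non-zero weight,
and Greenwood's variance for the Kaplan–Meier estimator equals (m−1)/m times
it. Confidence intervals are formed on the logit scale,

```
logit(p̂) ± z_{α/2} · SE(p̂) / (p̂ (1 − p̂)),
```

back-transformed so they stay inside [0, 1].

The package also provides a log-logistic accelerated-failure-time comparator
(fitted on the full event-time information via `survival::survreg`), a
pluggable adapter for boosting-style learners, an IPC-weighted Brier score,
and an ADEMP-style simulation harness.

## Worked example

```r
library(ipcwjack)

# a synthetic cohort: log-logistic event times (shape 1,
# scale exp(1 - 0.5*x1 + 0.5*x2)), exponential censoring at rate 0.10
cfg <- scenario_config(n = 400, nsim = 1, seed = 2026, lambda_cens = 0.10)
d <- simulate_dataset(cfg, 2026)

analyze_survival(d, tau = 5, method = "ipcw_glm",
                 se_method = "adjusted_jackknife",
                 query = rbind(c(1, 1), c(1, 0)))
#>   x1 x2 p_hat     se ci_low ci_high          se_method   n n_zero_weight pct_zero_weight
#> 1  1  1 0.409 0.0506  0.315   0.511 adjusted_jackknife 400           100              25
#> 2  1  0 0.244 0.0446  0.168   0.342 adjusted_jackknife 400           100              25
```

Reading the output: 100 of 400 subjects (25%) were censored before both the
5-unit horizon and their event and so received IPC weight zero. For a subject
with covariates (x1, x2) = (1, 1), the IPC-weighted logistic model predicts a
5-unit survival probability of 0.409 with an adjusted-jackknife standard error
of 0.051 and 95% logit-scale confidence interval (0.315, 0.511); the true
value in this generating model is 0.352. Swapping
`se_method = "model_based"` gives the delta-method standard error from the
weighted-GLM information matrix instead; `method = "aft"` fits the parametric
survival comparator.

A thin command-line front-end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ipcwjack.R", package = "ipcwjack"))')" \
    analyze --input cohort.csv --tau 5 --method ipcw_glm --se adjusted_jackknife
```

Input CSVs need `time` and `status` columns; every other column is a numeric
covariate.

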