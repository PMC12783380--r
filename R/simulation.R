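# ADEMP simulation harness: log-logistic event times with two Bernoulli
# covariates, exponential censoring, the three analysis methods (parametric
# AFT, IPC-weighted logistic GLM, optional plugin classifier), and summary
# measures (bias, empirical SD, mean model/jackknife SEs, coverage of the
# logit-scale CI, IPC-weighted Brier score).

#' Simulation scenario configuration
#'
#' Describes one cell of the simulation study: event times are log-logistic
#' with shape `shape` and scale `exp(b[1] + b[2] x1 + b[3] x2)`, covariates
#' `x1` uniform on `{-1, 1}` and `x2` uniform on `{0, 1}`, censoring times
#' exponential with rate `lambda_cens` (0 = no censoring), dichotomization and
#' weighting at horizon `tau`. Rates 0.017, 0.10 and 0.27 give on average 5%,
#' 25% and 50% of records with IPC weight zero at `tau = 5` under the default
#' coefficients `b = (1, -0.5, 0.5)`.
#'
#' @param n sample size per replicate (`>= 10`).
#' @param nsim number of replicates (`>= 1`).
#' @param seed master seed; spawns one substream seed per replicate.
#' @param b length-3 coefficient vector `(b0, b1, b2)` on the log-scale
#'   location.
#' @param shape log-logistic shape `a > 0`.
#' @param lambda_cens exponential censoring rate (`>= 0`).
#' @param tau prediction horizon (`> 0`).
#' @param methods subset of `c("aft", "ipcw_glm", "ipcw_plugin")`.
#' @param query_patterns matrix of covariate patterns (columns `x1`, `x2`) at
#'   which predictions and their uncertainty are evaluated.
#' @param plugin_spec a [classifier_spec()] of kind `"plugin"`, required when
#'   `"ipcw_plugin"` is among the methods.
#' @param alpha two-sided CI error level.
#' @param jackknife compute adjusted-jackknife SEs for the weighted
#'   classifiers (`TRUE` by default); set `FALSE` in cells that only report
#'   predictions, where the leave-one-out sweep is wasted work.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n, nsim, seed = 1L,
                            b = c(1, -0.5, 0.5), shape = 1,
                            lambda_cens = 0.10, tau = 5,
                            methods = c("aft", "ipcw_glm"),
                            query_patterns = rbind(c(1, 1), c(1, 0)),
                            plugin_spec = NULL, alpha = 0.05,
                            jackknife = TRUE) {
  if (n < 10) stop("'n' must be >= 10")
  if (nsim < 1) stop("'nsim' must be >= 1")
  if (tau <= 0) stop("'tau' must be positive")
  if (shape <= 0) stop("'shape' must be positive")
  if (lambda_cens < 0) stop("'lambda_cens' must be >= 0")
  if (length(b) != 3) stop("'b' must have length 3")
  methods <- match.arg(methods, c("aft", "ipcw_glm", "ipcw_plugin"),
                       several.ok = TRUE)
  if ("ipcw_plugin" %in% methods &&
      (!inherits(plugin_spec, "classifier_spec") ||
       plugin_spec$kind != "plugin"))
    stop("'ipcw_plugin' requires a plugin classifier_spec")
  query_patterns <- as.matrix(query_patterns)
  if (ncol(query_patterns) != 2) stop("'query_patterns' must have 2 columns")
  structure(list(n = as.integer(n), nsim = as.integer(nsim),
                 seed = as.integer(seed), b = b, shape = shape,
                 lambda_cens = lambda_cens, tau = tau, methods = methods,
                 query_patterns = query_patterns, plugin_spec = plugin_spec,
                 alpha = alpha, jackknife = isTRUE(jackknife)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: n = %d, nsim = %d, lambda_cens = %g, tau = %g, seed = %d\n",
    x$n, x$nsim, x$lambda_cens, x$tau, x$seed))
  cat("  methods:", paste(x$methods, collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form survival probability of the generating model
#'
#' `S(tau | x) = (1 + (tau / exp(b'(1, x)))^shape)^-1` for the log-logistic
#' event-time model. With the default `b = (1, -0.5, 0.5)`, `shape = 1` and
#' `tau = 5` this gives 0.352 for `x = (1, 1)` and 0.248 for `x = (1, 0)`.
#'
#' @param x covariate vector `(x1, x2)` or matrix of patterns.
#' @param b length-3 coefficients `(b0, b1, b2)`.
#' @param shape log-logistic shape.
#' @param tau horizon.
#' @return survival probabilities in `(0, 1)`.
#' @export
true_survival <- function(x, b = c(1, -0.5, 0.5), shape = 1, tau = 5) {
  if (tau <= 0) stop("'tau' must be positive")
  if (shape <= 0) stop("'shape' must be positive")
  xq <- query_matrix(x, length(b) - 1L)
  lp <- drop(cbind(1, xq) %*% b)
  drop(plogis(shape * (lp - log(tau))))
}

#' Simulate one dataset from a scenario
#'
#' Draws covariates, log-logistic event times (via [flexsurv::rllogis()]) and
#' exponential censoring times, and returns the observed data.
#'
#' @param config a [scenario_config()].
#' @param replicate_seed seed for this replicate.
#' @return data.frame with columns `time`, `status`, `x1`, `x2`.
#' @export
simulate_dataset <- function(config, replicate_seed) {
  if (!inherits(config, "scenario_config")) stop("'config' must be a scenario_config")
  set.seed(replicate_seed)
  n <- config$n
  x1 <- sample(c(-1, 1), n, replace = TRUE)
  x2 <- sample(c(0, 1), n, replace = TRUE)
  scale <- exp(config$b[1] + config$b[2] * x1 + config$b[3] * x2)
  tstar <- flexsurv::rllogis(n, shape = config$shape, scale = scale)
  cens <- if (config$lambda_cens > 0) rexp(n, config$lambda_cens) else
    rep(Inf, n)
  data.frame(time = pmin(tstar, cens),
             status = as.integer(tstar <= cens),
             x1 = x1, x2 = x2)
}

#' IPC-weighted Brier score
#'
#' `sum_i w_i (p_i - y_i)^2` with normalized weights; unknown-outcome records
#' (weight zero) contribute nothing. With correct censoring weights this is an
#' unbiased estimate of the mean squared prediction error on the dichotomized
#' outcome.
#'
#' @param prob in-sample predicted probabilities.
#' @inheritParams weighted_mean_predict
#' @return non-negative score.
#' @export
weighted_brier <- function(prob, y, weights) {
  w <- as_ipcw_weights(weights)
  if (length(prob) != w$n || length(y) != w$n)
    stop("'prob', 'y' and 'weights' lengths differ")
  if (any(prob < 0 | prob > 1)) stop("'prob' must lie in [0, 1]")
  if (any(is.na(y) & w$normalized > 0))
    stop("unknown outcomes must have weight zero")
  known <- !is.na(y)
  sum(w$normalized[known] * (prob[known] - y[known])^2)
}

#' Run one simulation replicate end to end
#'
#' Simulates a dataset, dichotomizes at `tau`, estimates reverse-KM IPC
#' weights, fits each requested method, and evaluates predictions, standard
#' errors (model-based for AFT and GLM; adjusted jackknife for GLM and
#' plugin), logit-scale CIs for every available SE flavour, and the in-sample
#' IPC-weighted Brier score. Fit failures are flagged per method
#' (`converged = FALSE`, `NA` results), never propagated as errors.
#'
#' @param config a [scenario_config()].
#' @param replicate_seed seed for this replicate.
#' @return data.frame with one row per (method, query pattern): columns
#'   `method`, `x1`, `x2`, `p_hat`, `mod_se`, `wjk_se`, CI bounds
#'   `mod_lo`/`mod_hi`/`wjk_lo`/`wjk_hi`, `brier`, `converged`,
#'   `replicate_seed`.
#' @export
run_replicate <- function(config, replicate_seed) {
  if (!inherits(config, "scenario_config")) stop("'config' must be a scenario_config")
  dat <- simulate_dataset(config, replicate_seed)
  qp <- config$query_patterns
  nq <- nrow(qp)
  alpha <- config$alpha
  tau <- config$tau
  xm <- as.matrix(dat[, c("x1", "x2")])
  y <- dichotomize_at(dat$time, dat$status, tau)
  w <- tryCatch(ipc_weights(dat$time, dat$status, tau),
                error = function(e) NULL)

  empty_row <- function(method) data.frame(
    method = method, x1 = qp[, 1], x2 = qp[, 2],
    p_hat = NA_real_, mod_se = NA_real_, wjk_se = NA_real_,
    mod_lo = NA_real_, mod_hi = NA_real_,
    wjk_lo = NA_real_, wjk_hi = NA_real_,
    brier = NA_real_, converged = FALSE, replicate_seed = replicate_seed)

  one_method <- function(method) {
    res <- tryCatch({
      if (method == "aft") {
        fit <- fit_loglogistic_aft(dat$time, dat$status, xm)
        p_hat <- predict(fit, qp, tau = tau)
        mod_se <- model_se(fit, qp, tau = tau)
        wjk_se <- rep(NA_real_, nq)
        brier <- if (is.null(w)) NA_real_ else
          weighted_brier(predict(fit, xm, tau = tau), y, w)
        conv <- fit$converged
      } else {
        if (is.null(w)) stop("IPC weights unavailable")
        if (method == "ipcw_glm") {
          fit <- fit_weighted_logit(xm, y, w, offset = -log(tau))
          p_hat <- predict(fit, qp)
          mod_se <- model_se(fit, qp)
          wjk_se <- if (config$jackknife) {
            spec <- classifier_spec("weighted_logit",
                                    hyperparameters = list(offset = -log(tau)))
            jackknife_se(spec, xm, y, w, qp)$se
          } else rep(NA_real_, nq)
          brier <- weighted_brier(predict(fit, xm), y, w)
          conv <- fit$converged
        } else {  # ipcw_plugin
          spec <- config$plugin_spec
          f <- refit_with_weights(spec, xm, y, w)
          p_hat <- f(qp)
          mod_se <- rep(NA_real_, nq)
          wjk_se <- if (config$jackknife)
            jackknife_se(spec, xm, y, w, qp)$se else rep(NA_real_, nq)
          brier <- weighted_brier(f(xm), y, w)
          conv <- TRUE
        }
      }
      mod_ci <- if (all(is.na(mod_se))) matrix(NA_real_, nq, 2) else
        logit_ci(p_hat, mod_se, alpha)
      wjk_ci <- if (all(is.na(wjk_se))) matrix(NA_real_, nq, 2) else
        logit_ci(p_hat, wjk_se, alpha)
      mod_ci <- matrix(mod_ci, nq, 2)
      wjk_ci <- matrix(wjk_ci, nq, 2)
      data.frame(method = method, x1 = qp[, 1], x2 = qp[, 2],
                 p_hat = p_hat, mod_se = mod_se, wjk_se = wjk_se,
                 mod_lo = mod_ci[, 1], mod_hi = mod_ci[, 2],
                 wjk_lo = wjk_ci[, 1], wjk_hi = wjk_ci[, 2],
                 brier = brier, converged = conv,
                 replicate_seed = replicate_seed)
    }, error = function(e) {
      message("replicate ", replicate_seed, ", method ", method,
              " failed: ", conditionMessage(e))
      empty_row(method)
    })
    res
  }

  do.call(rbind, lapply(config$methods, one_method))
}

#' Run a full simulation scenario
#'
#' Executes `config$nsim` replicates with independent per-replicate seeds
#' spawned from the master seed, concatenating the per-replicate results.
#' Identical master seeds give bitwise identical results.
#'
#' @param config a [scenario_config()].
#' @return object of class `ipcw_simulation`: list with `results` (long
#'   data.frame from [run_replicate()]) and `config`.
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "scenario_config")) stop("'config' must be a scenario_config")
  set.seed(config$seed)
  rep_seeds <- sample.int(2147483646L, config$nsim)
  results <- do.call(rbind, lapply(rep_seeds, function(s)
    run_replicate(config, s)))
  structure(list(results = results, config = config),
            class = "ipcw_simulation")
}

#' @export
print.ipcw_simulation <- function(x, ...) {
  cat("IPCW simulation:", x$config$nsim, "replicates\n")
  print(summarize_ademp(x))
  invisible(x)
}

#' Summarize a simulation into ADEMP performance measures
#'
#' For each (method, query pattern): replicate-mean prediction, empirical SD
#' of predictions (denominator `n_converged - 1`; `NA` when fewer than two
#' converged replicates), mean adjusted-jackknife and model-based SE
#' estimates, empirical coverage of the logit-scale CIs against the true
#' survival probability of the generating model, mean IPC-weighted Brier
#' score, and the number of converged replicates. Non-converged replicates
#' are excluded per measure.
#'
#' @param sim an `ipcw_simulation` from [run_simulation()], or a compatible
#'   long data.frame (then `truth` and `config` must be supplied via `truth`).
#' @param truth optional named vector / data.frame override of the true
#'   probabilities per pattern; by default computed with [true_survival()]
#'   from the scenario's generating parameters.
#' @return data.frame with one row per (method, pattern) and columns
#'   `method`, `x1`, `x2`, `truth`, `mean_prediction`, `empirical_sd`,
#'   `mean_wjk_see`, `mean_mod_see`, `coverage_wjk`, `coverage_mod`,
#'   `mean_brier`, `n_converged`.
#' @export
summarize_ademp <- function(sim, truth = NULL) {
  if (inherits(sim, "ipcw_simulation")) {
    res <- sim$results
    cfg <- sim$config
    if (is.null(truth))
      truth <- data.frame(
        x1 = cfg$query_patterns[, 1], x2 = cfg$query_patterns[, 2],
        truth = true_survival(cfg$query_patterns, cfg$b, cfg$shape, cfg$tau))
  } else {
    res <- sim
    if (is.null(truth)) stop("'truth' is required for raw result tables")
  }
  res <- res[res$converged & !is.na(res$p_hat), , drop = FALSE]
  if (nrow(res) == 0) stop("no converged replicates to summarize")
  key <- interaction(res$method, res$x1, res$x2, drop = TRUE)
  rows <- lapply(split(res, key), function(g) {
    tr <- truth_for_pattern(truth, g$x1[1], g$x2[1])
    data.frame(
      method = g$method[1], x1 = g$x1[1], x2 = g$x2[1], truth = tr,
      mean_prediction = mean(g$p_hat),
      empirical_sd = if (nrow(g) > 1) sd(g$p_hat) else NA_real_,
      mean_wjk_see = mean_or_na(g$wjk_se),
      mean_mod_see = mean_or_na(g$mod_se),
      coverage_wjk = cover_or_na(g$wjk_lo, g$wjk_hi, tr),
      coverage_mod = cover_or_na(g$mod_lo, g$mod_hi, tr),
      mean_brier = mean_or_na(g$brier),
      n_converged = nrow(g))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, -out$x1, -out$x2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

mean_or_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)

cover_or_na <- function(lo, hi, tr) {
  ok <- !is.na(lo) & !is.na(hi)
  if (!any(ok)) return(NA_real_)
  mean(lo[ok] <= tr & tr <= hi[ok])
}

truth_for_pattern <- function(truth, x1, x2) {
  if (is.data.frame(truth)) {
    hit <- truth$x1 == x1 & truth$x2 == x2
    if (!any(hit)) stop("no truth value for pattern (", x1, ", ", x2, ")")
    return(truth$truth[which(hit)[1]])
  }
  nm <- paste0(x1, ",", x2)
  if (!is.null(names(truth)) && nm %in% names(truth)) return(truth[[nm]])
  if (length(truth) == 1L) return(truth)
  stop("cannot resolve truth for pattern (", x1, ", ", x2, ")")
}

#' Format an ADEMP summary as a fixed-width text table
#'
#' Renders one metric of a [summarize_ademp()] table with methods as columns
#' and query patterns as rows, mirroring the layout of per-scenario report
#' tables.
#'
#' @param summary output of [summarize_ademp()].
#' @param metric column of the summary to tabulate.
#' @param digits significant digits.
#' @return character vector of table lines (also printed).
#' @export
format_ademp_table <- function(summary, metric = "mean_prediction",
                               digits = 4) {
  if (!metric %in% names(summary)) stop("unknown metric: ", metric)
  pats <- unique(summary[, c("x1", "x2")])
  methods <- unique(summary$method)
  header <- c(sprintf("%-10s", "pattern"), sprintf("%12s", methods))
  lines <- paste(header, collapse = "")
  for (i in seq_len(nrow(pats))) {
    vals <- vapply(methods, function(m) {
      v <- summary[summary$method == m & summary$x1 == pats$x1[i] &
                     summary$x2 == pats$x2[i], metric]
      if (length(v) == 0 || is.na(v)) "-" else format(signif(v, digits))
    }, character(1))
    lines <- c(lines, paste0(sprintf("%-10s", paste0("(", pats$x1[i], ",",
                                                     pats$x2[i], ")")),
                             paste(sprintf("%12s", vals), collapse = "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
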