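# File I/O and the analyze/simulate workflows behind the command-line
# front-end (inst/cli/ipcwjack.R). Survival CSV dialect: header row, columns
# `time` (positive float) and `status` (0/1); every remaining column is a
# numeric covariate (categoricals must be pre-encoded -- no silent dummy
# coding).

#' Read a survival CSV file
#'
#' @param path CSV file with header; columns `time` and `status` are
#'   mandatory, all other columns are treated as numeric covariates.
#' @return validated data.frame.
#' @export
read_survival_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "status") %in% names(dat)))
    stop("CSV must contain 'time' and 'status' columns: ", path)
  bad <- which(!is.finite(dat$time) | dat$time <= 0)
  if (length(bad))
    stop("non-positive or missing 'time' at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  bad <- which(!(dat$status %in% c(0, 1)))
  if (length(bad))
    stop("'status' not 0/1 at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), " of ", path)
  covs <- setdiff(names(dat), c("time", "status"))
  for (cv in covs) {
    if (!is.numeric(dat[[cv]]))
      stop("covariate column '", cv, "' is not numeric; ",
           "encode categorical variables before analysis")
    if (any(!is.finite(dat[[cv]])))
      stop("covariate column '", cv, "' contains missing/non-finite values")
  }
  dat
}

#' Predict survival probabilities with uncertainty for a dataset
#'
#' Runs the full IPCW prediction workflow on a survival dataset: dichotomize
#' at `tau`, estimate reverse-KM IPC weights, fit the requested method and
#' report, for each query covariate pattern, the predicted probability of
#' surviving `tau` with its standard error and logit-scale confidence
#' interval.
#'
#' @param data data.frame with columns `time`, `status` and numeric
#'   covariates (as from [read_survival_csv()]).
#' @param tau prediction horizon.
#' @param method `"ipcw_glm"` (IPC-weighted logistic regression),
#'   `"weighted_mean"` (covariate-free IPC-weighted mean) or `"aft"`
#'   (log-logistic AFT on the full event-time information), or
#'   `"ipcw_plugin"` with a `plugin_spec`.
#' @param se_method `"adjusted_jackknife"` or `"model_based"` (AFT and GLM
#'   only; the AFT has no IPCW jackknife -- it does not use the weights).
#' @param alpha CI error level.
#' @param query matrix/data.frame of covariate patterns (columns matching the
#'   covariate columns of `data`), or `NULL` for the unique covariate rows of
#'   the data. Ignored by `weighted_mean`.
#' @param plugin_spec a plugin [classifier_spec()] for `method = "ipcw_plugin"`.
#' @param seed seed forwarded to plugin fits.
#' @return data.frame with one row per query pattern: the covariates,
#'   `p_hat`, `se`, `ci_low`, `ci_high`, `se_method`, `n`, `n_zero_weight`,
#'   `pct_zero_weight`.
#' @export
analyze_survival <- function(data, tau,
                             method = c("ipcw_glm", "weighted_mean", "aft",
                                        "ipcw_plugin"),
                             se_method = c("adjusted_jackknife", "model_based"),
                             alpha = 0.05, query = NULL, plugin_spec = NULL,
                             seed = 1L) {
  method <- match.arg(method)
  se_method <- match.arg(se_method)
  check_survival_input(data$time, data$status)
  covs <- setdiff(names(data), c("time", "status"))
  xm <- as.matrix(data[, covs, drop = FALSE])
  y <- dichotomize_at(data$time, data$status, tau)
  w <- ipc_weights(data$time, data$status, tau)
  nzero <- sum(w$zero_mask)

  if (method == "weighted_mean") {
    qx <- matrix(0, 1, max(1L, ncol(xm)))
    qdf <- data.frame(row.names = 1)
  } else {
    if (is.null(query)) {
      qx <- unique(xm)
    } else {
      qx <- as.matrix(query)
      if (ncol(qx) != ncol(xm))
        stop("'query' must have one column per covariate (",
             paste(covs, collapse = ", "), ")")
    }
    qdf <- as.data.frame(qx)
    names(qdf) <- covs
  }

  if (method == "aft") {
    if (se_method == "adjusted_jackknife")
      stop("the AFT model does not use IPC weights; use se_method = 'model_based'")
    fit <- fit_loglogistic_aft(data$time, data$status, xm)
    p_hat <- predict(fit, qx, tau = tau)
    se <- model_se(fit, qx, tau = tau)
  } else if (method == "ipcw_glm" && se_method == "model_based") {
    fit <- fit_weighted_logit(xm, y, w, offset = -log(tau))
    p_hat <- predict(fit, qx)
    se <- model_se(fit, qx)
  } else {
    spec <- switch(method,
      weighted_mean = classifier_spec("weighted_mean"),
      ipcw_glm = classifier_spec("weighted_logit",
                                 hyperparameters = list(offset = -log(tau))),
      ipcw_plugin = {
        if (is.null(plugin_spec)) stop("'ipcw_plugin' requires a plugin_spec")
        plugin_spec$seed <- as.integer(seed)
        plugin_spec
      })
    if (method == "ipcw_plugin" && se_method == "model_based")
      stop("plugins have no model-based SE; use se_method = 'adjusted_jackknife'")
    jk <- jackknife_se(spec, xm, y, w, qx)
    p_hat <- jk$p_hat
    se <- jk$se
  }
  ci <- matrix(logit_ci(p_hat, se, alpha), ncol = 2)
  out <- cbind(qdf,
               data.frame(p_hat = p_hat, se = se,
                          ci_low = ci[, 1], ci_high = ci[, 2],
                          se_method = if (method %in% c("aft") ||
                                          se_method == "model_based")
                            "model_based" else "adjusted_jackknife",
                          n = w$n, n_zero_weight = nzero,
                          pct_zero_weight = 100 * nzero / w$n))
  rownames(out) <- NULL
  out
}

SCENARIO_KEYS <- c("n", "nsim", "seed", "b", "shape", "lambda_cens", "tau",
                   "methods", "query_patterns", "alpha", "jackknife")

#' Read a scenario configuration from JSON
#'
#' Accepts the [scenario_config()] fields as top-level JSON keys
#' (`query_patterns` as an array of 2-element arrays). Unknown keys are
#' rejected by name.
#'
#' @param path JSON file path.
#' @return a [scenario_config()].
#' @export
read_scenario_json <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown))
    stop("unknown scenario config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$query_patterns))
    raw$query_patterns <- matrix(as.numeric(raw$query_patterns),
                                 ncol = 2,
                                 byrow = is.list(raw$query_patterns))
  do.call(scenario_config, raw)
}

#' Run a scenario file and write tidy results plus formatted tables
#'
#' @param config_path scenario JSON (see [read_scenario_json()]).
#' @param out_prefix path prefix; writes `<prefix>_results.csv` (tidy long
#'   format: method, x1, x2, metric, value) and `<prefix>_tables.txt`.
#' @return the [summarize_ademp()] data.frame, invisibly.
#' @export
run_scenario_file <- function(config_path, out_prefix) {
  cfg <- read_scenario_json(config_path)
  sim <- run_simulation(cfg)
  summ <- summarize_ademp(sim)
  tidy <- tidy_summary(summ)
  write.csv(tidy, paste0(out_prefix, "_results.csv"), row.names = FALSE)
  metrics <- c("mean_prediction", "empirical_sd", "mean_wjk_see",
               "mean_mod_see", "coverage_wjk", "coverage_mod", "mean_brier")
  txt <- unlist(lapply(metrics, function(m) {
    c(paste0("== ", m, " =="),
      utils::capture.output(format_ademp_table(summ, m)), "")
  }))
  writeLines(txt, paste0(out_prefix, "_tables.txt"))
  invisible(summ)
}

tidy_summary <- function(summ) {
  metrics <- setdiff(names(summ), c("method", "x1", "x2"))
  do.call(rbind, lapply(metrics, function(m)
    data.frame(method = summ$method, x1 = summ$x1, x2 = summ$x2,
               metric = m, value = as.numeric(summ[[m]]))))
}

#' Reproduce the reduced simulation-study grid
#'
#' Runs the scenario grid `n` x censoring-rate with the package's default
#' generating model and both built-in analysis methods, and returns the
#' stacked summaries. The defaults reproduce a reduced version of the
#' simulation study (the full study uses 5000 replicates per cell).
#'
#' @param n sample sizes to run.
#' @param lambda_cens censoring rates to run (0.10 and 0.27 give 25% and 50%
#'   zero-weight records).
#' @param nsim replicates per cell.
#' @param seed master seed (each cell derives its own substream).
#' @return data.frame of [summarize_ademp()] rows with `n` and `lambda_cens`
#'   columns prepended.
#' @export
reproduce_tables <- function(n = c(200, 1000), lambda_cens = c(0.10, 0.27),
                             nsim = 500, seed = 1L) {
  grid <- expand.grid(n = n, lambda_cens = lambda_cens)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- scenario_config(n = grid$n[i], nsim = nsim,
                           seed = seed + 1000L * i,
                           lambda_cens = grid$lambda_cens[i])
    cbind(n = grid$n[i], lambda_cens = grid$lambda_cens[i],
          summarize_ademp(run_simulation(cfg)))
  })
  do.call(rbind, out)
}
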