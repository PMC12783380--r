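# The package's core: the IPCW-adjusted infinitesimal jackknife standard
# error. Each record with positive weight is removed in turn, the remaining
# weights are renormalized by 1/(1 - w_i) -- the censoring curve is NOT
# re-estimated -- the classifier is refitted (warm-started where possible) and
# Var(p) = sum_i (1 - w_i) (p - p_{-i})^2. Records with weight zero satisfy
# p_{-i} = p exactly and are skipped.

#' Leave-one-out renormalized IPC weights
#'
#' Removes record `i` and renormalizes the remaining weights by
#' `1/(1 - w_i)`, so they again sum to 1. The censoring curve is treated as
#' fixed: the weights are not re-estimated.
#'
#' @param weights an `ipcw_weights` object or numeric raw weights.
#' @param i index of the record to remove; its normalized weight must be < 1.
#' @return an `ipcw_weights` object over the remaining `n - 1` records.
#' @export
loo_weights <- function(weights, i) {
  w <- as_ipcw_weights(weights)
  if (length(i) != 1L || i < 1 || i > w$n) stop("invalid index 'i'")
  wi <- w$normalized[i]
  if (wi >= 1 - 1e-12)
    stop("record ", i, " carries (numerically) all the weight; ",
         "leave-one-out weights are undefined")
  structure(list(raw = w$raw[-i],
                 normalized = w$normalized[-i] / (1 - wi),
                 zero_mask = w$zero_mask[-i],
                 tau = w$tau, n = w$n - 1L),
            class = "ipcw_weights")
}

#' IPCW-adjusted (and unadjusted) jackknife standard error of predictions
#'
#' Estimates the standard error of an IPC-weighted classifier's predicted
#' survival probabilities at the query covariate patterns by leave-one-out
#' jackknifing adapted to the IPC weights. For each record with `w_i > 0` the
#' classifier is refitted on the leave-one-out renormalized weights
#' ([loo_weights()]) and evaluated at every query pattern; the adjusted
#' variance is `sum_i (1 - w_i)(p - p_{-i})^2`. Records with weight zero do
#' not affect the fit (`p_{-i} = p`) and are skipped. The unadjusted variant
#' uses the classical factor `(n - 1)/n` on the same leave-one-out
#' predictions. All query patterns share one leave-one-out sweep.
#'
#' @param spec a [classifier_spec()].
#' @param x covariate matrix (no intercept) or vector.
#' @param y dichotomized outcomes (1 / 0 / `NA`).
#' @param weights an `ipcw_weights` object or numeric raw weights.
#' @param query_x covariate vector or matrix of query patterns.
#' @param type `"adjusted"` (IPCW-adjusted, the default) or `"unadjusted"`.
#' @return object of class `ipcw_jackknife`: list with `se` (one per query
#'   pattern), `p_hat` (full-sample predictions), `type`, and `trace` (the
#'   leave-one-out prediction matrix, weights used, and full-sample
#'   predictions; convertible with [as.data.frame()]).
#' @examples
#' d <- two_point_sample(60, seed = 2)
#' y <- dichotomize_at(d$time, d$status, 1)
#' w <- ipc_weights(d$time, d$status, 1)
#' jk <- jackknife_se(classifier_spec("weighted_mean"), NULL, y, w, 0)
#' c(jk$p_hat, jk$se)
#' @export
jackknife_se <- function(spec, x, y, weights, query_x,
                         type = c("adjusted", "unadjusted")) {
  type <- match.arg(type)
  if (!inherits(spec, "classifier_spec")) stop("'spec' must be a classifier_spec")
  w <- as_ipcw_weights(weights)
  n <- w$n
  wi <- w$normalized
  if (any(wi >= 1 - 1e-12))
    stop("a single record carries (numerically) all the weight")

  qx <- if (spec$kind == "weighted_mean") matrix(0, 1, 1) else
    query_matrix(query_x, if (is.null(dim(x))) 1L else ncol(as.matrix(x)))
  nq <- nrow(qx)

  full <- refit_with_weights(spec, x, y, w)
  p_hat <- full(qx)
  warm <- if (spec$kind == "weighted_logit")
    attr(full, "fit")$coefficients else NULL

  loo <- matrix(rep(p_hat, each = n), nrow = n)  # zero-weight rows: p_{-i} = p
  xm <- if (is.null(x)) NULL else as.matrix(x)
  for (i in which(wi > 0)) {
    p_loo <- tryCatch({
      w_loo <- loo_weights(w, i)
      f <- refit_with_weights(spec,
                              if (is.null(xm)) NULL else xm[-i, , drop = FALSE],
                              y[-i], w_loo, start = warm)
      f(qx)
    }, error = function(e)
      stop("leave-one-out refit failed at record ", i, ": ",
           conditionMessage(e), call. = FALSE))
    loo[i, ] <- p_loo
  }

  dev2 <- (matrix(rep(p_hat, each = n), nrow = n) - loo)^2
  se <- if (type == "adjusted")
    sqrt(colSums((1 - wi) * dev2))
  else
    sqrt(colSums(dev2) * (n - 1) / n)

  structure(list(se = se, p_hat = p_hat, type = type,
                 trace = structure(list(loo_predictions = loo,
                                        weights_used = w,
                                        p_hat_full = p_hat),
                                   class = "jackknife_trace")),
            class = "ipcw_jackknife")
}

#' @export
print.ipcw_jackknife <- function(x, ...) {
  cat(sprintf("%s jackknife SE over %d records\n",
              x$type, x$trace$weights_used$n))
  print(data.frame(p_hat = x$p_hat, se = x$se))
  invisible(x)
}

#' @export
as.data.frame.jackknife_trace <- function(x, ...) {
  loo <- x$loo_predictions
  colnames(loo) <- paste0("loo_prediction", seq_len(ncol(loo)))
  data.frame(record = seq_len(nrow(loo)),
             weight = x$weights_used$normalized,
             loo, check.names = FALSE)
}

#' Write a jackknife trace to CSV for audit
#'
#' @param trace the `trace` component of a [jackknife_se()] result.
#' @param path output file path.
#' @export
write_jackknife_trace <- function(trace, path) {
  if (!inherits(trace, "jackknife_trace")) stop("'trace' must be a jackknife_trace")
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Single-jump Greenwood variance
#'
#' Greenwood's variance estimate for a Kaplan-Meier survival estimate with a
#' single jump: `d (m - d) / m^3`, where `m` is the number at risk and `d` the
#' number of events. In the tractable two-point model this equals
#' `(m - 1)/m` times the adjusted jackknife variance of the IPC-weighted mean.
#'
#' @param m number at risk (`>= 1`).
#' @param d number of events, `0 <= d <= m`.
#' @return non-negative variance.
#' @export
greenwood_variance <- function(m, d) {
  if (m < 1 || d < 0 || d > m) stop("require 1 <= m and 0 <= d <= m")
  d * (m - d) / m^3
}
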