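# IPC-weighted classifiers built around the weighted binary log loss: the
# weighted mean (no covariates), the weighted logistic GLM, and the loss
# itself. The GLM is fitted by iteratively reweighted least squares with
# step-halving; warm starts keep the leave-one-out jackknife refits cheap.

LOSS_EPS <- 1e-10

#' IPC-weighted mean of the dichotomized outcomes
#'
#' The simplest IPCW classifier: predicts the same probability for every
#' subject, the normalized-weight mean of the known dichotomized outcomes.
#' Records with unknown outcome must carry weight zero.
#'
#' @param y dichotomized outcomes from [dichotomize_at()] (1 / 0 / `NA`).
#' @param weights an `ipcw_weights` object or non-negative numeric raw weights.
#' @return predicted survival probability in `[0, 1]`.
#' @export
weighted_mean_predict <- function(y, weights) {
  w <- as_ipcw_weights(weights)
  if (length(y) != w$n) stop("'y' and 'weights' lengths differ")
  if (any(is.na(y) & w$normalized > 0))
    stop("unknown outcomes must have weight zero")
  known <- !is.na(y)
  sum(w$normalized[known] * y[known])
}

#' IPC-weighted binary log loss
#'
#' Negative weighted log-likelihood `-sum(w_i [y_i log p_i + (1-y_i) log(1-p_i)])`
#' with normalized weights; unknown-outcome records (weight zero) contribute
#' nothing. Probabilities are clipped to `[1e-10, 1 - 1e-10]` for evaluation
#' only; a probability exactly at 0 or 1 that disagrees with its label is an
#' error.
#'
#' @param prob predicted probabilities.
#' @inheritParams weighted_mean_predict
#' @return non-negative loss.
#' @export
weighted_log_loss <- function(prob, y, weights) {
  w <- as_ipcw_weights(weights)
  if (length(prob) != w$n || length(y) != w$n)
    stop("'prob', 'y' and 'weights' lengths differ")
  if (any(prob < 0 | prob > 1)) stop("'prob' must lie in [0, 1]")
  if (any(is.na(y) & w$normalized > 0))
    stop("unknown outcomes must have weight zero")
  known <- !is.na(y) & w$normalized > 0
  p <- prob[known]; yy <- y[known]
  if (any((p <= 0 & yy == 1) | (p >= 1 & yy == 0)))
    stop("probability 0 or 1 with discordant label: loss is infinite")
  p <- pmin(pmax(p, LOSS_EPS), 1 - LOSS_EPS)
  -sum(w$normalized[known] * (yy * log(p) + (1 - yy) * log(1 - p)))
}

# Moore-Penrose solve for (possibly rank-deficient) information matrices:
# aliased directions (e.g. an all-zero covariate column) get coefficient 0
# instead of an error.
psolve <- function(A, b = NULL) {
  sv <- svd(A)
  pos <- sv$d > max(sv$d, 0) * 1e-12
  if (!any(pos)) stop("singular information matrix (separation?)")
  u <- sv$u[, pos, drop = FALSE]
  v <- sv$v[, pos, drop = FALSE]
  if (is.null(b)) v %*% (t(u) / sv$d[pos])
  else drop(v %*% ((t(u) %*% b) / sv$d[pos]))
}

# Newton/IRLS for the weighted binomial log-likelihood with a fixed offset.
# Step-halving guards against overshoot; convergence is declared on relative
# coefficient change < epsilon. Returns the inverse weighted observed
# information as the covariance.
irls_logit <- function(X, y, w, offset = 0, start = NULL,
                       epsilon = 1e-8, maxit = 100L) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else as.numeric(start)
  loglik <- function(b) {
    mu <- plogis(offset + drop(X %*% b))
    mu <- pmin(pmax(mu, LOSS_EPS), 1 - LOSS_EPS)
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    mu <- plogis(offset + drop(X %*% beta))
    wd <- w * mu * (1 - mu)
    info <- crossprod(X, X * wd)
    score <- drop(crossprod(X, w * (y - mu)))
    delta <- tryCatch(solve(info, score), error = function(e) psolve(info, score))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    rel <- max(abs(step * delta) / pmax(abs(cand), 1))
    beta <- cand
    ll <- ll_new
    if (rel < epsilon) { converged <- TRUE; break }
  }
  mu <- plogis(offset + drop(X %*% beta))
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  cov <- tryCatch(solve(info), error = function(e) psolve(info))
  list(coefficients = beta,
       covariance = cov,
       converged = converged,
       iterations = iter,
       loglik = ll)
}

#' Fit an IPC-weighted logistic regression
#'
#' Maximizes the IPC-weighted binomial log-likelihood (equivalently, minimizes
#' the weighted binary log loss) over coefficients `b` in
#' `logit P(Y = 1 | x) = offset + b'(1, x)`, with a fixed offset in the linear
#' predictor. With `offset = -log(tau)` the fitted coefficients are directly
#' comparable to the location coefficients of a shape-1 log-logistic event-time
#' model. Unknown-outcome records (weight zero) are excluded and cannot
#' influence the fit. Raw weights are used, so the covariance -- the inverse
#' weighted observed information at the optimum -- is on the usual `1/n` scale.
#'
#' @param x covariate matrix (one row per record, no intercept column) or
#'   vector for a single covariate.
#' @param y dichotomized outcomes (1 / 0 / `NA`) from [dichotomize_at()].
#' @param weights an `ipcw_weights` object or numeric raw weights.
#' @param offset fixed scalar added to the linear predictor (e.g. `-log(tau)`).
#' @param start optional warm-start coefficient vector (intercept first).
#' @param epsilon relative coefficient-change convergence tolerance.
#' @param maxit maximum IRLS iterations.
#' @return object of class `ipcw_logit` with `coefficients`, `covariance`,
#'   `offset`, `converged`, `iterations`.
#' @export
fit_weighted_logit <- function(x, y, weights, offset = 0, start = NULL,
                               epsilon = 1e-8, maxit = 100L) {
  w <- as_ipcw_weights(weights)
  x <- as.matrix(x)
  if (nrow(x) != w$n || length(y) != w$n)
    stop("'x', 'y' and 'weights' dimensions differ")
  if (any(is.na(y) & w$raw > 0))
    stop("unknown outcomes must have weight zero")
  keep <- w$raw > 0
  if (sum(keep) < ncol(x) + 2L)
    stop("need at least p + 2 records with non-zero weight")
  yk <- y[keep]
  if (length(unique(yk)) < 2L)
    stop("both outcome classes must be present among non-zero-weight records")
  X <- cbind(`(Intercept)` = 1, x[keep, , drop = FALSE])
  fit <- irls_logit(X, yk, w$raw[keep], offset = offset, start = start,
                    epsilon = epsilon, maxit = maxit)
  if (!fit$converged)
    warning("weighted logistic fit did not converge in ", maxit, " iterations")
  names(fit$coefficients) <- colnames(X)
  dimnames(fit$covariance) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$coefficients,
                 covariance = fit$covariance,
                 offset = offset,
                 converged = fit$converged,
                 iterations = fit$iterations,
                 loglik = fit$loglik,
                 n_used = sum(keep)),
            class = "ipcw_logit")
}

#' @export
print.ipcw_logit <- function(x, ...) {
  cat("IPC-weighted logistic regression (offset ", format(x$offset), ")\n",
      sep = "")
  print(x$coefficients)
  cat(if (x$converged) "Converged" else "NOT converged",
      "in", x$iterations, "IRLS iterations;", x$n_used,
      "non-zero-weight records\n")
  invisible(x)
}

query_matrix <- function(newx, p) {
  if (is.null(dim(newx))) newx <- matrix(newx, ncol = p, byrow = TRUE)
  if (ncol(newx) != p) stop("covariate dimension mismatch: expected ", p)
  newx
}

#' @rdname fit_weighted_logit
#' @param object an `ipcw_logit` fit.
#' @param newx covariate vector or matrix of query patterns (no intercept).
#' @param ... unused.
#' @export
predict.ipcw_logit <- function(object, newx, ...) {
  p <- length(object$coefficients) - 1L
  Xq <- cbind(1, query_matrix(newx, p))
  drop(plogis(object$offset + Xq %*% object$coefficients))
}

#' @rdname model_se
#' @export
model_se.ipcw_logit <- function(object, newx, ...) {
  if (!object$converged) stop("model SE requires a converged fit")
  p <- length(object$coefficients) - 1L
  Xq <- cbind(1, query_matrix(newx, p))
  prob <- drop(plogis(object$offset + Xq %*% object$coefficients))
  # delta method: d p / d b = p (1 - p) x
  quad <- rowSums((Xq %*% object$covariance) * Xq)
  prob * (1 - prob) * sqrt(pmax(quad, 0))
}
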