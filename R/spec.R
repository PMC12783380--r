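# Common refit-with-weights contract shared by all IPCW classifiers. The
# jackknife engine only needs one thing from a classifier: refit on a given
# weight vector and predict at query patterns. Plugins (e.g. gradient
# boosting) join through the same contract.

#' Specification of an IPC-weighted classifier
#'
#' Describes a classifier that can be (re)fitted on a dataset with per-record
#' IPC weights: the built-in weighted mean and weighted logistic regression,
#' or a user plugin (typically a machine-learning model minimizing the
#' IPC-weighted binary log loss). Refitting the same spec on the same data and
#' weights must yield identical predictions; plugins receive a fixed seed to
#' make that possible.
#'
#' @param kind one of `"weighted_mean"`, `"weighted_logit"`, `"plugin"`.
#' @param hyperparameters named list; for `weighted_logit` the entry `offset`
#'   (default 0) fixes the linear-predictor offset; plugin hyperparameters are
#'   passed through.
#' @param seed integer seed handed to plugin fits.
#' @param fit_fun for `kind = "plugin"`: a function
#'   `function(x, y, weights, seed, hyperparameters)` receiving the covariate
#'   matrix, outcomes (1/0/`NA`), normalized non-negative weights and returning
#'   a prediction function `function(newx) -> probabilities`. It must honour
#'   the weights: doubling a record's weight must be equivalent to duplicating
#'   the record (see [refit_with_weights()]).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("weighted_mean", "weighted_logit", "plugin"),
                            hyperparameters = list(), seed = 1L,
                            fit_fun = NULL) {
  kind <- match.arg(kind)
  if (kind == "plugin" && !is.function(fit_fun))
    stop("plugin specs require a 'fit_fun' function")
  if (kind != "plugin" && !is.null(fit_fun))
    stop("'fit_fun' is only meaningful for plugin specs")
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed), fit_fun = fit_fun),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("IPCW classifier spec:", x$kind, "\n")
  if (length(x$hyperparameters))
    cat("  hyperparameters:",
        paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Refit a classifier on given IPC weights
#'
#' Fits the classifier described by `spec` on `(x, y)` with the supplied
#' weights and returns a prediction function of the covariates. Unknown
#' outcomes (`NA`) must carry weight zero and never influence the fit. The
#' result is deterministic for fixed `(spec, x, y, weights)`.
#'
#' @param spec a [classifier_spec()].
#' @param x covariate matrix (no intercept column) or vector; ignored by
#'   `weighted_mean`.
#' @param y dichotomized outcomes (1 / 0 / `NA`).
#' @param weights an `ipcw_weights` object or numeric raw weights.
#' @param start optional warm-start coefficients (weighted_logit only).
#' @return a function `function(newx) -> probabilities`, with the underlying
#'   fit (if any) attached as attribute `"fit"`.
#' @export
refit_with_weights <- function(spec, x, y, weights, start = NULL) {
  if (!inherits(spec, "classifier_spec")) stop("'spec' must be a classifier_spec")
  w <- as_ipcw_weights(weights)
  switch(spec$kind,
    weighted_mean = {
      p <- weighted_mean_predict(y, w)
      f <- function(newx) {
        k <- if (is.null(dim(newx))) 1L else nrow(newx)
        rep(p, k)
      }
      attr(f, "fit") <- p
      f
    },
    weighted_logit = {
      off <- spec$hyperparameters$offset
      if (is.null(off)) off <- 0
      fit <- fit_weighted_logit(x, y, w, offset = off, start = start)
      f <- function(newx) predict(fit, newx)
      attr(f, "fit") <- fit
      f
    },
    plugin = {
      if (any(is.na(y) & w$normalized > 0))
        stop("unknown outcomes must have weight zero")
      f <- spec$fit_fun(as.matrix(x), y, w$normalized, spec$seed,
                        spec$hyperparameters)
      if (!is.function(f)) stop("plugin fit_fun must return a function")
      f
    })
}
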