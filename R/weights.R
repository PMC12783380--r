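# Dichotomization at the horizon, reverse Kaplan-Meier censoring curve and
# IPC weights. These are the ingredients every IPCW classifier in the package
# shares.

#' Dichotomize right-censored follow-up at a horizon
#'
#' Converts observed follow-up times into the trichotomous outcome used by
#' IPCW classification at horizon `tau`: `1` if the subject is known to have
#' survived `tau` (`time >= tau`, regardless of status -- a subject censored at
#' or after `tau` is known to have survived it), `0` if an event occurred
#' before `tau`, and `NA` when the subject was censored before both `tau` and
#' an event, so that survival status at `tau` is unknown.
#'
#' @param time positive follow-up times.
#' @param status event indicator, 1 = event at `time`, 0 = censored at `time`.
#' @param tau positive horizon.
#' @return integer vector of 1 / 0 / `NA`.
#' @examples
#' dichotomize_at(c(1.25, 0.5, 1), c(1, 0, 1), tau = 1)  # 1, NA, 1
#' @export
dichotomize_at <- function(time, status, tau) {
  check_survival_input(time, status)
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("'tau' must be a single positive number")
  ifelse(time >= tau, 1L, ifelse(status == 1L, 0L, NA_integer_))
}

check_survival_input <- function(time, status) {
  if (length(time) != length(status))
    stop("'time' and 'status' must have the same length")
  if (length(time) < 1L) stop("at least one record is required")
  if (!is.numeric(time) || any(!is.finite(time)) || any(time <= 0))
    stop("'time' must be finite and positive")
  if (!all(status %in% c(0, 1)))
    stop("'status' must be 0 (censored) or 1 (event)")
  invisible(TRUE)
}

#' Right-continuous step survival curve
#'
#' Container for a product-limit style estimate of a survival function:
#' value 1 before the first jump, the stored value at and after each jump
#' (right-continuous evaluation), non-increasing.
#'
#' @param jump_times strictly increasing positive jump times (may be empty,
#'   giving the constant-1 curve).
#' @param values survival probability after each jump, non-increasing, in
#'   `[0, 1]`.
#' @return object of class `step_curve`.
#' @seealso [curve_at()], [reverse_km()]
#' @export
step_curve <- function(jump_times = numeric(0), values = numeric(0)) {
  jump_times <- as.numeric(jump_times)
  values <- as.numeric(values)
  if (length(jump_times) != length(values))
    stop("'jump_times' and 'values' must have the same length")
  if (length(jump_times) > 0) {
    if (any(!is.finite(jump_times)) || any(jump_times <= 0))
      stop("'jump_times' must be finite and positive")
    if (is.unsorted(jump_times, strictly = TRUE))
      stop("'jump_times' must be strictly increasing")
    if (any(values < 0) || any(values > 1))
      stop("'values' must lie in [0, 1]")
    if (any(diff(c(1, values)) > 1e-12))
      stop("'values' must be non-increasing from 1")
  }
  structure(list(jump_times = jump_times, values = values),
            class = "step_curve")
}

#' @export
print.step_curve <- function(x, ...) {
  cat("Step survival curve with", length(x$jump_times), "jump(s)\n")
  if (length(x$jump_times) > 0) {
    show <- utils::head(data.frame(time = x$jump_times, surv = x$values), 10)
    print(show, row.names = FALSE)
    if (length(x$jump_times) > 10) cat("...\n")
  }
  invisible(x)
}

#' Evaluate a step survival curve
#'
#' Right-continuous evaluation: `S(t)` is the stored value at the largest jump
#' time `<= t`, and 1 before the first jump.
#'
#' @param curve a [step_curve()].
#' @param t non-negative evaluation time(s).
#' @return numeric vector of survival probabilities.
#' @export
curve_at <- function(curve, t) {
  if (!inherits(curve, "step_curve")) stop("'curve' must be a step_curve")
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be finite and >= 0")
  if (length(curve$jump_times) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$jump_times)
  out <- rep(1, length(t))
  out[idx > 0] <- curve$values[idx[idx > 0]]
  out
}

#' Reverse Kaplan-Meier estimate of the censoring survival function
#'
#' Product-limit estimate of `G(u) = P(C > u)` obtained by swapping the roles
#' of event and censoring: censorings (`status == 0`) are the events of
#' interest and observed events act as censored observations. With tied event
#' and censoring times, events remain in the risk set for the censoring jump
#' at that time. The estimation itself is delegated to
#' [survival::survfit()] on the flipped status, whose tie convention matches.
#'
#' @inheritParams dichotomize_at
#' @return a [step_curve()] for `G`; the constant-1 curve when no censoring
#'   was observed.
#' @export
reverse_km <- function(time, status) {
  check_survival_input(time, status)
  sf <- survival::survfit(survival::Surv(time, 1 - status) ~ 1,
                          se.fit = FALSE)
  keep <- sf$n.event > 0
  step_curve(sf$time[keep], pmax(sf$surv[keep], 0))
}

#' IPC weight set
#'
#' Inverse-probability-of-censoring weights at horizon `tau`: a record censored
#' before both `tau` and an event gets raw weight 0 (its dichotomized outcome
#' is unknown); a record with `time >= tau` gets `1 / G(tau)`; a record with an
#' event before `tau` gets `1 / G(time)`, with `G` the censoring survival
#' curve evaluated right-continuously. Normalized weights divide by the total
#' raw weight so they sum to 1.
#'
#' @inheritParams dichotomize_at
#' @param curve censoring survival [step_curve()]; estimated by [reverse_km()]
#'   on the same data when `NULL`.
#' @return object of class `ipcw_weights` with components `raw`, `normalized`,
#'   `zero_mask` (`TRUE` exactly for unknown-outcome records), `tau` and `n`.
#' @examples
#' d <- two_point_sample(50, p = 0.4, q = 0.7, seed = 1)
#' w <- ipc_weights(d$time, d$status, tau = 1)
#' sum(w$normalized)  # 1
#' @export
ipc_weights <- function(time, status, tau, curve = NULL) {
  y <- dichotomize_at(time, status, tau)
  if (is.null(curve)) curve <- reverse_km(time, status)
  if (!inherits(curve, "step_curve")) stop("'curve' must be a step_curve")
  n <- length(time)
  raw <- numeric(n)
  known <- !is.na(y)
  eval_at <- ifelse(y[known] == 1L, tau, time[known])
  g <- curve_at(curve, eval_at)
  if (any(g <= 0)) {
    bad <- eval_at[g <= 0][1]
    stop("estimated censoring survival is 0 at time ", format(bad),
         "; IPC weights are undefined there")
  }
  raw[known] <- 1 / g
  if (all(raw == 0)) stop("all records have weight zero; no information at tau")
  structure(list(raw = raw,
                 normalized = raw / sum(raw),
                 zero_mask = !known,
                 tau = tau, n = n),
            class = "ipcw_weights")
}

#' @export
print.ipcw_weights <- function(x, ...) {
  cat(sprintf("IPC weights: n = %d, tau = %g, zero-weight = %d (%.1f%%)\n",
              x$n, x$tau, sum(x$zero_mask), 100 * mean(x$zero_mask)))
  invisible(x)
}

# Coerce a weights argument to an ipcw_weights-like list; numeric vectors are
# taken as raw weights with zero meaning unknown outcome.
as_ipcw_weights <- function(weights) {
  if (inherits(weights, "ipcw_weights")) return(weights)
  if (is.numeric(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    s <- sum(weights)
    if (s <= 0) stop("weights must not all be zero")
    return(structure(list(raw = weights, normalized = weights / s,
                          zero_mask = weights == 0,
                          tau = NA_real_, n = length(weights)),
                     class = "ipcw_weights"))
  }
  stop("'weights' must be an ipcw_weights object or a numeric vector")
}

#' Sample from the tractable two-point event/censoring model
#'
#' Draws i.i.d. records where the event time is 0.75 with probability `1 - p`
#' and 1.25 with probability `p`, and the censoring time is 0.5 with
#' probability `1 - q` and 2 with probability `q`; the observed time is the
#' minimum of the two and the status indicates whether the event came first.
#' At horizon `tau = 1` this model admits closed-form IPC weights (all
#' non-zero normalized weights equal `1/m`), which makes the adjusted
#' jackknife estimator analytically tractable.
#'
#' @param n sample size.
#' @param p probability the event time is 1.25 (i.e. survives `tau = 1`).
#' @param q probability the censoring time is 2 (not censored early).
#' @param seed integer seed; the function sets the RNG state.
#' @return data.frame with columns `time` and `status`.
#' @export
two_point_sample <- function(n, p = 0.4, q = 0.7, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  if (p < 0 || p > 1 || q < 0 || q > 1) stop("'p' and 'q' must lie in [0, 1]")
  set.seed(seed)
  event <- ifelse(runif(n) < p, 1.25, 0.75)
  cens <- ifelse(runif(n) < q, 2, 0.5)
  data.frame(time = pmin(event, cens),
             status = as.integer(event <= cens))
}
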