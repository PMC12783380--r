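# Confidence intervals for predicted probabilities. The logit-scale interval
# applies the delta method to logit(p): bounds logit(p) +/- z * se / (p(1-p)),
# back-transformed, which keeps the interval inside [0, 1]. The Wald interval
# is provided for comparison and deliberately NOT clipped: bounds outside
# [0, 1] are its known defect.

CI_EPS <- 1e-10

#' Logit-scale confidence interval for a predicted probability
#'
#' `100(1 - alpha)%` interval obtained by the delta method on the logit scale:
#' `logit(p) +/- z_{alpha/2} * se / (p (1 - p))`, back-transformed with the
#' inverse logit. The interval always lies in `[0, 1]` and contains `p_hat`.
#' A `p_hat` of exactly 0 or 1 is clipped to `(1e-10, 1 - 1e-10)` with a
#' warning so extreme but valid predictions still get a usable interval.
#'
#' @param p_hat predicted probability (vectorized).
#' @param se standard error of `p_hat` (`>= 0`).
#' @param alpha two-sided error level in `(0, 1)`.
#' @return for scalar input, a named vector `c(lower, upper)`; otherwise a
#'   two-column matrix.
#' @examples
#' logit_ci(0.5, 0.1)  # (0.3134, 0.6866)
#' @export
logit_ci <- function(p_hat, se, alpha = 0.05) {
  check_ci_args(p_hat, se, alpha)
  if (any(p_hat <= 0 | p_hat >= 1)) {
    warning("p_hat at 0 or 1 clipped to (1e-10, 1 - 1e-10) for the logit CI")
    p_hat <- pmin(pmax(p_hat, CI_EPS), 1 - CI_EPS)
  }
  z <- qnorm(1 - alpha / 2)
  half <- z * se / (p_hat * (1 - p_hat))
  lo <- plogis(qlogis(p_hat) - half)
  hi <- plogis(qlogis(p_hat) + half)
  ci_shape(lo, hi, p_hat)
}

#' Wald confidence interval for a predicted probability
#'
#' `p_hat +/- z_{alpha/2} * se`. Not clipped to `[0, 1]`: bounds outside the
#' probability range are the method's documented defect and the caller may
#' clip if desired.
#'
#' @inheritParams logit_ci
#' @return as in [logit_ci()].
#' @export
wald_ci <- function(p_hat, se, alpha = 0.05) {
  check_ci_args(p_hat, se, alpha)
  z <- qnorm(1 - alpha / 2)
  ci_shape(p_hat - z * se, p_hat + z * se, p_hat)
}

check_ci_args <- function(p_hat, se, alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly in (0, 1)")
  if (any(se < 0)) stop("'se' must be non-negative")
  if (length(se) != length(p_hat) && length(se) != 1L && length(p_hat) != 1L)
    stop("'p_hat' and 'se' lengths are incompatible")
  invisible(TRUE)
}

ci_shape <- function(lo, hi, p_hat) {
  if (length(p_hat) == 1L && length(lo) == 1L)
    c(lower = lo, upper = hi)
  else
    cbind(lower = lo, upper = hi)
}
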