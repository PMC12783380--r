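# Independent oracles used across the suite. They deliberately share no code
# with the package internals: brute-force product-limit computation, full
# enumeration of leave-one-out means, and finite differences.

# Product-limit estimate of P(C > u) by direct enumeration over unique times.
# Censorings (status == 0) are the events of interest; observed events stay in
# the risk set for a censoring jump at the same time.
oracle_reverse_km <- function(time, status, u) {
  jumps <- sort(unique(time[status == 0]))
  g <- 1
  for (tj in jumps) {
    if (tj > u) break
    at_risk <- sum(time >= tj)               # events at tj still at risk
    d <- sum(time == tj & status == 0)
    g <- g * (1 - d / at_risk)
  }
  g
}

# Three-case IPC weight definition applied literally, record by record.
oracle_ipc_weights <- function(time, status, tau) {
  raw <- vapply(seq_along(time), function(i) {
    if (time[i] >= tau) {
      1 / oracle_reverse_km(time, status, tau)
    } else if (status[i] == 1) {
      1 / oracle_reverse_km(time, status, time[i])
    } else 0
  }, numeric(1))
  list(raw = raw, normalized = raw / sum(raw))
}

# Full-enumeration jackknife for the weighted mean: recompute each
# leave-one-out weighted mean from its renormalized weights.
oracle_jackknife_mean <- function(y, w_norm, type = "adjusted") {
  yy <- ifelse(is.na(y), 0, y)
  p_hat <- sum(w_norm * yy)
  n <- length(y)
  loo <- vapply(seq_len(n), function(i) {
    if (w_norm[i] == 0) return(p_hat)
    sum((w_norm[-i] / (1 - w_norm[i])) * yy[-i])
  }, numeric(1))
  v <- if (type == "adjusted") sum((1 - w_norm) * (p_hat - loo)^2)
  else (n - 1) / n * sum((p_hat - loo)^2)
  list(p_hat = p_hat, se = sqrt(v), loo = loo)
}

# Weighted binary log loss evaluated directly (for optimizer oracles).
oracle_loss <- function(beta, X, y, w, offset = 0) {
  p <- plogis(offset + drop(X %*% beta))
  -sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# A small survival dataset with ties and mixed censoring, fully hand-checkable.
mixed_six <- function() {
  data.frame(time = c(0.5, 0.8, 1.2, 2.0, 2.0, 3.0),
             status = c(0, 1, 0, 1, 0, 1))
}
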