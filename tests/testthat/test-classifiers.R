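# IPC-weighted classifiers: weighted mean, weighted log loss, weighted
# logistic regression (vs independent optimizers), AFT comparator, and the
# refit-with-weights contract.

test_that("weighted mean prediction follows the normalized weights", {
  expect_equal(weighted_mean_predict(c(1, 0, 1), c(0.5, 0.3, 0.2)), 0.7)
  expect_equal(weighted_mean_predict(c(1, 1, 1), c(1, 2, 3)), 1)
  # unknown outcomes must carry weight zero
  expect_equal(weighted_mean_predict(c(1, NA, 0), c(0.5, 0, 0.5)), 0.5)
  expect_error(weighted_mean_predict(c(1, NA), c(0.5, 0.5)), "weight zero")
})

test_that("weighted log loss matches hand arithmetic and handles edge cases", {
  expect_equal(weighted_log_loss(0.5, 1, 1), log(2))
  w <- c(0.5, 0.3, 0.2)
  p <- c(0.8, 0.4, 0.6)
  y <- c(1, 0, 1)
  expect_equal(weighted_log_loss(p, y, w),
               -(0.5 * log(0.8) + 0.3 * log(0.6) + 0.2 * log(0.6)))
  # perfect prediction limit: clipped, tiny loss
  expect_lt(weighted_log_loss(c(1, 0), c(1, 0), c(0.5, 0.5)), 1e-9)
  # discordant hard 0/1 is an error
  expect_error(weighted_log_loss(c(0, 0.5), c(1, 0), c(0.5, 0.5)), "discordant")
})

make_fixture8 <- function() {
  # 8-row fixture with both classes, unequal weights and two covariates
  list(x = cbind(x1 = c(-1, 1, 1, -1, 1, -1, 1, -1),
                 x2 = c(0, 1, 0, 1, 1, 0, 0, 1)),
       y = c(1L, 0L, 1L, 0L, 1L, 1L, 0L, 0L),
       w = c(1, 1.5, 0.8, 1.2, 1, 2, 0.5, 1))
}

test_that("weighted logit matches a derivative-free optimizer of the same loss", {
  fx <- make_fixture8()
  for (off in c(0, -log(5))) {
    fit <- fit_weighted_logit(fx$x, fx$y, fx$w, offset = off)
    X <- cbind(1, fx$x)
    nm <- optim(c(0, 0, 0), oracle_loss, X = X, y = fx$y, w = fx$w,
                offset = off, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 50000))
    expect_equal(unname(fit$coefficients), nm$par, tolerance = 1e-6)
    # optimum loss no worse than the oracle's
    expect_lte(oracle_loss(unname(fit$coefficients), X, fx$y, fx$w, off),
               nm$value + 1e-10)
  }
})

test_that("weighted logit agrees with stats::glm on the same weighted problem", {
  fx <- make_fixture8()
  fit <- fit_weighted_logit(fx$x, fx$y, fx$w, offset = 0)
  gf <- suppressWarnings(
    glm(fx$y ~ fx$x, family = binomial(), weights = fx$w,
        control = glm.control(epsilon = 1e-12)))
  expect_equal(unname(fit$coefficients), unname(coef(gf)), tolerance = 1e-8)
  expect_equal(unname(fit$covariance),
               unname(summary(gf)$cov.unscaled), tolerance = 1e-6)
})

test_that("all-zero covariates with balanced outcome give intercept 0", {
  x <- matrix(0, 10, 1)
  y <- rep(c(0L, 1L), 5)
  fit <- fit_weighted_logit(x, y, rep(1, 10), offset = 0)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)
})

test_that("weighted logit refuses degenerate inputs", {
  fx <- make_fixture8()
  expect_error(fit_weighted_logit(fx$x, rep(1L, 8), fx$w), "both outcome classes")
  expect_error(fit_weighted_logit(fx$x[1:3, ], fx$y[1:3], fx$w[1:3]),
               "p \\+ 2")
  yy <- fx$y; yy[1] <- NA
  expect_error(fit_weighted_logit(fx$x, yy, fx$w), "weight zero")
})

test_that("offset equivalence: -log(tau) offset only shifts the intercept", {
  set.seed(41)
  cfg <- scenario_config(n = 400, nsim = 1, seed = 41)
  d <- simulate_dataset(cfg, 41)
  y <- dichotomize_at(d$time, d$status, 5)
  w <- ipc_weights(d$time, d$status, 5)
  xm <- as.matrix(d[, c("x1", "x2")])
  f0 <- fit_weighted_logit(xm, y, w, offset = 0)
  f1 <- fit_weighted_logit(xm, y, w, offset = -log(5))
  expect_equal(unname(f0$coefficients[1]), unname(f1$coefficients[1]) - log(5),
               tolerance = 1e-7)
  expect_equal(unname(f0$coefficients[-1]), unname(f1$coefficients[-1]),
               tolerance = 1e-7)
  q <- rbind(c(1, 1), c(-1, 0))
  expect_equal(predict(f0, q), predict(f1, q), tolerance = 1e-10)
})

test_that("logit predictions reproduce the closed-form survival probabilities", {
  fit <- structure(list(coefficients = c(1, -0.5, 0.5),
                        covariance = diag(3) * 0,
                        offset = -log(5), converged = TRUE),
                   class = "ipcw_logit")
  expect_equal(round(predict(fit, c(1, 1)), 3), 0.352)
  expect_equal(round(predict(fit, c(1, 0)), 3), 0.248)
  expect_equal(model_se(fit, c(1, 1)), 0)  # zero covariance -> zero SE
  fit$coefficients <- c(0, 0, 0); fit$offset <- 0
  expect_equal(predict(fit, c(0, 0)), 0.5)
})

test_that("delta-method GLM SE agrees with a finite-difference oracle", {
  fx <- make_fixture8()
  fit <- fit_weighted_logit(fx$x, fx$y, fx$w, offset = -log(2))
  for (q in list(c(1, 1), c(-1, 0))) {
    pred_at <- function(b) plogis(fit$offset + sum(b * c(1, q)))
    h <- 1e-6
    g <- vapply(1:3, function(j) {
      bp <- bm <- fit$coefficients
      bp[j] <- bp[j] + h; bm[j] <- bm[j] - h
      (pred_at(bp) - pred_at(bm)) / (2 * h)
    }, numeric(1))
    expect_equal(model_se(fit, q),
                 sqrt(drop(g %*% fit$covariance %*% g)), tolerance = 1e-6)
  }
})

test_that("log-logistic AFT recovers generating parameters and predictions", {
  cfg <- scenario_config(n = 5000, nsim = 1, seed = 53, lambda_cens = 0.10)
  d <- simulate_dataset(cfg, 53)
  fit <- fit_loglogistic_aft(d$time, d$status, as.matrix(d[, c("x1", "x2")]))
  se <- sqrt(diag(fit$covariance))[1:3]
  expect_true(all(abs(fit$coefficients - c(1, -0.5, 0.5)) < 3 * se))
  expect_lt(abs(fit$shape - 1), 0.1)
  expect_lt(abs(predict(fit, c(1, 1), tau = 5) - 0.352), 0.03)
})

test_that("AFT closed-form predictions and symmetry checks hold", {
  fit <- structure(list(coefficients = c(1, -0.5, 0.5), scale = 1, shape = 1,
                        covariance = diag(4) * 0, converged = TRUE),
                   class = "ipcw_aft")
  expect_equal(round(predict(fit, c(1, 1), tau = 5), 3), 0.352)
  expect_equal(predict(fit, c(1, 1), tau = 5), exp(1) / (exp(1) + 5))
  expect_equal(round(predict(fit, c(1, 0), tau = 5), 3), 0.248)
  expect_gt(predict(fit, c(1, 1), tau = 1e-9), 1 - 1e-6)  # tau -> 0: S -> 1
  expect_equal(model_se(fit, c(1, 1), tau = 5), 0)
  # null covariate effects: predictions equal across patterns up to MC error
  cfg <- scenario_config(n = 3000, nsim = 1, seed = 57, b = c(1, 0, 0))
  d <- simulate_dataset(cfg, 57)
  f2 <- fit_loglogistic_aft(d$time, d$status, as.matrix(d[, c("x1", "x2")]))
  q <- rbind(c(1, 1), c(-1, 0), c(1, 0))
  preds <- predict(f2, q, tau = 5)
  truth <- true_survival(c(1, 1), b = c(1, 0, 0))
  expect_true(all(abs(preds - truth) < 4 * model_se(f2, q, tau = 5)))
})

test_that("AFT delta-method SE agrees with a finite-difference oracle", {
  d <- two_point_sample(200, p = 0.5, q = 0.8, seed = 61)
  x <- cbind(x1 = rep(c(-1, 1), 100))
  fit <- fit_loglogistic_aft(d$time, d$status, x)
  q <- 1
  tau <- 1
  pred_at <- function(theta) {  # theta = (b0, b1, log sigma)
    lp <- theta[1] + theta[2] * q
    plogis((lp - log(tau)) / exp(theta[3]))
  }
  theta0 <- c(fit$coefficients, log(fit$scale))
  h <- 1e-6
  g <- vapply(1:3, function(j) {
    tp <- tm <- theta0
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (pred_at(tp) - pred_at(tm)) / (2 * h)
  }, numeric(1))
  expect_equal(model_se(fit, q, tau = tau),
               sqrt(drop(g %*% fit$covariance %*% g)), tolerance = 1e-6)
})

test_that("refit_with_weights delegates and is deterministic", {
  d <- two_point_sample(80, seed = 71)
  y <- dichotomize_at(d$time, d$status, 1)
  w <- ipc_weights(d$time, d$status, 1)
  x <- matrix(rnorm(80), ncol = 1)
  f_mean <- refit_with_weights(classifier_spec("weighted_mean"), x, y, w)
  expect_equal(f_mean(0), weighted_mean_predict(y, w))
  spec <- classifier_spec("weighted_logit")
  # both classes must be present; tractable sample has 0/1 among weighted rows
  f1 <- refit_with_weights(spec, x, y, w)
  f2 <- refit_with_weights(spec, x, y, w)
  expect_identical(f1(c(0.5)), f2(c(0.5)))
  fit <- fit_weighted_logit(x, y, w, offset = 0)
  expect_equal(f1(0.5), predict(fit, 0.5))
})

test_that("plugin weight/duplication equivalence holds for gradient boosting", {
  skip_if_not_installed("xgboost")
  xgb_fit <- function(x, y, weights, seed, hyper) {
    keep <- weights > 0
    dtrain <- xgboost::xgb.DMatrix(x[keep, , drop = FALSE],
                                   label = y[keep], weight = weights[keep])
    params <- list(objective = "binary:logistic", max_depth = 2,
                   eta = 0.3, nthread = 1, seed = seed)
    bst <- xgboost::xgb.train(params, dtrain, nrounds = 20)
    function(newx) predict(bst, xgboost::xgb.DMatrix(
      matrix(newx, ncol = ncol(x))))
  }
  spec <- classifier_spec("plugin", seed = 7L, fit_fun = xgb_fit)
  set.seed(81)
  n <- 60
  x <- cbind(x1 = sample(c(-1, 1), n, TRUE), x2 = sample(0:1, n, TRUE))
  y <- rbinom(n, 1, plogis(0.3 * x[, 1] - 0.2 * x[, 2]))
  w <- rep(1, n)
  q <- rbind(c(1, 1), c(-1, 0))
  # doubling record 1's weight == adding a duplicate record before normalization
  f_w <- refit_with_weights(spec, x, y, replace(w, 1, 2))
  f_dup <- refit_with_weights(spec, rbind(x, x[1, ]), c(y, y[1]), rep(1, n + 1))
  expect_equal(f_w(q), f_dup(q), tolerance = 1e-7)
  # and a plugin that ignores weights fails the same canary
  bad_fit <- function(x, y, weights, seed, hyper) {
    m <- mean(y)
    function(newx) rep(m, if (is.null(dim(newx))) 1 else nrow(newx))
  }
  bad <- classifier_spec("plugin", fit_fun = bad_fit)
  g_w <- refit_with_weights(bad, x, y, replace(w, 1, 5))
  g_dup <- refit_with_weights(bad, rbind(x, x[1, ]), c(y, y[1]), rep(1, n + 1))
  expect_false(isTRUE(all.equal(g_w(q), g_dup(q))))
})

test_that("weighted-logit loss at the optimum beats the true coefficients", {
  for (s in 1:5) {
    cfg <- scenario_config(n = 300, nsim = 1, seed = s)
    d <- simulate_dataset(cfg, s)
    y <- dichotomize_at(d$time, d$status, 5)
    w <- ipc_weights(d$time, d$status, 5)
    xm <- as.matrix(d[, c("x1", "x2")])
    fit <- fit_weighted_logit(xm, y, w, offset = -log(5))
    keep <- w$raw > 0
    X <- cbind(1, xm[keep, ])
    expect_lte(
      oracle_loss(unname(fit$coefficients), X, y[keep], w$raw[keep], -log(5)),
      oracle_loss(c(1, -0.5, 0.5), X, y[keep], w$raw[keep], -log(5)) + 1e-10)
  }
})
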