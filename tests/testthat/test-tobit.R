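test_that("log-likelihood matches closed-form normal contributions", {
  # one interior observation at the mean: log phi(0)
  expect_equal(tobit_loglik(0, 1, matrix(1), 0, lower = -Inf),
               dnorm(0, log = TRUE))
  expect_equal(dnorm(0, log = TRUE), -0.9189385, tolerance = 1e-7)
  # one observation censored at the limit with mu = 0: log Phi(0) = log(1/2)
  expect_equal(tobit_loglik(0, 1, matrix(1), 0, lower = 0), log(0.5))
  # likelihood concentrates as sigma shrinks around an exact fit
  X <- cbind(1, 1:5)
  y <- drop(X %*% c(1, 2))
  ll <- vapply(c(1, 0.1, 0.01), function(s)
    tobit_loglik(c(1, 2), s, X, y, lower = -Inf), numeric(1))
  expect_true(all(diff(ll) > 0))
  expect_error(tobit_loglik(c(1, NA), 1, X, y), "nonfinite")
  expect_error(tobit_loglik(c(1, 2), -1, X, y), "positive")
})

test_that("analytic gradient matches a numerical gradient", {
  sim <- generate_tobit_data(60, c(0.2, -0.1, 0.3), 0.25, lower = 0,
                             seed = 8)
  th <- c(0.15, -0.05, 0.25, log(0.3))
  g_an <- healtheff:::tobit_grad(th[1:3], th[4], sim$X, sim$y, 0, Inf)
  g_num <- numDeriv::grad(function(t)
    tobit_loglik(t[1:3], exp(t[4]), sim$X, sim$y, 0, Inf), th)
  expect_equal(g_an, g_num, tolerance = 1e-6)
})

test_that("uncensored fit equals OLS with ML residual variance", {
  sim <- generate_tobit_data(200, c(0.5, 0.2, -0.4), 0.3, lower = -Inf,
                             seed = 3)
  fit <- fit_tobit(sim$X[, -1], sim$y, lower = -Inf, upper = Inf)
  ols <- lm(sim$y ~ sim$X[, -1])
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma, sqrt(mean(resid(ols)^2)), tolerance = 1e-6)
  expect_equal(fit$n_censored_low + fit$n_censored_high, 0)
})

test_that("censored fit agrees with an independent survreg fit", {
  skip_if_not_installed("survival")
  sim <- generate_tobit_data(400, c(0.2, -0.1, 0.3), 0.25, lower = 0,
                             seed = 5)
  fit <- fit_tobit(sim$X[, -1], sim$y, lower = 0)
  sv <- survival::survreg(
    survival::Surv(sim$y, sim$y > 0, type = "left") ~ sim$X[, -1],
    dist = "gaussian")
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(fit$sigma, unname(sv$scale), tolerance = 1e-6)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-8)
  # Stata-style z inference: CI brackets the estimate symmetrically
  p <- length(coef(fit))
  expect_true(all(fit$ci[1:p, 1] < coef(fit) & coef(fit) < fit$ci[1:p, 2]))
  expect_gte(fit$lr_chi2, 0)
})

test_that("optimum log-likelihood improves on the OLS start", {
  sim <- generate_tobit_data(250, c(0.2, -0.1, 0.3), 0.25, lower = 0,
                             seed = 12)
  fit <- fit_tobit(sim$X[, -1], sim$y, lower = 0)
  b0 <- coef(lm(sim$y ~ sim$X[, -1]))
  s0 <- sqrt(mean(resid(lm(sim$y ~ sim$X[, -1]))^2))
  ll0 <- tobit_loglik(b0, s0, sim$X, sim$y, lower = 0)
  expect_gte(fit$loglik, ll0)
})

test_that("standardizing covariates and back-transforming is a no-op", {
  sim <- generate_tobit_data(300, c(0.2, -0.1, 0.3), 0.25, lower = 0,
                             seed = 19)
  X <- sim$X[, -1] %*% diag(c(10, 0.01))  # wildly different scales
  colnames(X) <- c("a", "b")
  f1 <- fit_tobit(X, sim$y, lower = 0)
  f2 <- fit_tobit(X, sim$y, lower = 0, standardize = TRUE)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$se, f2$se, tolerance = 1e-4)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("estimates stay finite and convergent under heavy censoring", {
  sim <- generate_tobit_data(600, c(-0.45, 0.25), 0.25, lower = 0, seed = 23)
  expect_gt(mean(sim$censored_low), 0.85)  # ~90% censored scenario
  fit <- fit_tobit(sim$X[, -1, drop = FALSE], sim$y, lower = 0)
  expect_true(fit$converged)
  expect_true(all(is.finite(c(coef(fit), fit$sigma, fit$loglik))))
})

test_that("input validation: rank deficiency and bad limits are named", {
  sim <- generate_tobit_data(50, c(0.2, 0.1), 0.2, lower = 0, seed = 2)
  X <- cbind(sim$X[, -1, drop = FALSE], dup = sim$X[, 2])
  expect_error(fit_tobit(X, sim$y, lower = 0), "rank deficient")
  expect_error(fit_tobit(sim$X[, -1, drop = FALSE], sim$y,
                         lower = 1, upper = 0), "lower")
  expect_error(fit_tobit(sim$X[1:3, -1, drop = FALSE], sim$y[1:3]),
               "n > p")
})

test_that("regression table carries the published-layout columns", {
  sim <- generate_tobit_data(120, c(0.2, -0.1, 0.3), 0.25, lower = 0,
                             seed = 31)
  tb <- tobit_table(fit_tobit(sim$X[, -1], sim$y, lower = 0))
  expect_equal(names(tb), c("variable", "coefficient", "se", "t_ratio",
                            "p", "ci_lower", "ci_upper"))
  expect_equal(tb$variable[nrow(tb)], "sigma")
})
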