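#' Censored-normal (Tobit) log-likelihood
#'
#' Log-likelihood of the censored linear model `y* = X beta + eps`,
#' `eps ~ N(0, sigma^2)`, where `y = max(lower, min(upper, y*))` is
#' observed. Interior observations contribute the normal log-density,
#' observations at the lower limit the lower-tail log-probability
#' `log Phi((lower - X beta)/sigma)`, and observations at the upper limit
#' the upper-tail log-probability.
#'
#' @param beta coefficient vector (length `ncol(X)`).
#' @param sigma positive scale.
#' @param X design matrix (include an intercept column if wanted).
#' @param y observed response.
#' @param lower,upper censoring limits; use `-Inf` / `Inf` for none.
#' @return The log-likelihood (scalar).
#' @export
tobit_loglik <- function(beta, sigma, X, y, lower = -Inf, upper = Inf) {
  X <- as.matrix(X)
  if (!all(is.finite(beta)) || !is.finite(sigma) || anyNA(X) || anyNA(y))
    stop("nonfinite inputs to tobit_loglik")
  if (sigma <= 0) stop("sigma must be positive")
  mu <- drop(X %*% beta)
  lo <- is.finite(lower) & y <= lower
  hi <- is.finite(upper) & y >= upper
  mid <- !lo & !hi
  ll <- 0
  if (any(mid))
    ll <- ll + sum(stats::dnorm((y[mid] - mu[mid]) / sigma, log = TRUE) -
                     log(sigma))
  if (any(lo))
    ll <- ll + sum(stats::pnorm((lower - mu[lo]) / sigma, log.p = TRUE))
  if (any(hi))
    ll <- ll + sum(stats::pnorm((mu[hi] - upper) / sigma, log.p = TRUE))
  ll
}

# gradient of tobit_loglik wrt (beta, log sigma)
tobit_grad <- function(beta, lsigma, X, y, lower, upper) {
  sigma <- exp(lsigma)
  mu <- drop(X %*% beta)
  lo <- is.finite(lower) & y <= lower
  hi <- is.finite(upper) & y >= upper
  mid <- !lo & !hi
  dmu <- numeric(length(y))
  dsig <- numeric(length(y))
  if (any(mid)) {
    r <- (y[mid] - mu[mid]) / sigma
    dmu[mid] <- r / sigma
    dsig[mid] <- (r^2 - 1) / sigma
  }
  if (any(lo)) {
    a <- (lower - mu[lo]) / sigma
    lam <- exp(stats::dnorm(a, log = TRUE) - stats::pnorm(a, log.p = TRUE))
    dmu[lo] <- -lam / sigma
    dsig[lo] <- -lam * a / sigma
  }
  if (any(hi)) {
    b <- (mu[hi] - upper) / sigma
    lam <- exp(stats::dnorm(b, log = TRUE) - stats::pnorm(b, log.p = TRUE))
    dmu[hi] <- lam / sigma
    dsig[hi] <- -lam * b / sigma
  }
  as.numeric(c(crossprod(X, dmu), sigma * sum(dsig)))
}

#' Fit a Tobit regression by maximum likelihood
#'
#' Maximizes the censored-normal likelihood by BFGS with analytic gradient
#' in the parameterization `(beta, log sigma)`, starting from the OLS fit.
#' Standard errors come from the inverse observed information (numerical
#' Hessian of the log-likelihood in `(beta, sigma)` at the optimum);
#' T-ratios and p-values use the standard normal reference, and a likelihood
#' ratio chi-square tests against the intercept-only Tobit. With both limits
#' infinite the model is plain Gaussian regression and the ML solution
#' equals OLS (with the ML variance `RSS/n`).
#'
#' @param X design matrix *without* intercept (one column per covariate),
#'   or a data frame of covariates.
#' @param y response vector (e.g. combined efficiency scores).
#' @param lower,upper censoring limits. Default left-censoring at 0, no
#'   upper limit: super-efficiency scores exceed 1, so the classical (0,1]
#'   DEA censoring cannot apply; left-censoring at 0 is the weakest
#'   assumption consistent with a nonnegative score.
#' @param standardize if `TRUE`, covariates are centred/scaled before
#'   fitting and coefficients and standard errors are mapped back to the
#'   original scale (the fit is invariant; this only aids optimization and
#'   interpretation of starting values).
#' @param ci_level confidence level for the coefficient intervals.
#' @param intercept include an intercept (default `TRUE`).
#' @return An object of class `tobit_fit`: `coefficients` (intercept first),
#'   `sigma`, `se` (includes `sigma`'s), `t_ratios`, `p_values`, `ci`
#'   (matrix), `loglik`, `loglik_null`, `lr_chi2`, `lr_df`, `lr_p`, `n_obs`,
#'   `n_censored_low`, `n_censored_high`, `converged`, `lower`, `upper`.
#' @examples
#' set.seed(1)
#' sim <- generate_tobit_data(200, beta = c(0.2, -0.1, 0.3), sigma = 0.25,
#'                            lower = 0, seed = 1)
#' fit <- fit_tobit(sim$X[, -1], sim$y, lower = 0)
#' coef(fit)
#' @export
fit_tobit <- function(X, y, lower = 0, upper = Inf, standardize = FALSE,
                      ci_level = 0.95, intercept = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, ci_level > 0, ci_level < 1)
  if (is.finite(lower) && is.finite(upper) && lower >= upper)
    stop("lower limit must be below upper limit")
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize && ncol(X) > 0) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0)) stop("cannot standardize constant column(s): ",
                            paste(colnames(X)[scl == 0], collapse = ", "))
    Xf <- scale(X, center = ctr, scale = scl)
    if (!intercept)
      stop("standardize = TRUE requires an intercept")
  } else Xf <- X
  D <- if (intercept) cbind(`(Intercept)` = 1, Xf) else Xf
  p <- ncol(D)
  if (n <= p + 2) stop("need n > p + 2 observations")
  qrD <- qr(D)
  if (qrD$rank < p)
    stop("design is rank deficient; collinear column(s): ",
         paste(colnames(D)[qrD$pivot[(qrD$rank + 1):p]], collapse = ", "))

  fit_ml <- function(Dm, start = NULL) {
    pm <- ncol(Dm)
    if (is.null(start)) {
      b0 <- qr.coef(qr(Dm), y)
      r0 <- y - drop(Dm %*% b0)
      s0 <- sqrt(max(mean(r0^2), 1e-8))
      start <- unname(c(b0, log(s0)))
    }
    # guard against line-search excursions (overflowing exp, NaN)
    negll <- function(th) {
      if (!all(is.finite(th)) || !is.finite(exp(th[pm + 1]))) return(1e300)
      -tobit_loglik(th[seq_len(pm)], exp(th[pm + 1]), Dm, y, lower, upper)
    }
    neggr <- function(th) {
      if (!all(is.finite(th)) || !is.finite(exp(th[pm + 1])))
        return(numeric(pm + 1))
      -tobit_grad(th[seq_len(pm)], th[pm + 1], Dm, y, lower, upper)
    }
    opt <- stats::optim(start, negll, neggr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    list(beta = opt$par[seq_len(pm)], sigma = exp(opt$par[pm + 1]),
         loglik = -opt$value, converged = opt$convergence == 0)
  }

  full <- fit_ml(D)
  null <- if (intercept && p > 1) fit_ml(matrix(1, n, 1)) else NULL

  beta <- full$beta; sigma <- full$sigma
  # observed information in (beta, sigma)
  H <- numDeriv::hessian(function(th)
    tobit_loglik(th[seq_len(p)], th[p + 1], D, y, lower, upper),
    c(beta, sigma))
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, p + 1, p + 1))
  se <- sqrt(pmax(diag(vc), 0))

  if (standardize && ncol(X) > 0) {
    # back-transform: y = a + sum b_j (x_j - c_j)/s_j  =>  slope b_j/s_j,
    # intercept a - sum b_j c_j / s_j
    J <- diag(p + 1)
    for (j in seq_len(ncol(X))) {
      J[1, j + 1] <- -ctr[j] / scl[j]
      J[j + 1, j + 1] <- 1 / scl[j]
    }
    beta <- drop(J[seq_len(p), seq_len(p)] %*% beta)
    vc <- J %*% vc %*% t(J)
    se <- sqrt(pmax(diag(vc), 0))
  }

  names(beta) <- colnames(D)
  names(se) <- c(colnames(D), "sigma")
  tz <- beta / se[seq_len(p)]
  pv <- 2 * stats::pnorm(-abs(tz))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  ci <- cbind(lower = c(beta, sigma) - zq * se,
              upper = c(beta, sigma) + zq * se)
  rownames(ci) <- names(se)

  lr <- if (is.null(null)) NA_real_ else 2 * (full$loglik - null$loglik)
  structure(list(
    coefficients = beta, sigma = sigma, se = se, t_ratios = tz,
    p_values = pv, ci = ci, ci_level = ci_level,
    loglik = full$loglik,
    loglik_null = if (is.null(null)) NA_real_ else null$loglik,
    lr_chi2 = max(lr, 0), lr_df = p - 1,
    lr_p = if (is.na(lr)) NA_real_ else
      stats::pchisq(max(lr, 0), df = p - 1, lower.tail = FALSE),
    n_obs = n,
    n_censored_low = sum(is.finite(lower) & y <= lower),
    n_censored_high = sum(is.finite(upper) & y >= upper),
    converged = full$converged, lower = lower, upper = upper),
    class = "tobit_fit")
}

#' @export
coef.tobit_fit <- function(object, ...) object$coefficients

#' @export
logLik.tobit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' @export
vcov.tobit_fit <- function(object, ...) {
  p <- length(object$coefficients)
  # reconstruct from se is lossy; keep se-based diagonal for printing only
  diag(object$se[seq_len(p)]^2, p, p)
}

#' Regression table of a Tobit fit
#'
#' One row per coefficient with SE, T-ratio, p-value and confidence
#' interval, followed by a `sigma` row — the layout of a published Tobit
#' results table.
#'
#' @param fit a `tobit_fit`.
#' @return A data frame.
#' @export
tobit_table <- function(fit) {
  stopifnot(inherits(fit, "tobit_fit"))
  p <- length(fit$coefficients)
  data.frame(
    variable = c(names(fit$coefficients), "sigma"),
    coefficient = c(fit$coefficients, fit$sigma),
    se = fit$se,
    t_ratio = c(fit$t_ratios, NA),
    p = c(fit$p_values, NA),
    ci_lower = fit$ci[, "lower"],
    ci_upper = fit$ci[, "upper"],
    row.names = NULL)
}

#' @export
print.tobit_fit <- function(x, digits = 3, ...) {
  cat("Tobit regression (ML), n =", x$n_obs,
      "| censored low:", x$n_censored_low, "high:", x$n_censored_high, "\n")
  tb <- tobit_table(x)
  tb[-1] <- lapply(tb[-1], round, digits)
  print(tb, row.names = FALSE)
  cat("Log-likelihood:", round(x$loglik, 3),
      " LR chi2(", x$lr_df, "):", round(x$lr_chi2, 2),
      " Prob > chi2:", format.pval(x$lr_p, digits = 3), "\n")
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}
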