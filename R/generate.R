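#' Configuration of the synthetic health-resource panel generator
#'
#' Describes a synthetic world of `n_dmus` regions observed over
#' `n_periods` consecutive years: strictly positive inputs drawn
#' log-normally across DMUs (heavy right skew, as in provincial yearbook
#' data where one metropolis dwarfs the rest) with deterministic per-period
#' growth; a Cobb-Douglas best-practice frontier
#' `y_c = w_c * A_t * prod_a x_a^alpha_a` split across outputs by fixed
#' share weights, with Hicks-neutral technology level `A_t = (1 +
#' tech_growth)^(t-1)`; and DMU inefficiency `u >= 0` entering outputs as
#' `exp(-u)`, linked to contextual covariates through a softplus so it stays
#' smooth and nonnegative. A configurable fraction of DMUs sits exactly on
#' the frontier (`u = 0`). An optional one-period shock multiplies the
#' first output of every *non-frontier* DMU by a DMU-specific factor drawn
#' in `[shock_factor, 1]`. The asymmetry is deliberate twice over: a
#' uniform rescaling of an output column is absorbed by the unit invariance
#' of DEA and would leave every score unchanged, and in the disaster year
#' the motivating study emulates, service volume concentrated in the
#' frontier metropolis while peripheral systems lost visits — so the
#' frontier is spared and the rest sag below it, depressing that period's
#' mean score.
#'
#' Defaults emulate the structure of the 19-city, 2010-2018 provincial
#' panel that motivates the package: three inputs (health technicians,
#' beds, total expenditure in 10k yuan), two outputs (total visits,
#' discharges), five standardized covariates, first-period input levels and
#' growth rates matched to the published descriptive statistics, and a
#' negative technology drift consistent with the published total factor
#' productivity decline.
#'
#' @param n_dmus number of DMUs (default 19).
#' @param n_periods number of consecutive periods (default 9).
#' @param first_period label of the first period (default 2010).
#' @param frontier_exponents Cobb-Douglas input exponents `alpha_a > 0`
#'   (length `m`); their sum sets returns to scale (1 = constant).
#' @param input_base first-period mean level of each input.
#' @param input_growth per-period proportional growth of each input
#'   (scalar or length `m`).
#' @param input_scale_logsd log-sd of the common DMU size factor
#'   (cross-DMU skew).
#' @param input_mix_logsd log-sd of the per-input mix jitter around the
#'   common size factor.
#' @param output_levels target first-period mean level of each output
#'   (length `s`); fixes the share weights `w_c`.
#' @param tech_growth Hicks-neutral per-period technology growth (negative
#'   for regress).
#' @param covariate_cor correlation of each covariate with the DMU size
#'   factor.
#' @param inefficiency_location location of the softplus inefficiency link.
#' @param inefficiency_coefs covariate coefficients `gamma` in the link
#'   `u = softplus(location + gamma . z + nu)`; negative values mean the
#'   covariate reduces inefficiency (raises efficiency).
#' @param inefficiency_noise_sd sd of the persistent DMU noise `nu`.
#' @param frontier_fraction fraction of DMUs with `u = 0` exactly.
#' @param shock_period optional period label hit by the output shock.
#' @param shock_factor worst-case multiplicative shock in (0, 1]; the
#'   default matches the severity implied by the published disaster-year
#'   score column, where the hardest-hit sub-frontier units fell to about
#'   a fifth of their usual score.
#' @param seed integer root seed; fixed per-component offsets derive the
#'   substreams (inputs, covariates, inefficiency, shock, in that order) so
#'   adding a component never shifts existing draws.
#' @param schema a [panel_schema()] naming the columns; defaults to
#'   [sichuan_schema()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_dmus = 19L, n_periods = 9L,
                             first_period = 2010L,
                             frontier_exponents = c(0.45, 0.30, 0.25),
                             input_base = c(16157, 15093, 303932),
                             input_growth = c(0.071, 0.089, 0.171),
                             input_scale_logsd = 0.9,
                             input_mix_logsd = 0.15,
                             output_levels = c(18231480, 527948),
                             tech_growth = -0.05,
                             covariate_cor = 0.6,
                             inefficiency_location = -1.2,
                             inefficiency_coefs = c(0, -0.3, 0, -0.35, -0.25),
                             inefficiency_noise_sd = 0.3,
                             frontier_fraction = 0.45,
                             shock_period = NULL,
                             shock_factor = 0.25,
                             seed = 42L,
                             schema = sichuan_schema()) {
  m <- length(schema$inputs); s <- length(schema$outputs)
  p <- length(schema$covariates)
  if (length(input_growth) == 1L) input_growth <- rep(input_growth, m)
  stopifnot(n_dmus >= 1, n_periods >= 1,
            length(frontier_exponents) == m, all(frontier_exponents > 0),
            length(input_base) == m, all(input_base > 0),
            length(input_growth) == m,
            input_scale_logsd > 0, input_mix_logsd >= 0,
            length(output_levels) == s, all(output_levels > 0),
            length(inefficiency_coefs) == p,
            inefficiency_noise_sd >= 0,
            frontier_fraction >= 0, frontier_fraction <= 1,
            shock_factor > 0, shock_factor <= 1,
            abs(covariate_cor) < 1)
  structure(as.list(environment()), class = "generator_config")
}

softplus <- function(x) log1p(exp(-abs(x))) + pmax(x, 0)

#' Generate a synthetic panel with known ground truth
#'
#' Draws a balanced panel from a [generator_config()]. Identical seeds give
#' identical panels. The ground truth records, per DMU-period, the true
#' inefficiency `u`, the frontier membership flag (`u == 0`) and the
#' technology level `A_t`. In a shock period the recorded `u` excludes the
#' shock: shocked (always non-frontier) DMUs lie further below the frontier
#' than `u` alone implies.
#'
#' Draw order (one substream per component, derived from the root seed):
#' (1) inputs — DMU size factors, mix jitter; (2) covariates; (3)
#' inefficiency — frontier membership, persistent noise; (4) shock
#' severities. Inputs are drawn for the first period and grown
#' deterministically, so a DMU's input mix is constant over time.
#'
#' @param config a [generator_config()].
#' @return A list: `panel` (a [panel_dataset()]), `truth` (data frame with
#'   `dmu`, `period`, `u`, `frontier`, `tech_level`), `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  n <- cf$n_dmus; TT <- cf$n_periods; m <- cf$m; s <- cf$s; p <- cf$p
  periods <- cf$first_period + seq_len(TT) - 1L
  dmus <- sprintf("dmu%02d", seq_len(n))

  set.seed(cf$seed + 101L)
  size <- stats::rnorm(n)                      # common DMU scale factor
  mix <- matrix(stats::rnorm(n * m, sd = cf$input_mix_logsd), n, m)
  X1 <- matrix(0, n, m)
  for (a in seq_len(m))
    X1[, a] <- cf$input_base[a] *
      exp(cf$input_scale_logsd * size - cf$input_scale_logsd^2 / 2 +
            mix[, a])

  set.seed(cf$seed + 211L)
  Z <- array(0, c(n, TT, p))
  if (p > 0) {
    r <- cf$covariate_cor
    for (j in seq_len(p))
      Z[, , j] <- r * size +
        sqrt(1 - r^2) * matrix(stats::rnorm(n * TT), n, TT)
  }

  set.seed(cf$seed + 307L)
  n_front <- round(cf$frontier_fraction * n)
  frontier <- seq_len(n) %in% sample(n, n_front)
  nu <- stats::rnorm(n, sd = cf$inefficiency_noise_sd)

  set.seed(cf$seed + 401L)
  severity <- stats::runif(n, cf$shock_factor, 1)

  gmean_level <- prod(cf$input_base^cf$frontier_exponents)
  w <- cf$output_levels /
    (gmean_level * exp(cf$input_scale_logsd^2 *
                         (sum(cf$frontier_exponents) - 1) / 2))

  rows <- vector("list", n * TT)
  truth <- vector("list", n * TT)
  k <- 0L
  for (t in seq_len(TT)) {
    At <- (1 + cf$tech_growth)^(t - 1)
    Xt <- X1 %*% diag((1 + cf$input_growth)^(t - 1), m, m)
    for (i in seq_len(n)) {
      z <- if (p > 0) Z[i, t, ] else numeric(0)
      u <- if (frontier[i]) 0 else
        softplus(cf$inefficiency_location +
                   sum(cf$inefficiency_coefs * z) + nu[i])
      ybase <- w * At * prod(Xt[i, ]^cf$frontier_exponents) * exp(-u)
      if (!is.null(cf$shock_period) && periods[t] == cf$shock_period &&
          !frontier[i])
        ybase[1] <- ybase[1] * severity[i]
      k <- k + 1L
      row <- c(list(dmus[i], periods[t]), as.list(Xt[i, ]), as.list(ybase),
               as.list(z))
      names(row) <- c(cf$schema$dmu_column, cf$schema$period_column,
                      cf$schema$inputs, cf$schema$outputs,
                      cf$schema$covariates)
      rows[[k]] <- as.data.frame(row, check.names = FALSE)
      truth[[k]] <- data.frame(dmu = dmus[i], period = periods[t], u = u,
                               frontier = frontier[i], tech_level = At)
    }
  }
  df <- do.call(rbind, rows)
  tr <- do.call(rbind, truth)
  list(panel = panel_dataset(df, cf$schema), truth = tr, config = cf)
}

#' Simulate data for the Tobit recovery experiments
#'
#' Latent `y* = X beta + eps`, `eps ~ N(0, sigma^2)`, observed `y` clipped
#' at the censoring limits. The design is an intercept column followed by
#' independent standard-normal covariates.
#'
#' @param n sample size.
#' @param beta true coefficients, intercept first.
#' @param sigma true error sd.
#' @param lower,upper censoring limits.
#' @param seed integer seed.
#' @return A list: `X` (`n x length(beta)`, first column 1), `y`,
#'   `y_latent`, `censored_low`, `censored_high`, `censored_fraction`.
#' @export
generate_tobit_data <- function(n, beta, sigma, lower = 0, upper = Inf,
                                seed = 1L) {
  p <- length(beta)
  stopifnot(n > p + 2, sigma > 0)
  set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)",
                   if (p > 1) paste0("x", seq_len(p - 1)) else NULL)
  ystar <- drop(X %*% beta) + stats::rnorm(n, sd = sigma)
  y <- pmin(pmax(ystar, lower), upper)
  lo <- is.finite(lower) & ystar <= lower
  hi <- is.finite(upper) & ystar >= upper
  list(X = X, y = y, y_latent = ystar, censored_low = lo, censored_high = hi,
       censored_fraction = mean(lo | hi))
}
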