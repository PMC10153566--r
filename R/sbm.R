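#' Non-oriented slacks-based measure (SBM) of efficiency
#'
#' Scores DMU `k` against the full reference technology of a cross-section
#' by Tone's non-oriented SBM,
#' \deqn{\rho = \min \frac{1 - \frac1m \sum_a s_a^-/x_{ak}}
#'                        {1 + \frac1s \sum_c s_c^+/y_{ck}}}
#' subject to \eqn{x_k = X'\lambda + s^-}, \eqn{y_k = Y'\lambda - s^+},
#' \eqn{\lambda, s^-, s^+ \ge 0} (and \eqn{\sum\lambda = 1} under VRS).
#' The linear-fractional program is linearized by the Charnes-Cooper
#' transformation (scale all variables by a scalar `t` chosen so the
#' denominator equals 1) and solved as a single LP; slacks and weights are
#' de-scaled before being returned. `rho` lies in (0, 1], and equals 1
#' exactly when a zero-slack solution exists (the DMU is SBM-efficient).
#'
#' @param k DMU index (row of the cross-section) or DMU name.
#' @param section a [cross_section()].
#' @param rts `"vrs"` (default) or `"crs"`.
#' @return A list of class `sbm_result`: `rho`, `slack_input` (length `m`,
#'   in input units), `slack_output` (length `s`), `lambda` (length `n`),
#'   `status`.
#' @references Tone, K. (2001) A slacks-based measure of efficiency in data
#'   envelopment analysis. European Journal of Operational Research 130.
#' @export
sbm_score <- function(k, section, rts = c("vrs", "crs")) {
  rts <- match.arg(rts)
  stopifnot(inherits(section, "cross_section"))
  if (is.character(k)) k <- match(k, section$dmus)
  X <- section$X; Y <- section$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  stopifnot(!is.na(k), k >= 1L, k <= n)
  xk0 <- X[k, ]; yk0 <- Y[k, ]
  # unit invariance: normalize every column by the evaluated DMU's value so
  # the LP works at O(1) magnitudes regardless of the data's units
  X <- sweep(X, 2, xk0, "/"); Y <- sweep(Y, 2, yk0, "/")
  xk <- rep(1, m); yk <- rep(1, s)

  # variables: (t, Lambda_1..n, Sin_1..m, Sout_1..s), all >= 0
  nv <- 1L + n + m + s
  i_t <- 1L; i_l <- 1L + seq_len(n); i_si <- 1L + n + seq_len(m)
  i_so <- 1L + n + m + seq_len(s)
  obj <- numeric(nv)
  obj[i_t] <- 1
  obj[i_si] <- -1 / (m * xk)

  rows <- list(); dir <- character(0); rhs <- numeric(0)
  # denominator normalization: t + (1/s) sum Sout_c / y_ck = 1
  r <- numeric(nv); r[i_t] <- 1; r[i_so] <- 1 / (s * yk)
  rows[[1]] <- r; dir <- "=="; rhs <- 1
  for (a in seq_len(m)) {
    r <- numeric(nv); r[i_l] <- X[, a]; r[i_si[a]] <- 1; r[i_t] <- -xk[a]
    rows[[length(rows) + 1L]] <- r; dir <- c(dir, "=="); rhs <- c(rhs, 0)
  }
  for (c in seq_len(s)) {
    r <- numeric(nv); r[i_l] <- Y[, c]; r[i_so[c]] <- -1; r[i_t] <- -yk[c]
    rows[[length(rows) + 1L]] <- r; dir <- c(dir, "=="); rhs <- c(rhs, 0)
  }
  if (rts == "vrs") {
    r <- numeric(nv); r[i_l] <- 1; r[i_t] <- -1
    rows[[length(rows) + 1L]] <- r; dir <- c(dir, "=="); rhs <- c(rhs, 0)
  }
  sol <- solve_lp(obj, do.call(rbind, rows), dir, rhs)
  if (sol$status != "optimal")
    return(structure(list(rho = NA_real_, slack_input = rep(NA_real_, m),
                          slack_output = rep(NA_real_, s),
                          lambda = rep(NA_real_, n), status = "error"),
                     class = "sbm_result"))
  tt <- sol$x[i_t]
  res <- list(rho = sol$value,
              slack_input = sol$x[i_si] / tt * xk0,
              slack_output = sol$x[i_so] / tt * yk0,
              lambda = sol$x[i_l] / tt,
              status = "optimal")
  names(res$slack_input) <- colnames(X)
  names(res$slack_output) <- colnames(Y)
  names(res$lambda) <- section$dmus
  structure(res, class = "sbm_result")
}

#' Super-efficiency SBM score of an efficient DMU
#'
#' Re-scores a frontier DMU against the technology spanned by all *other*
#' DMUs, allowing values above 1 so efficient units can be ranked. The
#' program searches for a projection point \eqn{(\bar x, \bar y)} with
#' \eqn{\bar x \ge X_{-k}'\lambda}, \eqn{\bar y \le Y_{-k}'\lambda},
#' \eqn{\bar x \ge x_k}, \eqn{0 < \bar y \le y_k} (and \eqn{\sum\lambda = 1}
#' under VRS), minimizing
#' \deqn{\delta = \frac{\frac1m \sum_a \bar x_a / x_{ak}}
#'                     {\frac1s \sum_c \bar y_c / y_{ck}},}
#' linearized by the same Charnes-Cooper device. For a DMU on the frontier
#' `delta >= 1`; callers should route sub-frontier DMUs to [sbm_score()]
#' instead (see [combined_score()]).
#'
#' @inheritParams sbm_score
#' @return A list of class `super_sbm_result`: `delta`, `projection_input`
#'   (\eqn{\bar x}), `projection_output` (\eqn{\bar y}), `lambda` (length
#'   `n`, zero at `k`), `status` (`"optimal"` or `"infeasible"`; the program
#'   is infeasible when the reference set is empty, i.e. `n = 1`).
#' @references Tone, K. (2002) A slacks-based measure of super-efficiency in
#'   data envelopment analysis. European Journal of Operational Research 143.
#' @export
super_sbm_score <- function(k, section, rts = c("vrs", "crs")) {
  rts <- match.arg(rts)
  stopifnot(inherits(section, "cross_section"))
  if (is.character(k)) k <- match(k, section$dmus)
  X <- section$X; Y <- section$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  stopifnot(!is.na(k), k >= 1L, k <= n)
  if (n < 2L)
    return(structure(list(delta = NA_real_,
                          projection_input = rep(NA_real_, m),
                          projection_output = rep(NA_real_, s),
                          lambda = rep(NA_real_, n), status = "infeasible"),
                     class = "super_sbm_result"))
  xk0 <- X[k, ]; yk0 <- Y[k, ]
  X <- sweep(X, 2, xk0, "/"); Y <- sweep(Y, 2, yk0, "/")  # unit invariance
  xk <- rep(1, m); yk <- rep(1, s)
  Xr <- X[-k, , drop = FALSE]; Yr <- Y[-k, , drop = FALSE]
  nr <- n - 1L

  # variables: (t, Lambda_1..nr, Xbar_1..m, Ybar_1..s) scaled by t, all >= 0
  nv <- 1L + nr + m + s
  i_t <- 1L; i_l <- 1L + seq_len(nr); i_x <- 1L + nr + seq_len(m)
  i_y <- 1L + nr + m + seq_len(s)
  obj <- numeric(nv); obj[i_x] <- 1 / (m * xk)

  rows <- list(); dir <- character(0); rhs <- numeric(0)
  add <- function(r, d) { rows[[length(rows) + 1L]] <<- r
                          dir <<- c(dir, d); rhs <<- c(rhs, 0) }
  # normalization: (1/s) sum Ybar_c / y_ck = 1
  r <- numeric(nv); r[i_y] <- 1 / (s * yk)
  rows[[1]] <- r; dir <- "=="; rhs <- 1
  for (a in seq_len(m)) {           # Xbar_a >= sum lambda x_ab
    r <- numeric(nv); r[i_l] <- Xr[, a]; r[i_x[a]] <- -1; add(r, "<=")
  }
  for (c in seq_len(s)) {           # Ybar_c <= sum lambda y_cb
    r <- numeric(nv); r[i_l] <- Yr[, c]; r[i_y[c]] <- -1; add(r, ">=")
  }
  for (a in seq_len(m)) {           # Xbar_a >= t x_ak
    r <- numeric(nv); r[i_x[a]] <- 1; r[i_t] <- -xk[a]; add(r, ">=")
  }
  for (c in seq_len(s)) {           # Ybar_c <= t y_ck
    r <- numeric(nv); r[i_y[c]] <- 1; r[i_t] <- -yk[c]; add(r, "<=")
  }
  if (rts == "vrs") {
    r <- numeric(nv); r[i_l] <- 1; r[i_t] <- -1; add(r, "==")
  }
  sol <- solve_lp(obj, do.call(rbind, rows), dir, rhs)
  if (sol$status != "optimal")
    return(structure(list(delta = NA_real_,
                          projection_input = rep(NA_real_, m),
                          projection_output = rep(NA_real_, s),
                          lambda = rep(NA_real_, n), status = "infeasible"),
                     class = "super_sbm_result"))
  tt <- sol$x[i_t]
  lam <- numeric(n); lam[-k] <- sol$x[i_l] / tt
  names(lam) <- section$dmus
  structure(list(delta = sol$value,
                 projection_input = stats::setNames(sol$x[i_x] / tt * xk0,
                                                    colnames(X)),
                 projection_output = stats::setNames(sol$x[i_y] / tt * yk0,
                                                     colnames(Y)),
                 lambda = lam, status = "optimal"),
            class = "super_sbm_result")
}

#' Combined SBM / super-efficiency score
#'
#' The score a practitioner tabulates: the plain SBM `rho` for dominated
#' DMUs (`rho < 1`), and the super-efficiency `delta >= 1` for frontier
#' DMUs, so the whole column is comparable and efficient units are ranked.
#'
#' @inheritParams sbm_score
#' @param infeasible what to report when the super-efficiency program is
#'   infeasible: `"na"` (default; flag and omit) or `"clamp"` (report 1).
#' @param tol efficiency threshold for routing to the super model.
#' @return A list: `score`, `model` (`"sbm"` or `"super"`), `status`.
#' @export
combined_score <- function(k, section, rts = c("vrs", "crs"),
                           infeasible = c("na", "clamp"), tol = 1e-6) {
  rts <- match.arg(rts)
  infeasible <- match.arg(infeasible)
  base <- sbm_score(k, section, rts)
  if (base$status != "optimal")
    return(list(score = NA_real_, model = "sbm", status = base$status))
  if (base$rho < 1 - tol)
    return(list(score = base$rho, model = "sbm", status = "optimal"))
  sup <- super_sbm_score(k, section, rts)
  if (sup$status != "optimal") {
    sc <- if (infeasible == "clamp") 1 else NA_real_
    return(list(score = sc, model = "super", status = "infeasible"))
  }
  list(score = sup$delta, model = "super", status = "optimal")
}

#' Score matrix over all DMUs and periods
#'
#' Runs [combined_score()] on every DMU in every period cross-section and
#' assembles the DMU-by-period score matrix together with arithmetic DMU
#' means, period means and the grand mean (the layout of published
#' super-efficiency score tables). Scores are kept at full precision;
#' rounding belongs to rendering.
#'
#' @param panel a [panel_dataset()].
#' @inheritParams combined_score
#' @return An object of class `score_matrix`: `scores` (`n x T`),
#'   `dmu_means`, `period_means`, `grand_mean`, `model` (matrix of
#'   `"sbm"`/`"super"`), `status` (matrix). Cells whose super-efficiency
#'   program was infeasible are `NA` (with a warning) and means are taken
#'   over available cells.
#' @export
score_matrix <- function(panel, rts = c("vrs", "crs"),
                         infeasible = c("na", "clamp")) {
  rts <- match.arg(rts)
  infeasible <- match.arg(infeasible)
  stopifnot(inherits(panel, "panel_dataset"))
  scores <- matrix(NA_real_, panel$n, panel$T,
                   dimnames = list(panel$dmus, panel$periods))
  model <- status <- matrix(NA_character_, panel$n, panel$T,
                            dimnames = dimnames(scores))
  for (j in seq_along(panel$periods)) {
    sec <- cross_section(panel, panel$periods[j])
    for (i in seq_len(panel$n)) {
      cs <- combined_score(i, sec, rts, infeasible)
      scores[i, j] <- cs$score
      model[i, j] <- cs$model
      status[i, j] <- cs$status
    }
  }
  if (anyNA(scores))
    warning(sum(is.na(scores)),
            " cell(s) had no score (infeasible super-efficiency program);",
            " means use available cells")
  structure(c(summarize_scores(scores),
              list(model = model, status = status, rts = rts)),
            class = "score_matrix")
}

#' Summarize a DMU-by-period score matrix
#'
#' Arithmetic row (DMU), column (period) and grand means of a score matrix,
#' ignoring missing cells. Usable both on matrices this package computes and
#' on transcribed published tables.
#'
#' @param scores numeric `n x T` matrix, DMUs in rows.
#' @return A list: `scores`, `dmu_means`, `period_means`, `grand_mean`.
#' @export
summarize_scores <- function(scores) {
  scores <- as.matrix(scores)
  list(scores = scores,
       dmu_means = rowMeans(scores, na.rm = TRUE),
       period_means = colMeans(scores, na.rm = TRUE),
       grand_mean = mean(scores, na.rm = TRUE))
}

#' @export
print.score_matrix <- function(x, digits = 3, ...) {
  cat("Combined SBM / super-efficiency scores (", toupper(x$rts), ")\n",
      sep = "")
  tab <- cbind(round(x$scores, digits), Mean = round(x$dmu_means, digits))
  print(tab)
  cat("Period means:",
      paste(round(x$period_means, digits), collapse = " "), "\n")
  cat("Grand mean:", round(x$grand_mean, digits), "\n")
  invisible(x)
}

#' Input-redundancy / output-shortage projection report
#'
#' For every DMU scoring below 1 in the chosen period, reports the optimal
#' SBM slacks as input redundancy and output shortage, in measure units and
#' as percentages of the observed values (slack / observed x 100). Efficient
#' DMUs are excluded; a zero slack yields a zero percentage.
#'
#' @param panel a [panel_dataset()].
#' @param period period label to analyze.
#' @inheritParams sbm_score
#' @param tol efficiency threshold below which a DMU enters the report.
#' @return A data frame with one row per inefficient DMU: `dmu`, `score`,
#'   then for each input `<name>_excess` and `<name>_excess_pct`, and for
#'   each output `<name>_shortfall` and `<name>_shortfall_pct`.
#' @export
projection_report <- function(panel, period, rts = c("vrs", "crs"),
                              tol = 1e-6) {
  rts <- match.arg(rts)
  sec <- cross_section(panel, period)
  out <- list()
  for (i in seq_along(sec$dmus)) {
    r <- sbm_score(i, sec, rts)
    if (r$status != "optimal" || r$rho >= 1 - tol) next
    row <- list(dmu = sec$dmus[i], score = r$rho)
    for (a in seq_along(r$slack_input)) {
      nm <- names(r$slack_input)[a]
      row[[paste0(nm, "_excess")]] <- r$slack_input[[a]]
      row[[paste0(nm, "_excess_pct")]] <- 100 * r$slack_input[[a]] / sec$X[i, a]
    }
    for (c in seq_along(r$slack_output)) {
      nm <- names(r$slack_output)[c]
      row[[paste0(nm, "_shortfall")]] <- r$slack_output[[c]]
      row[[paste0(nm, "_shortfall_pct")]] <-
        100 * r$slack_output[[c]] / sec$Y[i, c]
    }
    out[[length(out) + 1L]] <- as.data.frame(row, check.names = FALSE)
  }
  if (!length(out)) {
    nm <- c("dmu", "score",
            as.vector(rbind(paste0(colnames(sec$X), "_excess"),
                            paste0(colnames(sec$X), "_excess_pct"))),
            as.vector(rbind(paste0(colnames(sec$Y), "_shortfall"),
                            paste0(colnames(sec$Y), "_shortfall_pct"))))
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(nm)), nm),
                        check.names = FALSE)
    df$dmu <- character(0)
    return(df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
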