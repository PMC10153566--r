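#' Radial (Farrell) distance of a point to a reference frontier
#'
#' Solves the radial envelopment LP of a single observation against the
#' frontier spanned by a reference cross-section. Output orientation finds
#' the largest proportional output expansion `phi` feasible at the observed
#' inputs (`X'lambda <= x`, `Y'lambda >= phi*y`); input orientation finds the
#' smallest proportional input contraction `theta` at the observed outputs.
#' Under variable returns to scale the convexity constraint `sum(lambda) = 1`
#' is added. The observation need not belong to the reference section, which
#' is what makes the cross-period distances of the Malmquist index possible.
#'
#' Bookkeeping convention: `efficiency` is the Farrell efficiency, i.e.
#' `theta` under input orientation and `1/phi` under output orientation, so
#' that a within-frontier observation has `efficiency <= 1` in both
#' orientations and a cross-period observation outside the frontier has
#' `efficiency > 1`. `distance` is the Shephard distance (`1/theta` for
#' input, `1/phi` for output orientation).
#'
#' @param x numeric input vector (length `m`), strictly positive.
#' @param y numeric output vector (length `s`), strictly positive.
#' @param reference a [cross_section()] providing the frontier.
#' @param orientation `"output"` (default) or `"input"`.
#' @param rts returns-to-scale assumption, `"vrs"` or `"crs"`.
#' @return A list of class `radial_score`: `efficiency`, `distance`,
#'   `lambda` (reference weights) and `status` (`"optimal"` or
#'   `"infeasible"`; cross-period VRS programs can be infeasible).
#' @examples
#' toy <- structure(list(period = 1L, dmus = c("A", "B"),
#'                       X = matrix(c(2, 4), 2, 1), Y = matrix(c(2, 2), 2, 1)),
#'                  class = "cross_section")
#' radial_distance(4, 2, toy, orientation = "input", rts = "vrs")$efficiency
#' @export
radial_distance <- function(x, y, reference,
                            orientation = c("output", "input"),
                            rts = c("vrs", "crs")) {
  orientation <- match.arg(orientation)
  rts <- match.arg(rts)
  stopifnot(inherits(reference, "cross_section"))
  X <- reference$X; Y <- reference$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  stopifnot(length(x) == m, length(y) == s, all(x > 0), all(y > 0),
            n >= 1L)
  # unit invariance: normalize columns by the evaluated point so the LP is
  # solved at O(1) magnitudes; phi/theta and lambda are unaffected
  X <- sweep(X, 2, x, "/"); Y <- sweep(Y, 2, y, "/")
  x <- rep(1, m); y <- rep(1, s)

  # variables: (factor, lambda_1..n); factor = phi (output) or theta (input)
  if (orientation == "output") {
    # max phi : X'l <= x ; Y'l - phi y >= 0
    A <- rbind(cbind(0, t(X)), cbind(-y, t(Y)))
    dir <- c(rep("<=", m), rep(">=", s))
    rhs <- c(x, rep(0, s))
    objsign <- TRUE
  } else {
    # min theta : X'l - theta x <= 0 ; Y'l >= y
    A <- rbind(cbind(-x, t(X)), cbind(0, t(Y)))
    dir <- c(rep("<=", m), rep(">=", s))
    rhs <- c(rep(0, m), y)
    objsign <- FALSE
  }
  if (rts == "vrs") {
    A <- rbind(A, c(0, rep(1, n)))
    dir <- c(dir, "==")
    rhs <- c(rhs, 1)
  }
  obj <- c(1, rep(0, n))
  sol <- solve_lp(obj, A, dir, rhs, maximize = objsign)
  if (sol$status != "optimal") {
    st <- if (sol$status == "infeasible") "infeasible" else sol$status
    if (st %in% c("unbounded", "maxit"))
      stop("radial LP did not solve (", st, ")")
    return(structure(list(efficiency = NA_real_, distance = NA_real_,
                          lambda = rep(NA_real_, n), status = "infeasible"),
                     class = "radial_score"))
  }
  f <- sol$value
  lambda <- sol$x[-1L]
  if (orientation == "output") {
    eff <- 1 / f; dist <- 1 / f
  } else {
    eff <- f; dist <- 1 / f
  }
  structure(list(efficiency = eff, distance = dist, lambda = lambda,
                 status = "optimal"),
            class = "radial_score")
}
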