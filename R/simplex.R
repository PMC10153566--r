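#' Solve a small dense linear program
#'
#' Minimizes \code{obj %*% x} subject to \code{A x (dir) rhs} and \code{x >= 0},
#' by the two-phase primal simplex method on a dense tableau with Bland's
#' anti-cycling rule. Intended for the small envelopment programs this package
#' builds (tens of variables and constraints), not for large-scale LP.
#'
#' @param obj numeric objective coefficients (length `n`).
#' @param A constraint matrix (`m x n`).
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"=="`.
#' @param rhs numeric right-hand sides (length `m`).
#' @param maximize if `TRUE`, maximize instead of minimize.
#' @param tol pivot / feasibility tolerance.
#' @param maxit iteration cap per phase.
#'
#' @return A list with elements `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"` or `"maxit"`), `x` (primal solution, length `n`) and
#'   `value` (objective value at `x`), the latter two `NA` unless optimal.
#' @keywords internal
solve_lp <- function(obj, A, dir, rhs, maximize = FALSE,
                     tol = 1e-9, maxit = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(dir) == m, length(rhs) == m,
            all(dir %in% c("<=", ">=", "==")))
  if (!all(is.finite(obj)) || !all(is.finite(A)) || !all(is.finite(rhs)))
    stop("solve_lp: nonfinite coefficients")
  obj0 <- obj
  if (maximize) obj <- -obj

  # normalize to nonnegative rhs
  flip <- rhs < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    rhs[flip] <- -rhs[flip]
    dir[flip] <- c("<=" = ">=", ">=" = "<=", "==" = "==")[dir[flip]]
  }

  n_slack <- sum(dir != "==")
  n_art <- sum(dir != "<=")
  ntot <- n + n_slack + n_art
  Tb <- matrix(0, m, ntot)
  Tb[, seq_len(n)] <- A
  basis <- integer(m)
  js <- n          # next slack column
  ja <- n + n_slack  # next artificial column
  art_cols <- integer(0)
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      js <- js + 1L
      Tb[i, js] <- 1
      basis[i] <- js
    } else if (dir[i] == ">=") {
      js <- js + 1L
      Tb[i, js] <- -1
      ja <- ja + 1L
      Tb[i, ja] <- 1
      basis[i] <- ja
      art_cols <- c(art_cols, ja)
    } else {
      ja <- ja + 1L
      Tb[i, ja] <- 1
      basis[i] <- ja
      art_cols <- c(art_cols, ja)
    }
  }
  b <- rhs

  # Bland pivoting on (Tb, b, basis) for cost vector cc over `active` columns.
  run_phase <- function(Tb, b, basis, cc, active) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(status = "maxit"))
      cb <- cc[basis]
      # reduced costs r_j = c_j - cb' Tb[, j]
      r <- cc - as.numeric(crossprod(Tb, cb))
      r[!active] <- Inf
      ent <- which(r < -tol)
      if (!length(ent)) {
        return(list(status = "optimal", Tb = Tb, b = b, basis = basis))
      }
      j <- ent[1L]  # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]  # Bland tie-break
      # pivot on (i, j)
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      b[i] <- b[i] / piv
      other <- setdiff(seq_len(m), i)
      f <- Tb[other, j]
      Tb[other, ] <- Tb[other, , drop = FALSE] - outer(f, Tb[i, ])
      b[other] <- b[other] - f * b[i]
      basis[i] <- j
    }
  }

  active <- rep(TRUE, ntot)
  if (n_art > 0L) {
    cc1 <- numeric(ntot)
    cc1[art_cols] <- 1
    ph1 <- run_phase(Tb, b, basis, cc1, active)
    if (ph1$status != "optimal")
      return(list(status = if (ph1$status == "maxit") "maxit" else "infeasible",
                  x = NA, value = NA))
    Tb <- ph1$Tb; b <- ph1$b; basis <- ph1$basis
    if (sum(b[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible", x = NA, value = NA))
    # drive remaining artificials out of the basis where possible
    for (i in which(basis %in% art_cols)) {
      cand <- which(abs(Tb[i, seq_len(n + n_slack)]) > tol)
      if (length(cand)) {
        j <- cand[1L]
        piv <- Tb[i, j]
        Tb[i, ] <- Tb[i, ] / piv
        b[i] <- b[i] / piv
        other <- setdiff(seq_len(m), i)
        f <- Tb[other, j]
        Tb[other, ] <- Tb[other, , drop = FALSE] - outer(f, Tb[i, ])
        b[other] <- b[other] - f * b[i]
        basis[i] <- j
      }
      # else: redundant row with zero artificial value; harmless to keep
    }
    active[art_cols] <- FALSE
  }

  cc2 <- numeric(ntot)
  cc2[seq_len(n)] <- obj
  ph2 <- run_phase(Tb, b, basis, cc2, active)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, x = NA, value = NA))
  x <- numeric(ntot)
  x[ph2$basis] <- ph2$b
  x <- x[seq_len(n)]
  val <- sum(obj0 * x)
  list(status = "optimal", x = x, value = val)
}
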