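# shared fixtures: toy cross-sections, random panels, and the brute-force
# SBM oracle used to validate the LP route

toy_section <- function(X, Y, dmus = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(dmus)) dmus <- paste0("d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("in", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("out", seq_len(ncol(Y)))
  structure(list(period = 1L, dmus = dmus, X = X, Y = Y),
            class = "cross_section")
}

# the 2-DMU toy behind the analytic derivations: A=(2,2) efficient,
# B=(4,2) dominated
ab_section <- function() toy_section(c(2, 4), c(2, 2), dmus = c("A", "B"))

tiny_schema <- function(m = 1, s = 1, p = 0) {
  panel_schema(inputs = paste0("in", seq_len(m)),
               outputs = paste0("out", seq_len(s)),
               covariates = if (p) paste0("z", seq_len(p)) else character(),
               dmu_column = "dmu", period_column = "period")
}

random_panel <- function(n = 5, periods = 3, m = 2, s = 2, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(dmu = paste0("d", seq_len(n)),
                      period = seq_len(periods) + 2000L)
  df <- cbind(grid,
              matrix(exp(rnorm(nrow(grid) * m, 0, 0.4)), nrow(grid), m,
                     dimnames = list(NULL, paste0("in", seq_len(m)))),
              matrix(exp(rnorm(nrow(grid) * s, 0, 0.4)), nrow(grid), s,
                     dimnames = list(NULL, paste0("out", seq_len(s)))))
  panel_dataset(df, tiny_schema(m, s))
}

# brute-force SBM oracle: grid lambda over the unit simplex (VRS), compute
# slacks in closed form per lambda, minimize the ratio objective; n <= 3
oracle_sbm_vrs <- function(k, X, Y, res = 1e-3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n <= 3)
  grid <- seq(0, 1, by = res)
  L <- switch(as.character(n),
              "1" = matrix(1, 1, 1),
              "2" = rbind(grid, 1 - grid),
              "3" = {
                g <- expand.grid(l1 = grid, l2 = grid)
                g <- g[g$l1 + g$l2 <= 1 + 1e-12, ]
                rbind(g$l1, g$l2, 1 - g$l1 - g$l2)
              })
  XL <- t(X) %*% L
  YL <- t(Y) %*% L
  xk <- X[k, ]; yk <- Y[k, ]
  feas <- colSums(XL <= xk + 1e-12) == ncol(X) &
    colSums(YL >= yk - 1e-12) == ncol(Y)
  if (!any(feas)) return(NA_real_)
  sin_ <- xk - XL[, feas, drop = FALSE]
  sout <- YL[, feas, drop = FALSE] - yk
  num <- 1 - colMeans(sin_ / xk)
  den <- 1 + colMeans(sout / yk)
  min(num / den)
}

random_oracle_instance <- function(seed) {
  set.seed(seed)
  n <- sample(1:3, 1); m <- sample(1:2, 1); s <- sample(1:2, 1)
  list(section = toy_section(matrix(exp(rnorm(n * m, 0, 0.5)), n, m),
                             matrix(exp(rnorm(n * s, 0, 0.5)), n, s)),
       k = sample(n, 1))
}
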