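#' Malmquist productivity record for one DMU and one adjacent period pair
#'
#' Computes the Fare-style adjacent-period Malmquist total factor
#' productivity index and its full decomposition from six radial distance
#' LPs: four CRS distances (each period's observation against each period's
#' frontier) and two within-period VRS distances. Writing `E_r(a)` for the
#' Farrell efficiency of the period-`a` observation against the period-`r`
#' CRS frontier and `V_a(a)` for its within-period VRS efficiency:
#' \deqn{EFFCH = E_{t+1}(t+1) / E_t(t)}
#' \deqn{TECHCH = \sqrt{\frac{E_t(t+1)}{E_{t+1}(t+1)} \cdot
#'                      \frac{E_t(t)}{E_{t+1}(t)}}}
#' \deqn{PECH = V_{t+1}(t+1) / V_t(t), \quad SECH = EFFCH / PECH,}
#' \deqn{TFPCH = EFFCH \times TECHCH.}
#' The product identities hold to machine precision by construction. Values
#' above 1 indicate improvement (catch-up, frontier progress, productivity
#' growth).
#'
#' @param panel a [panel_dataset()].
#' @param dmu DMU name or index.
#' @param t first period of the adjacent pair (`t`, `t+1`).
#' @param orientation passed to [radial_distance()]; `"output"` by default.
#' @return A list of class `malmquist_record`: `dmu`, `period_pair`,
#'   `effch`, `techch`, `pech`, `sech`, `tfpch`, `status`.
#' @references Fare, R., Grosskopf, S., Norris, M., Zhang, Z. (1994)
#'   Productivity growth, technical progress, and efficiency change in
#'   industrialized countries. American Economic Review 84.
#' @export
malmquist_record <- function(panel, dmu, t,
                             orientation = c("output", "input")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(panel, "panel_dataset"))
  if (is.character(dmu)) dmu <- match(dmu, panel$dmus)
  t <- as.integer(t)
  if (!(t %in% panel$periods) || !((t + 1L) %in% panel$periods))
    stop("need adjacent periods ", t, " and ", t + 1L, " in the panel")
  s1 <- cross_section(panel, t)
  s2 <- cross_section(panel, t + 1L)
  x1 <- s1$X[dmu, ]; y1 <- s1$Y[dmu, ]
  x2 <- s2$X[dmu, ]; y2 <- s2$Y[dmu, ]

  d <- function(x, y, ref, rts) radial_distance(x, y, ref, orientation, rts)
  e_t_t   <- d(x1, y1, s1, "crs")
  e_n_n   <- d(x2, y2, s2, "crs")
  e_t_n   <- d(x2, y2, s1, "crs")   # period t+1 obs vs period t frontier
  e_n_t   <- d(x1, y1, s2, "crs")
  v_t_t   <- d(x1, y1, s1, "vrs")
  v_n_n   <- d(x2, y2, s2, "vrs")
  parts <- list(e_t_t, e_n_n, e_t_n, e_n_t, v_t_t, v_n_n)
  if (any(vapply(parts, function(z) z$status != "optimal", logical(1))))
    return(structure(list(dmu = panel$dmus[dmu], period_pair = c(t, t + 1L),
                          effch = NA_real_, techch = NA_real_,
                          pech = NA_real_, sech = NA_real_, tfpch = NA_real_,
                          status = "infeasible"),
                     class = "malmquist_record"))
  effch <- e_n_n$efficiency / e_t_t$efficiency
  techch <- sqrt((e_t_n$efficiency / e_n_n$efficiency) *
                 (e_t_t$efficiency / e_n_t$efficiency))
  pech <- v_n_n$efficiency / v_t_t$efficiency
  sech <- effch / pech
  tfpch <- effch * techch
  structure(list(dmu = panel$dmus[dmu], period_pair = c(t, t + 1L),
                 effch = effch, techch = techch, pech = pech, sech = sech,
                 tfpch = tfpch, status = "optimal"),
            class = "malmquist_record")
}

#' Malmquist records for every DMU and adjacent period pair
#'
#' @param panel a [panel_dataset()].
#' @inheritParams malmquist_record
#' @return A data frame of class `malmquist_records` with columns `dmu`,
#'   `from`, `to`, `effch`, `techch`, `pech`, `sech`, `tfpch`, `status`.
#' @export
malmquist <- function(panel, orientation = c("output", "input")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(panel, "panel_dataset"))
  if (panel$T < 2L) stop("Malmquist needs at least two periods")
  rows <- list()
  for (t in panel$periods[-panel$T]) {
    for (d in panel$dmus) {
      r <- malmquist_record(panel, d, t, orientation)
      rows[[length(rows) + 1L]] <-
        data.frame(dmu = r$dmu, from = t, to = t + 1L, effch = r$effch,
                   techch = r$techch, pech = r$pech, sech = r$sech,
                   tfpch = r$tfpch, status = r$status)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("malmquist_records", "data.frame")
  out
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  exp(mean(log(x)))
}

#' Summarize Malmquist records by geometric means
#'
#' Aggregates the five indices by geometric means per period pair (across
#' DMUs), per DMU (across pairs) and overall, the convention of the DEAP
#' program's summary tables. Geometric averaging preserves the product
#' structure, so `tfpch = effch * techch` and `effch = pech * sech` hold for
#' every summary row too.
#'
#' @param records a `malmquist_records` data frame from [malmquist()], or
#'   any data frame with columns `dmu`, `from`, `to` and the five indices.
#' @return A list of class `malmquist_summary`: `by_period` (one row per
#'   adjacent pair plus a grand `Mean` row), `by_dmu`, `grand` (named vector
#'   of the five grand geometric means).
#' @export
summarize_malmquist <- function(records) {
  records <- as.data.frame(records)
  need <- c("dmu", "from", "to", "effch", "techch", "pech", "sech", "tfpch")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  idx <- c("effch", "techch", "pech", "sech", "tfpch")
  if (anyNA(records[idx])) stop("records contain missing index values")
  pairs <- unique(records[, c("from", "to")])
  dmus <- unique(records$dmu)
  cells <- table(records$dmu, records$from)
  if (any(cells != 1L))
    stop("unbalanced record set: each DMU needs exactly one record per ",
         "adjacent period pair")
  gm_rows <- function(split_by) {
    agg <- lapply(idx, function(v)
      tapply(records[[v]], split_by, geometric_mean))
    as.data.frame(stats::setNames(agg, idx))
  }
  by_period <- gm_rows(paste(records$from, records$to, sep = "-"))
  by_period <- by_period[order(rownames(by_period)), , drop = FALSE]
  by_dmu <- gm_rows(factor(records$dmu, levels = dmus))
  grand <- vapply(records[idx], geometric_mean, numeric(1))
  by_period <- rbind(by_period, Mean = as.list(grand))
  structure(list(by_period = by_period, by_dmu = by_dmu, grand = grand),
            class = "malmquist_summary")
}

#' @export
print.malmquist_summary <- function(x, digits = 3, ...) {
  cat("Malmquist index summary (geometric means)\n")
  print(round(x$by_period, digits))
  invisible(x)
}
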