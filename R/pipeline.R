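#' Read a pipeline run configuration
#'
#' A YAML file (or a plain list) with any of the keys: `panel` (CSV path),
#' `schema` (schema YAML path; omitted means [sichuan_schema()]), `output_dir`
#' (default `"."`), `rts` (`"vrs"`/`"crs"`), `orientation`
#' (`"output"`/`"input"`), `period` (for the projection report; default last
#' panel period), `seed`, `digits` (report rounding, default 3),
#' `tobit` (sub-keys `lower`, `upper`, `standardize`, `ci_level`), and
#' `generator` (overrides for [generator_config()] fields).
#'
#' @param config path to a YAML file, or a list of the same shape.
#' @return A normalized config list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- list(
    panel = config$panel %||% NULL,
    schema = config$schema %||% NULL,
    output_dir = config$output_dir %||% ".",
    rts = match.arg(config$rts %||% "vrs", c("vrs", "crs")),
    orientation = match.arg(config$orientation %||% "output",
                            c("output", "input")),
    period = config$period %||% NULL,
    seed = as.integer(config$seed %||% 42L),
    digits = as.integer(config$digits %||% 3L),
    tobit = config$tobit %||% list(),
    generator = config$generator %||% list())
  class(cfg) <- "run_config"
  cfg
}

load_run_schema <- function(cfg) {
  if (is.null(cfg$schema)) sichuan_schema() else read_schema(cfg$schema)
}

load_run_panel <- function(cfg) {
  if (is.null(cfg$panel)) stop("config needs a 'panel' CSV path")
  read_panel(cfg$panel, load_run_schema(cfg))
}

out_path <- function(cfg, name) {
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(cfg$output_dir, name)
}

#' Pipeline step: simulate a synthetic panel
#'
#' Writes `panel.csv` (readable by [read_panel()]) and `ground_truth.csv`
#' to the configured output directory.
#'
#' @param config a [run_config()] (list or YAML path).
#' @return Invisibly, the paths written.
#' @export
run_simulate <- function(config = list()) {
  cfg <- run_config(config)
  gc_args <- cfg$generator
  gc_args$seed <- cfg$seed
  gen <- generate_panel(do.call(generator_config, gc_args))
  p1 <- write_panel(gen$panel, out_path(cfg, "panel.csv"))
  p2 <- out_path(cfg, "ground_truth.csv")
  utils::write.csv(gen$truth, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Pipeline step: combined efficiency score table
#'
#' Writes `scores.csv` in the published layout: one DMU per row, one column
#' per year, a `Mean` column, and a final `Mean` row of period means (its
#' `Mean` cell is the grand mean). Scores are rounded to `digits` decimals
#' at this rendering stage only.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the path written; the full-precision `score_matrix`
#'   as attribute `"scores"`.
#' @export
run_scores <- function(config = list()) {
  cfg <- run_config(config)
  sm <- score_matrix(load_run_panel(cfg), rts = cfg$rts)
  tab <- cbind(as.data.frame(round(sm$scores, cfg$digits)),
               Mean = round(sm$dmu_means, cfg$digits))
  tab <- cbind(dmu = rownames(sm$scores), tab)
  mean_row <- c(list(dmu = "Mean"),
                as.list(round(c(sm$period_means, sm$grand_mean), cfg$digits)))
  names(mean_row) <- names(tab)
  tab <- rbind(tab, as.data.frame(mean_row, check.names = FALSE))
  path <- out_path(cfg, "scores.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  out <- invisible(path)
  attr(out, "scores") <- sm
  out
}

#' Pipeline step: Malmquist index tables
#'
#' Writes `malmquist_periods.csv` (per adjacent pair, geometric means across
#' DMUs, plus the grand `Mean` row) and `malmquist_dmus.csv` (per-DMU
#' geometric means across pairs).
#'
#' @inheritParams run_simulate
#' @return Invisibly, the paths written.
#' @export
run_malmquist <- function(config = list()) {
  cfg <- run_config(config)
  rec <- malmquist(load_run_panel(cfg), orientation = cfg$orientation)
  sm <- summarize_malmquist(rec)
  bp <- cbind(period = rownames(sm$by_period),
              round(sm$by_period, cfg$digits))
  bd <- cbind(dmu = rownames(sm$by_dmu), round(sm$by_dmu, cfg$digits))
  p1 <- out_path(cfg, "malmquist_periods.csv")
  p2 <- out_path(cfg, "malmquist_dmus.csv")
  utils::write.csv(bp, p1, row.names = FALSE)
  utils::write.csv(bd, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Pipeline step: projection (redundancy / shortage) report
#'
#' Writes `projection.csv` for the configured period (default: the last
#' panel period), slack amounts at full precision and percentages rounded
#' to two decimals.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the path written.
#' @export
run_projection <- function(config = list()) {
  cfg <- run_config(config)
  panel <- load_run_panel(cfg)
  period <- cfg$period %||% max(panel$periods)
  rep <- projection_report(panel, period, rts = cfg$rts)
  pct <- grep("_pct$", names(rep))
  rep[pct] <- lapply(rep[pct], round, 2)
  path <- out_path(cfg, "projection.csv")
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline step: Tobit regression of scores on covariates
#'
#' Scores the panel, stacks all DMU-periods (N = n x T), regresses the
#' combined score on the schema's covariates by ML Tobit, and writes
#' `tobit.csv` in the published layout (coefficient, SE, T-ratio, p, CI,
#' then sigma, log-likelihood and the LR chi-square rows).
#'
#' @inheritParams run_simulate
#' @return Invisibly, the path written; the `tobit_fit` as attribute
#'   `"fit"`.
#' @export
run_tobit <- function(config = list()) {
  cfg <- run_config(config)
  panel <- load_run_panel(cfg)
  sm <- score_matrix(panel, rts = cfg$rts)
  y <- as.vector(t(sm$scores))  # (dmu, period) row order of panel$data
  Z <- covariate_matrix(panel)
  keep <- !is.na(y)
  ts <- cfg$tobit
  fit <- fit_tobit(Z[keep, , drop = FALSE], y[keep],
                   lower = ts$lower %||% 0, upper = ts$upper %||% Inf,
                   standardize = isTRUE(ts$standardize),
                   ci_level = ts$ci_level %||% 0.95)
  tab <- tobit_table(fit)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, cfg$digits)
  extra <- data.frame(variable = c("Log-likelihood", "LR chi2", "Prob>chi2",
                                   "N", "N censored"),
                      coefficient = round(c(fit$loglik, fit$lr_chi2,
                                            fit$lr_p, fit$n_obs,
                                            fit$n_censored_low +
                                              fit$n_censored_high), 3),
                      se = NA, t_ratio = NA, p = NA,
                      ci_lower = NA, ci_upper = NA)
  tab <- rbind(tab, extra)
  path <- out_path(cfg, "tobit.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  out <- invisible(path)
  attr(out, "fit") <- fit
  out
}
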