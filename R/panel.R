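#' Define a panel schema
#'
#' A schema assigns each measure column of a long-format panel a role:
#' input, output or contextual covariate. Inputs and outputs enter the
#' envelopment models and must be strictly positive; covariates feed the
#' second-stage Tobit regression and may take any real value.
#'
#' @param inputs character vector of input column names (length `m >= 1`).
#' @param outputs character vector of output column names (length `s >= 1`).
#' @param covariates character vector of covariate column names (may be empty).
#' @param dmu_column name of the column identifying the decision-making unit.
#' @param period_column name of the integer period (year) column.
#' @param units optional named character vector mapping measure names to
#'   unit strings, for report labelling only.
#'
#' @return An object of class `panel_schema`.
#' @examples
#' sichuan_schema()
#' @export
panel_schema <- function(inputs, outputs, covariates = character(),
                         dmu_column = "dmu", period_column = "period",
                         units = NULL) {
  inputs <- as.character(inputs); outputs <- as.character(outputs)
  covariates <- as.character(covariates)
  if (length(inputs) < 1L) stop("schema needs at least one input")
  if (length(outputs) < 1L) stop("schema needs at least one output")
  nm <- c(inputs, outputs, covariates, dmu_column, period_column)
  if (anyDuplicated(nm))
    stop("schema names must be disjoint across roles; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(inputs = inputs, outputs = outputs, covariates = covariates,
                 dmu_column = dmu_column, period_column = period_column,
                 units = units),
            class = "panel_schema")
}

#' Schema used by the provincial health-resource study
#'
#' Three inputs (health technicians, beds, total expenditure), two outputs
#' (total visits, discharges) and five covariates (per-capita GDP, average
#' annual income, urbanization rate, population density, education level).
#'
#' @return A [panel_schema()].
#' @export
sichuan_schema <- function() {
  panel_schema(
    inputs = c("health_technicians", "beds", "total_expenditure"),
    outputs = c("total_visits", "discharges"),
    covariates = c("pgdp", "avg_income", "urbanization", "pop_density",
                   "education"),
    dmu_column = "city", period_column = "year",
    units = c(health_technicians = "person", beds = "quantity",
              total_expenditure = "10k yuan", total_visits = "person",
              discharges = "person", pgdp = "yuan", avg_income = "yuan",
              urbanization = "%", pop_density = "person/sq.km",
              education = "person"))
}

#' Read a panel schema from a YAML config file
#'
#' The file holds keys `inputs`, `outputs`, `covariates` (lists of column
#' names) and scalar `dmu_column`, `period_column`.
#'
#' @param path path to the YAML file.
#' @return A [panel_schema()].
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("inputs", "outputs"))
    if (is.null(cfg[[k]])) stop("schema config missing key: ", k)
  panel_schema(inputs = unlist(cfg$inputs), outputs = unlist(cfg$outputs),
               covariates = unlist(cfg$covariates %||% character()),
               dmu_column = cfg$dmu_column %||% "dmu",
               period_column = cfg$period_column %||% "period")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a validated panel dataset
#'
#' A balanced DMU-by-period panel with role-tagged measures. The data frame
#' must contain one row per (dmu, period) combination; inputs and outputs
#' must be strictly positive (the SBM objective divides by them), periods
#' must be consecutive integers, and no cell may be missing. Rows are
#' normalized to (dmu, period) order with the DMU order of first appearance.
#'
#' @param data long-format data frame.
#' @param schema a [panel_schema()].
#' @return An object of class `panel_dataset` with elements `data` (the
#'   normalized data frame), `schema`, `dmus`, `periods` and dimensions
#'   `n`, `T`, `m`, `s`, `p`.
#' @export
panel_dataset <- function(data, schema) {
  stopifnot(inherits(schema, "panel_schema"))
  data <- as.data.frame(data)
  need <- c(schema$dmu_column, schema$period_column, schema$inputs,
            schema$outputs, schema$covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "))
  data <- data[, need, drop = FALSE]

  dcol <- schema$dmu_column; pcol <- schema$period_column
  data[[pcol]] <- as.integer(data[[pcol]])
  dmus <- unique(as.character(data[[dcol]]))
  periods <- sort(unique(data[[pcol]]))
  if (length(periods) > 1L && any(diff(periods) != 1L))
    stop("periods must be consecutive integers; got gaps at: ",
         paste(periods[which(diff(periods) != 1L)], collapse = ", "))

  meas <- c(schema$inputs, schema$outputs, schema$covariates)
  bad_na <- meas[vapply(data[meas], anyNA, logical(1))]
  if (length(bad_na))
    stop("missing values in column(s): ", paste(bad_na, collapse = ", "),
         " (the panel must be complete; drop incomplete DMUs upstream)")

  key <- paste(data[[dcol]], data[[pcol]], sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (dmu, period) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  full <- as.vector(outer(dmus, periods, paste, sep = "\r"))
  gaps <- setdiff(full, key)
  if (length(gaps))
    stop("panel is unbalanced; missing (dmu, period) cells: ",
         paste(gsub("\r", "/", utils::head(gaps, 10)), collapse = ", "))

  for (v in c(schema$inputs, schema$outputs)) {
    bad <- which(data[[v]] <= 0)
    if (length(bad))
      stop("nonpositive value in '", v, "' at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           " (inputs and outputs must be strictly positive)")
  }

  ord <- order(match(as.character(data[[dcol]]), dmus), data[[pcol]])
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  structure(list(data = data, schema = schema, dmus = dmus, periods = periods,
                 n = length(dmus), T = length(periods),
                 m = length(schema$inputs), s = length(schema$outputs),
                 p = length(schema$covariates)),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", x$n, "DMUs x", x$T, "periods (",
      min(x$periods), "-", max(x$periods), ")\n")
  cat("  inputs:    ", paste(x$schema$inputs, collapse = ", "), "\n")
  cat("  outputs:   ", paste(x$schema$outputs, collapse = ", "), "\n")
  if (x$p)
    cat("  covariates:", paste(x$schema$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format panel CSV
#'
#' Expects a UTF-8 comma-separated file with a header row containing the
#' DMU and period columns plus every measure named in the schema. Validation
#' (balance, positivity, consecutive periods) happens in [panel_dataset()].
#'
#' @param path file path or connection.
#' @inheritParams panel_dataset
#' @return A [panel_dataset()].
#' @export
read_panel <- function(path, schema) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  panel_dataset(df, schema)
}

#' Write a panel to CSV
#'
#' Serializes at full double precision so that
#' `read_panel(write_panel(p), schema)` reproduces `p` exactly.
#'
#' @param panel a [panel_dataset()].
#' @param path file path or connection.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_dataset"))
  df <- panel$data
  meas <- c(panel$schema$inputs, panel$schema$outputs, panel$schema$covariates)
  for (v in meas) df[[v]] <- format(df[[v]], digits = 17, trim = TRUE,
                                    scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract one period's cross-section
#'
#' @param panel a [panel_dataset()].
#' @param period a period label present in `panel$periods`.
#' @return An object of class `cross_section` with `X` (`n x m`), `Y`
#'   (`n x s`), `dmus` and `period`; row order matches the panel's DMU order.
#' @export
cross_section <- function(panel, period) {
  stopifnot(inherits(panel, "panel_dataset"))
  period <- as.integer(period)
  if (!period %in% panel$periods)
    stop("unknown period ", period, "; panel covers ",
         min(panel$periods), "-", max(panel$periods))
  d <- panel$data
  rows <- d[[panel$schema$period_column]] == period
  sl <- d[rows, , drop = FALSE]
  sl <- sl[match(panel$dmus, sl[[panel$schema$dmu_column]]), , drop = FALSE]
  X <- as.matrix(sl[, panel$schema$inputs, drop = FALSE])
  Y <- as.matrix(sl[, panel$schema$outputs, drop = FALSE])
  rownames(X) <- rownames(Y) <- panel$dmus
  structure(list(period = period, dmus = panel$dmus, X = X, Y = Y),
            class = "cross_section")
}

#' Covariate matrix of a panel
#'
#' Returns the `(n*T) x p` covariate matrix in (dmu, period) row order,
#' for use as the Tobit design.
#'
#' @param panel a [panel_dataset()].
#' @return numeric matrix with one row per DMU-period.
#' @export
covariate_matrix <- function(panel) {
  stopifnot(inherits(panel, "panel_dataset"))
  as.matrix(panel$data[, panel$schema$covariates, drop = FALSE])
}
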