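#' Published super-efficiency score table (Sichuan, 2010-2018)
#'
#' The 19-city by 9-year matrix of combined SBM / super-efficiency scores
#' reported by the provincial health-resource study this package's models
#' follow, transcribed at the published 3-decimal precision. The underlying
#' yearbook inputs are not machine-readable, so the table itself is the
#' reference object: its row, column and grand means are reproducible
#' summary statistics (grand mean 1.041; the 2013 column mean 0.683 marks
#' the earthquake-year dip).
#'
#' @return A numeric `19 x 9` matrix, cities in rows, years in columns.
#' @seealso [summarize_scores()]
#' @export
sichuan_scores <- function() {
  path <- system.file("extdata", "sichuan_super_sbm_scores.csv",
                      package = "healtheff", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$city
  m
}

#' Published Malmquist index table (Sichuan, 2010-2018)
#'
#' The eight adjacent-period rows of the published Malmquist decomposition
#' (EFFCH, TECHCH, PECH, SECH, TFPCH) for the same study, at the published
#' 3-decimal precision. Geometric means of the columns reproduce the
#' published Mean row (TFPCH 0.950, EFFCH 1.007); arithmetic means do not
#' (TFPCH 0.951), which pins down the geometric-mean convention.
#'
#' @return A data frame with columns `from`, `to`, `effch`, `techch`,
#'   `pech`, `sech`, `tfpch`.
#' @seealso [summarize_malmquist()]
#' @export
sichuan_malmquist <- function() {
  path <- system.file("extdata", "sichuan_malmquist_index.csv",
                      package = "healtheff", mustWork = TRUE)
  utils::read.csv(path)
}
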