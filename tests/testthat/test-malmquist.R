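one_dmu_panel <- function(x, y) {
  panel_dataset(data.frame(dmu = "a", period = seq_along(x),
                           in1 = x, out1 = y), tiny_schema())
}

test_that("one-DMU doubling toy: frontier shift carries all the change", {
  p <- one_dmu_panel(c(2, 2), c(2, 4))
  r <- malmquist_record(p, "a", 1)
  expect_equal(r$tfpch, 2)
  expect_equal(r$effch, 1)
  expect_equal(r$techch, 2)
  expect_equal(r$pech, 1)
  expect_equal(r$sech, 1)
})

test_that("a static panel yields all indices exactly one", {
  df <- expand.grid(dmu = paste0("d", 1:4), period = 1:3)
  set.seed(2)
  vals <- data.frame(in1 = runif(4, 1, 3), out1 = runif(4, 1, 3))
  df <- cbind(df, vals[rep(1:4, 3), ])
  p <- panel_dataset(df, tiny_schema())
  rec <- malmquist(p)
  for (v in c("effch", "techch", "pech", "sech", "tfpch"))
    expect_equal(rec[[v]], rep(1, nrow(rec)), tolerance = 1e-9)
  s <- summarize_malmquist(rec)
  expect_equal(unname(s$grand), rep(1, 5), tolerance = 1e-9)
})

test_that("decomposition identities hold to machine precision per record", {
  p <- random_panel(n = 5, periods = 4, seed = 9)
  rec <- malmquist(p)
  expect_true(all(rec$status == "optimal"))
  expect_true(all(rec$effch > 0 & rec$techch > 0 & rec$tfpch > 0))
  expect_equal(rec$tfpch, rec$effch * rec$techch, tolerance = 1e-12)
  expect_equal(rec$effch, rec$pech * rec$sech, tolerance = 1e-12)
})

test_that("CRS indices are invariant to scaling one DMU in both periods", {
  p <- random_panel(n = 5, periods = 2, seed = 13)
  r0 <- malmquist_record(p, "d2", p$periods[1])
  d <- p$data
  rows <- d$dmu == "d2"
  d[rows, c("in1", "in2", "out1", "out2")] <-
    d[rows, c("in1", "in2", "out1", "out2")] * 3.7
  p2 <- panel_dataset(d, p$schema)
  r1 <- malmquist_record(p2, "d2", p$periods[1])
  expect_equal(r1$effch, r0$effch, tolerance = 1e-7)
  expect_equal(r1$techch, r0$techch, tolerance = 1e-7)
  expect_equal(r1$tfpch, r0$tfpch, tolerance = 1e-7)
})

test_that("Hicks-neutral technology growth is recovered by TECHCH", {
  cfg <- generator_config(seed = 17, n_dmus = 10, n_periods = 3,
                          tech_growth = 0.04, input_growth = 0.05,
                          inefficiency_coefs = rep(0, 5))
  gen <- generate_panel(cfg)
  rec <- malmquist(gen$panel)
  expect_equal(rec$techch, rep(1.04, nrow(rec)), tolerance = 1e-6)
  # sign property: pure technology regress pushes TFPCH below one
  cfg2 <- generator_config(seed = 17, n_dmus = 10, n_periods = 3,
                           tech_growth = -0.06, input_growth = 0.05,
                           inefficiency_coefs = rep(0, 5))
  rec2 <- malmquist(generate_panel(cfg2)$panel)
  expect_true(all(rec2$tfpch < 1))
})

test_that("geometric summary means preserve the product structure", {
  p <- random_panel(n = 4, periods = 3, seed = 21)
  s <- summarize_malmquist(malmquist(p))
  for (tab in list(s$by_period, s$by_dmu)) {
    expect_equal(tab$tfpch, tab$effch * tab$techch, tolerance = 1e-12)
    expect_equal(tab$effch, tab$pech * tab$sech, tolerance = 1e-12)
  }
  # grand geometric mean equals the geometric mean of per-pair means
  per_pair <- s$by_period[rownames(s$by_period) != "Mean", "tfpch"]
  expect_equal(geometric_mean(per_pair), s$grand[["tfpch"]],
               tolerance = 1e-12)
})

test_that("summaries demand a balanced record set", {
  p <- random_panel(n = 4, periods = 3, seed = 22)
  rec <- malmquist(p)
  expect_error(summarize_malmquist(rec[-3, ]), "unbalanced")
})

test_that("published index table: geometric means reproduce the Mean row", {
  tab <- sichuan_malmquist()
  expect_equal(round(geometric_mean(tab$tfpch), 3), 0.950)
  expect_equal(round(geometric_mean(tab$effch), 3), 1.007)
  expect_equal(round(geometric_mean(tab$techch), 3), 0.943)
  expect_equal(round(geometric_mean(tab$pech), 3), 1.005)
  expect_equal(round(geometric_mean(tab$sech), 3), 1.002)
  # arithmetic averaging would NOT reproduce the published TFPCH mean,
  # which pins down the geometric convention
  expect_equal(round(mean(tab$tfpch), 3), 0.951)
})
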