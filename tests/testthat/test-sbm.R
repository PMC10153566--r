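test_that("analytic SBM toys solve exactly", {
  sec <- ab_section()
  b <- sbm_score("B", sec, "vrs")
  expect_equal(b$rho, 0.5)  # (1 - 2/4) / (1 + 0)
  expect_equal(unname(b$slack_input), 2)
  expect_equal(unname(b$slack_output), 0)
  expect_equal(unname(b$lambda), c(1, 0))

  a <- sbm_score("A", sec, "vrs")
  expect_equal(a$rho, 1)
  expect_equal(max(a$slack_input, a$slack_output), 0)

  # duplicated frontier DMU still scores 1 (zero-slack twin solution)
  tw <- toy_section(c(2, 2, 4), c(2, 2, 2))
  expect_equal(sbm_score(1, tw, "vrs")$rho, 1)
  expect_equal(sbm_score(2, tw, "vrs")$rho, 1)
})

test_that("analytic super-efficiency toys solve exactly", {
  sup <- super_sbm_score("A", ab_section(), "vrs")
  expect_equal(sup$delta, 2)  # xbar = 4 forced by reference {B}
  expect_equal(unname(sup$projection_input), 4)
  expect_equal(unname(sup$projection_output), 2)

  tw <- toy_section(c(2, 2), c(2, 2))
  expect_equal(super_sbm_score(1, tw, "vrs")$delta, 1)  # twin reference

  lone <- toy_section(2, 2)
  expect_equal(super_sbm_score(1, lone, "vrs")$status, "infeasible")
})

test_that("LP rho matches the simplex-grid oracle on random instances", {
  # full 200-instance sweep runs in the acceptance suite; this spot-check
  # keeps the unit file fast
  for (seed in 1:40) {
    inst <- random_oracle_instance(seed)
    lp <- sbm_score(inst$k, inst$section, "vrs")$rho
    oracle <- oracle_sbm_vrs(inst$k, inst$section$X, inst$section$Y)
    expect_equal(lp, oracle, tolerance = 2e-3)
  }
})

test_that("rho lies in (0,1] and equals 1 exactly when slacks vanish", {
  for (seed in 1:10) {
    p <- random_panel(n = 6, periods = 1, seed = 300 + seed)
    sec <- cross_section(p, p$periods[1])
    for (i in 1:6) {
      r <- sbm_score(i, sec, "vrs")
      expect_gt(r$rho, 0)
      expect_lte(r$rho, 1 + 1e-9)
      slackless <- max(r$slack_input / sec$X[i, ],
                       r$slack_output / sec$Y[i, ]) <= 1e-6
      expect_equal(r$rho >= 1 - 1e-6, slackless)
      # feasibility identity: reference combination + slacks = observed
      expect_equal(drop(t(sec$X) %*% r$lambda) + r$slack_input,
                   sec$X[i, ], tolerance = 1e-7)
      expect_equal(drop(t(sec$Y) %*% r$lambda) - r$slack_output,
                   sec$Y[i, ], tolerance = 1e-7)
    }
  }
})

test_that("rho and delta are invariant to column rescaling", {
  p <- random_panel(n = 6, periods = 1, seed = 7)
  sec <- cross_section(p, p$periods[1])
  sec2 <- sec
  sec2$X <- sweep(sec$X, 2, c(1e5, 0.003), "*")
  sec2$Y <- sweep(sec$Y, 2, c(40, 2e6), "*")
  for (i in 1:6) for (rts in c("vrs", "crs")) {
    expect_equal(sbm_score(i, sec, rts)$rho, sbm_score(i, sec2, rts)$rho,
                 tolerance = 1e-7)
    c1 <- combined_score(i, sec, rts)
    c2 <- combined_score(i, sec2, rts)
    expect_equal(c1$score, c2$score, tolerance = 1e-7)
  }
})

test_that("worsening an input cannot raise rho; super rises as input falls", {
  sec <- toy_section(matrix(c(2, 4, 3, 2, 3, 5), 3, 2),
                     matrix(c(2, 2, 2.5, 3, 2, 4), 3, 2))
  base <- sbm_score(2, sec, "vrs")$rho
  expect_lt(base, 1)
  worse <- sec
  worse$X[2, 1] <- worse$X[2, 1] * 1.5
  expect_lte(sbm_score(2, worse, "vrs")$rho, base + 1e-9)

  sup0 <- super_sbm_score("A", ab_section(), "vrs")$delta
  better <- ab_section()
  better$X[1, 1] <- 1  # frontier DMU moves further outside the others' hull
  sup1 <- super_sbm_score(1, better, "vrs")$delta
  expect_gte(sup1, sup0 - 1e-9)
})

test_that("combined score routes below-1 to SBM and frontier to super", {
  sec <- ab_section()
  cb <- combined_score("B", sec, "vrs")
  expect_equal(cb$model, "sbm")
  expect_equal(cb$score, 0.5)
  ca <- combined_score("A", sec, "vrs")
  expect_equal(ca$model, "super")
  expect_equal(ca$score, 2)
  # infeasible super policy: flag-and-omit vs clamp
  lone_panel <- panel_dataset(
    data.frame(dmu = "a", period = 1, in1 = 2, out1 = 2), tiny_schema())
  lone <- cross_section(lone_panel, 1)
  expect_true(is.na(combined_score(1, lone, "vrs")$score))
  expect_equal(combined_score(1, lone, "vrs", infeasible = "clamp")$score, 1)
})

test_that("score matrix of an all-identical panel is all ones", {
  df <- expand.grid(dmu = paste0("d", 1:4), period = 1:3)
  df$in1 <- 3; df$out1 <- 5
  p <- panel_dataset(df, tiny_schema())
  sm <- score_matrix(p, "vrs")
  expect_equal(unname(sm$scores), matrix(1, 4, 3))
  expect_equal(sm$grand_mean, 1)
  expect_equal(unname(sm$dmu_means), rep(1, 4))
})

test_that("projection report covers exactly the sub-frontier DMUs", {
  df <- expand.grid(dmu = c("A", "B"), period = 1)
  df$in1 <- c(2, 4); df$out1 <- c(2, 2)
  p <- panel_dataset(df, tiny_schema())
  rep_ <- projection_report(p, 1, "vrs")
  expect_equal(rep_$dmu, "B")  # the efficient DMU is excluded
  expect_equal(rep_$in1_excess, 2)
  expect_equal(rep_$in1_excess_pct, 50)
  expect_equal(rep_$out1_shortfall_pct, 0)  # zero slack -> zero percentage

  # percentage convention: slack / observed x 100 at 2 decimals
  expect_equal(round(633.72 / 24096.2 * 100, 2), 2.63)

  # an efficient-only panel yields an empty report
  df2 <- expand.grid(dmu = c("A", "B"), period = 1)
  df2$in1 <- c(2, 2); df2$out1 <- c(2, 2)
  p2 <- panel_dataset(df2, tiny_schema())
  expect_equal(nrow(projection_report(p2, 1, "vrs")), 0)
})
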