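# Twin analyses: double-entry ICC, Falconer and ML ACE, between/within.

test_that("double-entry ICC matches hand computation and is symmetric", {
  tp <- twin_pairs(1:3, rep("MZ", 3), c(1, 2, 3), c(2, 1, 3))
  icc <- intraclass_correlation(tp, "MZ")
  # double entry: x = (1,2,3,2,1,3), y = (2,1,3,1,2,3) -> Pearson r = 0.5
  expect_equal(icc$r, 0.5, tolerance = 1e-12)
  expect_equal(icc$r, cor(c(tp$value1, tp$value2), c(tp$value2, tp$value1)))

  # swapping twin order within any pair leaves the statistic unchanged
  tp2 <- twin_pairs(1:3, rep("MZ", 3), c(2, 2, 3), c(1, 1, 3))
  tp3 <- twin_pairs(1:3, rep("MZ", 3), c(1, 2, 3), c(2, 1, 3))
  tp3[1, c("value1", "value2")] <- tp3[1, c("value2", "value1")]
  expect_equal(intraclass_correlation(tp3, "MZ")$r,
               intraclass_correlation(tp, "MZ")$r, tolerance = 1e-12)

  # perfectly concordant pairs
  tpc <- twin_pairs(1:4, rep("MZ", 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(intraclass_correlation(tpc, "MZ")$r, 1)

  # independent members over seeds stay within 3 SE of zero
  set.seed(50)
  tpn <- twin_pairs(1:500, rep("DZ", 500), rnorm(500), rnorm(500))
  expect_lt(abs(intraclass_correlation(tpn, "DZ")$r), 3 / sqrt(500))

  expect_error(intraclass_correlation(tp[1:2, ], "MZ"), "at least 3")
})

test_that("Falconer decomposition reproduces its closed forms", {
  f <- falconer_decomposition(0.87, 0.52)
  expect_equal(c(f$a2, f$c2, f$e2), c(0.70, 0.17, 0.13), tolerance = 1e-12)
  expect_false(f$truncated)

  f0 <- falconer_decomposition(0, 0)
  expect_equal(c(f0$a2, f0$c2, f0$e2), c(0, 0, 1))

  f1 <- falconer_decomposition(1, 0.5)
  expect_equal(c(f1$a2, f1$c2, f1$e2), c(1, 0, 0))

  # components sum to 1 before truncation for arbitrary correlations
  set.seed(51)
  for (i in 1:20) {
    rmz <- runif(1, -1, 1); rdz <- runif(1, -1, 1)
    raw <- c(2 * (rmz - rdz), 2 * rdz - rmz, 1 - rmz)
    expect_equal(sum(raw), 1, tolerance = 1e-12)
  }

  # rDZ > rMZ forces a negative a2: truncated and renormalized
  expect_message(ft <- falconer_decomposition(0.2, 0.5), "truncated")
  expect_true(ft$truncated)
  expect_gte(ft$a2, 0)
  expect_equal(ft$a2 + ft$c2 + ft$e2, 1, tolerance = 1e-12)
})

test_that("ML ACE recovers simulated variance fractions", {
  cfg <- sim_config(n_mz = 3000, n_dz = 3000, n_probes = 10,
                    score_ace = c(0.5, 0.2, 0.3),
                    within_slope_mz = 0, within_slope_pooled = 0)
  tw <- simulate_twins(cfg, seed = 52, betas = FALSE)
  ph <- tw$phenotype; ph$score <- tw$truth$score
  tp <- pairs_from_long(ph, "score")
  fit <- ml_ace_fit(tp)
  expect_lt(abs(fit$a2 - 0.5), 0.04)
  expect_lt(abs(fit$c2 - 0.2), 0.04)
  expect_lt(abs(fit$e2 - 0.3), 0.02)
  expect_equal(fit$a2 + fit$c2 + fit$e2, 1, tolerance = 1e-8)
  # profile CIs bracket the estimates
  expect_true(fit$ci["a2", 1] < fit$a2 && fit$a2 < fit$ci["a2", 2])
  expect_true(fit$ci["e2", 1] < fit$e2 && fit$e2 < fit$ci["e2", 2])
})

test_that("ML ACE sits near the boundary for pure-noise twins", {
  set.seed(53)
  tp <- twin_pairs(1:800, rep(c("MZ", "DZ"), each = 400),
                   rnorm(800), rnorm(800))
  fit <- ml_ace_fit(tp, ci = FALSE)
  expect_lt(fit$a2 + fit$c2, 0.1)
  expect_gt(fit$e2, 0.9)
})

test_that("ML ACE agrees with Falconer at the realized correlations", {
  cfg <- sim_config(n_mz = 4000, n_dz = 4000, n_probes = 10,
                    within_slope_mz = 0, within_slope_pooled = 0)
  tw <- simulate_twins(cfg, seed = 54, betas = FALSE)
  ph <- tw$phenotype; ph$score <- tw$truth$score
  tp <- pairs_from_long(ph, "score")
  rmz <- intraclass_correlation(tp, "MZ")$r
  rdz <- intraclass_correlation(tp, "DZ")$r
  fal <- falconer_decomposition(rmz, rdz)
  fit <- ml_ace_fit(tp, ci = FALSE)
  expect_lt(abs(fit$a2 - fal$a2), 0.02)
  expect_lt(abs(fit$c2 - fal$c2), 0.02)
  expect_lt(abs(fit$e2 - fal$e2), 0.02)
})

test_that("between/within decomposition matches constructed effects", {
  # outcome driven purely by the within-pair deviation at slope 0.18
  set.seed(55)
  pred1 <- rnorm(50, 10, 3); pred2 <- rnorm(50, 10, 3)
  pm <- (pred1 + pred2) / 2
  tp <- twin_pairs(1:50, rep(c("MZ", "DZ"), 25),
                   0.18 * (pred1 - pm), 0.18 * (pred2 - pm),
                   pred1 = pred1, pred2 = pred2)
  bw <- suppressWarnings(between_within_decomposition(tp))  # exact fit
  expect_equal(bw$table$estimate[bw$table$term == "within"], 0.18,
               tolerance = 1e-10)

  # predictor identical within every pair: within effect undefined
  tpd <- twin_pairs(1:10, rep("MZ", 10), rnorm(10), rnorm(10),
                    pred1 = 1:10, pred2 = 1:10)
  expect_error(between_within_decomposition(tpd), "identical within")
})

test_that("between/within matches an explicit decomposed design matrix", {
  tp <- twin_pairs(1:3, rep("MZ", 3),
                   value1 = c(1.0, 2.5, 0.3), value2 = c(2.0, 1.5, 0.9),
                   pred1 = c(4, 9, 1), pred2 = c(6, 5, 3))
  bw <- between_within_decomposition(tp)
  pm <- (tp$pred1 + tp$pred2) / 2
  X <- cbind(1, c(pm, pm), c(tp$pred1 - pm, tp$pred2 - pm))
  y <- c(tp$value1, tp$value2)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(bw$table$estimate, unname(beta[2:3]), tolerance = 1e-10)
})

test_that("MZ within coefficient equals the pair-difference regression", {
  set.seed(56)
  n <- 80
  pred1 <- rnorm(n); pred2 <- rnorm(n)
  v1 <- 0.3 * pred1 + rnorm(n, 0, 0.4)
  v2 <- 0.3 * pred2 + rnorm(n, 0, 0.4)
  tp <- twin_pairs(1:n, rep("MZ", n), v1, v2, pred1 = pred1, pred2 = pred2)
  bw <- between_within_decomposition(tp, subset = "MZ")
  diff_fit <- lm(I(v1 - v2) ~ 0 + I(pred1 - pred2))
  expect_equal(bw$table$estimate[bw$table$term == "within"],
               unname(coef(diff_fit)), tolerance = 1e-10)
})

test_that("simulated twins reproduce the configured within-pair slopes", {
  cfg <- sim_config(n_mz = 4000, n_dz = 4000, n_probes = 10)
  tw <- simulate_twins(cfg, seed = 57, betas = FALSE)
  ph <- tw$phenotype; ph$score <- tw$truth$score
  tp <- pairs_from_long(ph, "score", "pack_years")
  bw_all <- between_within_decomposition(tp)
  bw_mz <- between_within_decomposition(tp, subset = "MZ")
  w_all <- bw_all$table[bw_all$table$term == "within", ]
  w_mz <- bw_mz$table[bw_mz$table$term == "within", ]
  expect_lt(abs(w_all$estimate - 0.18), 3 * w_all$se)
  expect_lt(abs(w_mz$estimate - 0.09), 3 * w_mz$se)
})
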