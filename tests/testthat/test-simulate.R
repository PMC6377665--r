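# Generator contracts: determinism, bounds, and recovery of the declared
# correlational structure.

small_cfg <- function(...) {
  sim_config(n_never = 120, n_former = 60, n_current = 60, n_probes = 80, ...)
}

test_that("the same seed reproduces a cohort bit-for-bit", {
  c1 <- simulate_cohort(small_cfg(), seed = 5)
  c2 <- simulate_cohort(small_cfg(), seed = 5)
  expect_identical(unclass(c1$betas), unclass(c2$betas))
  expect_identical(c1$phenotype, c2$phenotype)
  c3 <- simulate_cohort(small_cfg(), seed = 6)
  expect_false(identical(unclass(c1$betas), unclass(c3$betas)))
})

test_that("generated betas always lie inside [0, 1]", {
  coh <- simulate_cohort(small_cfg(waves = 2), seed = 7)
  expect_true(all(coh$betas >= 0 & coh$betas <= 1))
  expect_true(all(coh$betas_w2 >= 0 & coh$betas_w2 <= 1))
  med <- simulate_mediation(sim_config(n_mediation = 100,
                                       mediation_probes = 60,
                                       n_causal = 20), seed = 7)
  expect_true(all(med$betas >= 0 & med$betas <= 1))
})

test_that("a null configuration discriminates at chance", {
  cfg <- small_cfg(effect_former = 0, effect_current = 0,
                   slope_packyears = 0)
  coh <- simulate_cohort(cfg, seed = 8)
  ph <- score_cohort(coh)
  sel <- ph$smoking_status != "former"
  a <- auc_discrimination(ph$z_score[sel],
                          ph$smoking_status[sel] == "current")
  expect_lt(abs(a$auc - 0.5), 3 * a$se)
})

test_that("configured group contrasts are recovered with near-nominal CIs", {
  hits <- 0
  for (s in 1:25) {
    coh <- simulate_cohort(sim_config(n_probes = 150), seed = 100 + s)
    ph <- score_cohort(coh)
    ct <- group_contrast(ph$z_score, ph$smoking_status)
    cur <- ct[ct$group == "current", ]
    hits <- hits + (cur$ci_low <= 1.65 && 1.65 <= cur$ci_high)
  }
  expect_gte(hits, 20)  # nominal 95% coverage; allow Monte-Carlo slack
})

test_that("twin generator reproduces the biometric MZ/DZ correlations", {
  cfg <- sim_config(n_mz = 5000, n_dz = 5000, n_probes = 10)
  tw <- simulate_twins(cfg, seed = 21, betas = FALSE)
  ph <- tw$phenotype; ph$score <- tw$truth$score
  tp <- pairs_from_long(ph, "score")
  rmz <- intraclass_correlation(tp, "MZ")$r
  rdz <- intraclass_correlation(tp, "DZ")$r
  expect_lt(abs(rmz - 0.869), 0.02)   # a2 + c2
  expect_lt(abs(rdz - 0.5145), 0.03)  # a2/2 + c2
})

test_that("degenerate ACE mixes behave exactly as the model dictates", {
  # no familial variance: both correlations are null
  cfg0 <- sim_config(n_mz = 400, n_dz = 400, n_probes = 10,
                     score_ace = c(0, 0, 1),
                     within_slope_mz = 0, within_slope_pooled = 0)
  tw0 <- simulate_twins(cfg0, seed = 22, betas = FALSE)
  ph0 <- tw0$phenotype; ph0$score <- tw0$truth$score
  tp0 <- pairs_from_long(ph0, "score")
  se <- 1 / sqrt(400)
  expect_lt(abs(intraclass_correlation(tp0, "MZ")$r), 3 * se)
  expect_lt(abs(intraclass_correlation(tp0, "DZ")$r), 3 * se)

  # pure shared environment: twins are identical, r = 1 exactly
  cfg1 <- sim_config(n_mz = 50, n_dz = 50, n_probes = 10,
                     score_ace = c(0, 1, 0),
                     within_slope_mz = 0, within_slope_pooled = 0)
  tw1 <- simulate_twins(cfg1, seed = 23, betas = FALSE)
  ph1 <- tw1$phenotype; ph1$score <- tw1$truth$score
  tp1 <- pairs_from_long(ph1, "score")
  expect_equal(tp1$value1, tp1$value2, tolerance = 1e-12)
  expect_equal(intraclass_correlation(tp1, "MZ")$r, 1, tolerance = 1e-12)
  expect_equal(intraclass_correlation(tp1, "DZ")$r, 1, tolerance = 1e-12)
})

test_that("infeasible within-pair slope targets are rejected", {
  cfg <- sim_config(score_ace = c(0.05, 0.05, 0.9),
                    within_slope_mz = 0.01, within_slope_pooled = 0.9)
  expect_error(simulate_twins(cfg, seed = 1, betas = FALSE), "incompatible")
})

test_that("mediation-only cohorts show no conditional adversity effect", {
  cfg <- sim_config(n_mediation = 800, mediation_probes = 150, n_causal = 100)
  med <- simulate_mediation(cfg, seed = 31)
  ph <- med$phenotype
  B <- unclass(med$betas)[med$truth$causal, ]
  # partial correlation of adversity with each causal probe, given pack-years
  ra <- resid(lm(ph$adversity ~ ph$pack_years))
  frac <- mean(apply(B, 1, function(b) {
    rb <- resid(lm(b ~ ph$pack_years))
    cor.test(ra, rb)$p.value < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / length(med$truth$causal))
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("a zero direct-adversity slope changes nothing under one seed", {
  cfg0 <- sim_config(n_mediation = 120, mediation_probes = 60, n_causal = 20)
  cfg1 <- sim_config(n_mediation = 120, mediation_probes = 60, n_causal = 20,
                     direct_adversity_slope = 0)
  m0 <- simulate_mediation(cfg0, seed = 33)
  m1 <- simulate_mediation(cfg1, seed = 33)
  expect_identical(unclass(m0$betas), unclass(m1$betas))
})

test_that("a null adversity-to-smoking path leaves the two independent", {
  cfg <- sim_config(n_mediation = 600, mediation_probes = 30, n_causal = 10,
                    packyears_per_adversity = 0)
  med <- simulate_mediation(cfg, seed = 34)
  r <- cor(med$phenotype$adversity, med$phenotype$pack_years)
  expect_lt(abs(r), 3 / sqrt(600))
})

test_that("wave-2 latent changes follow the configured recovery and slope", {
  cfg <- small_cfg(waves = 2)
  coh <- simulate_cohort(cfg, seed = 41)
  d <- coh$truth$score_w2 - coh$truth$score_w1
  g <- coh$phenotype$group
  expect_equal(unname(d[g == "quit_between"]),
               rep(cfg$recovery, sum(g == "quit_between")),
               tolerance = 1e-12)
  expect_equal(unname(d[g %in% c("never", "quit_by_w1")]),
               rep(0, sum(g %in% c("never", "quit_by_w1"))),
               tolerance = 1e-12)
  # continuing non-dependent smokers rise by slope x added pack-years
  nd <- g == "current_at_w2" & !coh$phenotype$dependent_w2
  expect_equal(d[nd], cfg$change_slope * coh$phenotype$dpack_years[nd],
               tolerance = 1e-8)
})
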