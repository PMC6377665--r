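# Expression integration: TWAS, stratified correlation screen, cis/trans,
# and the covariate sensitivity analysis.

make_expr_data <- function(seed, k = 200, n = 120, n_true = 0, r = 0.5) {
  set.seed(seed)
  z <- rnorm(n)
  E <- matrix(rnorm(k * n), k, n,
              dimnames = list(sprintf("ps%04d", 1:k), sprintf("s%04d", 1:n)))
  if (n_true > 0) {
    for (i in seq_len(n_true)) {
      E[i, ] <- r * z + sqrt(1 - r^2) * rnorm(n)
    }
  }
  list(E = E, z = setNames(z, colnames(E)))
}

test_that("the screen family size and Bonferroni threshold are exact", {
  expect_identical(screen_tests(2623, 143), 375089)
  expect_identical(signif(bonferroni_threshold(0.05, 375089), 3), 1.33e-07)
  expect_identical(screen_tests(100, 20), 2000)
  # threshold kept at full precision internally
  expect_equal(bonferroni_threshold(0.05, 375089), 0.05 / 375089,
               tolerance = 0)
})

test_that("TWAS under the global null makes (almost) no discoveries", {
  any_disc <- 0
  for (s in 1:40) {
    d <- make_expr_data(900 + s, k = 400, n = 60)
    tw <- transcriptome_association(d$E, d$z)
    any_disc <- any_disc + (sum(tw$significant) > 0)
  }
  # BH controls FWER under the global null at q = 0.05
  expect_lte(any_disc / 40, 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
})

test_that("TWAS controls the false discovery proportion with real signal", {
  fdp <- numeric(50)
  for (s in 1:50) {
    d <- make_expr_data(1000 + s, k = 400, n = 120, n_true = 40, r = 0.5)
    tw <- transcriptome_association(d$E, d$z)
    hits <- tw$probeset_id[tw$significant]
    if (length(hits)) {
      fdp[s] <- mean(!hits %in% sprintf("ps%04d", 1:40))
    }
  }
  se <- sd(fdp) / sqrt(50)
  expect_lte(mean(fdp), 0.05 + 3 * se)
})

test_that("TWAS validates inputs and drops constant probesets", {
  d <- make_expr_data(78, k = 20, n = 40)
  E <- d$E; E[5, ] <- 2
  expect_message(tw <- transcriptome_association(E, d$z), "constant")
  expect_false("ps0005" %in% tw$probeset_id)
  expect_error(transcriptome_association(d$E, setNames(rnorm(5),
    paste0("x", 1:5))), "no samples shared")
})

test_that("perfectly linked pairs are flagged significant in both strata", {
  set.seed(80)
  n <- 60
  M <- matrix(runif(5 * n, 0.2, 0.8), 5, n,
              dimnames = list(paste0("cg", 1:5), paste0("s", 1:n)))
  E <- matrix(rnorm(4 * n), 4, n,
              dimnames = list(paste0("ps", 1:4), paste0("s", 1:n)))
  E[2, ] <- 3 - 2 * M[1, ]    # exact linear function in every stratum
  strata <- rep(c("never", "current"), each = n / 2)
  scr <- correlation_screen(as_beta_matrix(M), E, strata)
  hit <- scr[scr$probe_id == "cg1" & scr$probeset_id == "ps2", ]
  expect_true(hit$significant_both)
  expect_equal(hit$r_1, -1, tolerance = 1e-8)
  expect_identical(sum(scr$significant_both), 1L)
})

test_that("a fully null screen grid yields no joint Bonferroni hits", {
  for (s in 1:5) {
    set.seed(81 + s)
    n <- 80
    M <- matrix(runif(100 * n, 0.2, 0.8), 100, n,
                dimnames = list(sprintf("cg%03d", 1:100), paste0("s", 1:n)))
    E <- matrix(rnorm(20 * n), 20, n,
                dimnames = list(sprintf("ps%02d", 1:20), paste0("s", 1:n)))
    strata <- rep(c("never", "current"), each = n / 2)
    scr <- correlation_screen(as_beta_matrix(M), E, strata)
    expect_identical(sum(scr$significant_both), 0L)
    expect_identical(attr(scr, "n_tests"), 2000)
  }
})

test_that("joint significance is monotone in the family-wise alpha", {
  coh <- simulate_cohort(sim_config(n_never = 60, n_former = 2,
                                    n_current = 60, n_probes = 50,
                                    n_probesets = 20, expr_linked = 6),
                         seed = 82, expression = TRUE)
  strata <- setNames(coh$phenotype$smoking_status, coh$phenotype$sample_id)
  keep <- names(strata)[strata != "former"]
  s1 <- correlation_screen(coh$betas[, keep], coh$expression[, keep],
                           strata[keep], alpha_family = 0.05)
  s2 <- correlation_screen(coh$betas[, keep], coh$expression[, keep],
                           strata[keep], alpha_family = 0.005)
  expect_true(all(s2$significant_both <= s1$significant_both))
  expect_gte(sum(s1$significant_both), 1)
})

test_that("correlations are invariant to affine rescaling of either side", {
  set.seed(83)
  n <- 50
  M <- matrix(runif(3 * n), 3, n,
              dimnames = list(paste0("cg", 1:3), paste0("s", 1:n)))
  E <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(paste0("ps", 1:2), paste0("s", 1:n)))
  strata <- rep(c("a", "b"), each = n / 2)
  base <- correlation_screen(as_beta_matrix(M), E, strata)
  resc <- correlation_screen(as_beta_matrix(M), 5 * E + 2, strata)
  expect_equal(resc$r_1, base$r_1, tolerance = 1e-12)
  expect_equal(resc$p_2, base$p_2, tolerance = 1e-12)
})

test_that("cis/trans labels follow the inclusive 250 kb window", {
  pa <- data.frame(probe_id = c("cgA", "cgB", "cgC", "cgD"),
                   chrom = c("chr1", "chr1", "chr1", "chr2"),
                   pos = c(1000000, 1250001, 999876, 1000000))
  ga <- data.frame(probeset_id = "ps1", gene = "IL32", chrom = "chr1",
                   gene_start = 1000000)
  pairs <- data.frame(probe_id = c("cgA", "cgB", "cgC", "cgD"),
                      probeset_id = "ps1", stringsAsFactors = FALSE)
  ann <- cis_trans_annotate(pairs, pa, ga)
  expect_identical(ann$cis_trans, c("cis", "trans", "cis", "trans"))
  expect_identical(ann$distance[1], 0)        # at the gene start
  expect_identical(ann$distance[2], 250001)   # one bp past the window
  expect_identical(ann$distance[3], -124)     # 124 bp upstream
  expect_true(is.na(ann$distance[4]))         # different chromosome

  # probe exactly at the boundary is cis (inclusive rule)
  pa2 <- data.frame(probe_id = "cgE", chrom = "chr1", pos = 1250000)
  ann2 <- cis_trans_annotate(data.frame(probe_id = "cgE",
                                        probeset_id = "ps1"), pa2, ga)
  expect_identical(ann2$cis_trans, "cis")

  # missing coordinates are labeled unknown
  pa3 <- data.frame(probe_id = "cgF", chrom = NA, pos = NA)
  ann3 <- cis_trans_annotate(data.frame(probe_id = "cgF",
                                        probeset_id = "ps1"), pa3, ga)
  expect_identical(ann3$cis_trans, "unknown")
})

test_that("partial correlations collapse to marginal for a null covariate", {
  set.seed(84)
  n <- 40
  M <- matrix(runif(4 * n), 4, n,
              dimnames = list(paste0("cg", 1:4), paste0("s", 1:n)))
  E <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("ps", 1:3), paste0("s", 1:n)))
  sens <- sensitivity_partial(as_beta_matrix(M), E, rep(0, n))
  expect_equal(sens$table$r_partial, sens$table$r_marginal,
               tolerance = 1e-10)
})

test_that("a covariate collinear with a probe is skipped with a record", {
  set.seed(85)
  n <- 40
  M <- matrix(runif(3 * n), 3, n,
              dimnames = list(paste0("cg", 1:3), paste0("s", 1:n)))
  E <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(paste0("ps", 1:2), paste0("s", 1:n)))
  expect_warning(sens <- sensitivity_partial(as_beta_matrix(M), E, M[2, ]),
                 "collinear")
  expect_identical(sens$skipped, "cg2")
  expect_false("cg2" %in% sens$table$probe_id)
})

test_that("an independent covariate leaves screen coefficients in place", {
  coh <- simulate_cohort(sim_config(n_never = 200, n_former = 2,
                                    n_current = 2, n_probes = 60,
                                    n_probesets = 30, expr_linked = 10),
                         seed = 86, expression = TRUE)
  nev <- coh$phenotype$sample_id[coh$phenotype$smoking_status == "never"]
  set.seed(87)
  shs <- rnorm(length(nev))   # second-hand-smoke proxy, independent
  sens <- sensitivity_partial(coh$betas[, nev], coh$expression[, nev], shs)
  expect_gt(sens$rho, 0.95)
})
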