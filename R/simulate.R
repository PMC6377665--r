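#' Simulation configuration for synthetic methylation cohorts
#'
#' Builds a validated configuration for the synthetic-cohort generators
#' ([simulate_cohort()], [simulate_twins()], [simulate_mediation()]).
#' Defaults reproduce the statistical structure of the two birth-cohort
#' studies that motivate the package: a middle-aged cohort measured at two
#' waves (ages 26 and 38) and a young-adult twin cohort measured once at
#' age 18.
#'
#' The generative model works forward from a latent "true" score:
#' each sample's latent score is built from its smoking phenotype (group
#' offsets in cohort-SD units plus a per-pack-year slope, with residual
#' variance chosen so the latent score has unit variance), the latent
#' score is then spread across probes in proportion to each probe's
#' weight, and probe-level beta values are produced through a logistic
#' squash around probe-specific baselines plus independent probe noise.
#' This construction guarantees the weighted-product-average estimator is
#' (nearly perfectly, for realistic probe counts) monotone and linear in
#' the latent score, so configured effects are recoverable.
#'
#' Group offsets and pack-years are generated independently of each other
#' within ever-smokers (former and current smokers draw pack-years from
#' the same distribution), so the marginal group contrasts and the
#' dose-response slope are separately identifiable at their configured
#' values.
#'
#' @param n_never,n_former,n_current group sizes (defaults 405/233/165,
#'   the age-38 wave of the middle-aged cohort).
#' @param effect_former,effect_current group offsets on the latent score,
#'   in cohort SD units (defaults 0.45 and 1.65).
#' @param slope_packyears latent-score slope per pack-year within
#'   ever-smokers (default 0.07).
#' @param packyears_mean,packyears_sd,packyears_min,packyears_max
#'   pack-year distribution for ever-smokers (defaults 11.71, 8.65,
#'   clipped to \[0.05, 38.75\]).
#' @param n_probes number of CpG probes (default 2623).
#' @param effect_sd SD of the synthetic probe weights.
#' @param signal_scale logit-scale gain applied to `weight x latent score`
#'   per probe.
#' @param probe_noise_sd SD of independent logit-scale probe noise.
#' @param waves 1 or 2 methylation waves.
#' @param quit_fraction fraction of baseline current-smokers who quit
#'   between waves.
#' @param change_slope latent-score change per additional pack-year
#'   smoked between waves (default 0.05).
#' @param recovery latent-score change for quitters between waves
#'   (default -0.25).
#' @param drift latent-score change common to all groups (default 0).
#' @param dpackyears_mean,dpackyears_sd distribution of added pack-years
#'   for continuing smokers.
#' @param dep_cor correlation of the nicotine-dependence liability with
#'   (cumulative) pack-years.
#' @param dep_threshold liability quantile above which a smoker is
#'   classified dependent.
#' @param dep_direct_w2,dep_direct_both direct latent-score change for
#'   smokers dependent at wave 2 only / at both waves, beyond the part
#'   mediated by added pack-years (defaults 0.35 each).
#' @param n_mz,n_dz numbers of monozygotic / dizygotic twin pairs
#'   (defaults 625/491, i.e. 1116 pairs, 56\% MZ).
#' @param score_ace,packyears_ace ACE variance fractions (a2, c2, e2) for
#'   the score propensity and for pack-years; each must sum to 1.
#'   Defaults (0.709, 0.160, 0.131) and (0.485, 0.160, 0.355).
#' @param within_slope_mz,within_slope_pooled target within-twin-pair
#'   regression slopes of score on pack-years (MZ pairs only, and both
#'   zygosities pooled; defaults 0.09 and 0.18). Cross-trait A and E
#'   paths are solved from these targets.
#' @param twin_packyears_mean,twin_packyears_sd pack-year scale in the
#'   twin cohort (defaults 2.04 and 1.76; young adults).
#' @param n_mediation,mediation_probes,n_causal sample size, total probe
#'   count and number of smoking-sensitive (causal) probes for the
#'   adversity-mediation cohort (defaults 800, 1000, 100).
#' @param adversity_prob per-category probability for the adversity count
#'   (sum of 10 binary categories; default 0.2 gives mean 2).
#' @param packyears_per_adversity pack-years added per adversity count
#'   unit (default 1.5).
#' @param packyears_noise_sd residual pack-year SD in the mediation
#'   cohort (default 5).
#' @param direct_adversity_slope direct adversity effect on causal probes
#'   (latent-score units per SD of adversity; 0 = mediation only).
#' @param n_probesets,expr_linked,expr_cor,expr_cis expression module:
#'   number of probesets, number linked to methylation probes, link
#'   correlation, and how many linked pairs are placed cis (within the
#'   `cis_window` of the gene start).
#' @param cis_window cis definition in bp (default 250000).
#' @param seed default integer seed used when a generator is called
#'   without one.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_never = 405, n_former = 233, n_current = 165,
                       effect_former = 0.45, effect_current = 1.65,
                       slope_packyears = 0.07,
                       packyears_mean = 11.71, packyears_sd = 8.65,
                       packyears_min = 0.05, packyears_max = 38.75,
                       n_probes = 2623, effect_sd = 0.05,
                       signal_scale = 4, probe_noise_sd = 0.15,
                       waves = 1, quit_fraction = 0.25,
                       change_slope = 0.05, recovery = -0.25, drift = 0,
                       dpackyears_mean = 10, dpackyears_sd = 4,
                       dep_cor = 0.5, dep_threshold = 0.6,
                       dep_direct_w2 = 0.35, dep_direct_both = 0.35,
                       n_mz = 625, n_dz = 491,
                       score_ace = c(0.709, 0.160, 0.131),
                       packyears_ace = c(0.485, 0.160, 0.355),
                       within_slope_mz = 0.09, within_slope_pooled = 0.18,
                       twin_packyears_mean = 2.04, twin_packyears_sd = 1.76,
                       n_mediation = 800, mediation_probes = 1000,
                       n_causal = 100, adversity_prob = 0.2,
                       packyears_per_adversity = 1.5,
                       packyears_noise_sd = 5,
                       direct_adversity_slope = 0,
                       n_probesets = 143, expr_linked = 20, expr_cor = 0.6,
                       expr_cis = 1, cis_window = 250000,
                       seed = 20260101) {
  cfg <- as.list(environment())
  for (nm in c("score_ace", "packyears_ace")) {
    v <- cfg[[nm]]
    if (length(v) != 3L || any(v < 0) || abs(sum(v) - 1) > 1e-8) {
      stop(sprintf("%s must be three non-negative fractions summing to 1", nm))
    }
  }
  stopifnot(waves %in% c(1, 2), quit_fraction >= 0, quit_fraction <= 1,
            n_probes >= 1, all(is.finite(c(effect_former, effect_current,
                                           slope_packyears))))
  class(cfg) <- "sim_config"
  cfg
}

# Latent score -> probes -> betas: logistic squash around per-probe
# baselines. Keeps every beta strictly inside (0, 1).
.betas_from_latent <- function(latent, w, b0, cfg) {
  m <- length(w)
  n <- length(latent)
  logit <- qlogis(b0) + (cfg$signal_scale * w) %o% latent +
    matrix(stats::rnorm(m * n, 0, cfg$probe_noise_sd), m, n)
  B <- stats::plogis(logit)
  sat <- mean(B < 1e-3 | B > 1 - 1e-3)
  if (sat > 0.01) {
    warning(sprintf("%.1f%% of betas saturate the [0,1] range; consider a smaller signal_scale", 100 * sat))
  }
  B
}

.clip_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Simulate a cross-sectional (or two-wave) smoking cohort
#'
#' Generates a synthetic cohort with never-, former- and current-smokers
#' whose latent polyepigenetic score differs by the configured SD-unit
#' offsets and rises with pack-years at the configured slope; probe-level
#' beta values are derived from the latent score as described in
#' [sim_config()]. With `waves = 2`, a second methylation wave is
#' generated in which continuing smokers accumulate pack-years (latent
#' score rising by `change_slope` per added pack-year), quitters recover
#' by `recovery`, and nicotine-dependence patterns add their configured
#' direct effects.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to `config$seed`. The same seed
#'   reproduces the cohort bit-for-bit.
#' @param expression also generate a linked expression matrix and gene
#'   annotation (see [sim_config()]'s expression parameters).
#' @return An object of class `sim_cohort`: a list with elements
#'   `betas` (wave-1 beta matrix), `betas_w2` (second wave or `NULL`),
#'   `phenotype` (data frame), `weights` (the generating
#'   [probe_weights()] table), `expression`, `gene_annotation`,
#'   `probe_annotation`, `truth` (latent scores) and `config`.
#' @examples
#' cfg <- sim_config(n_never = 40, n_former = 20, n_current = 20,
#'                   n_probes = 50)
#' coh <- simulate_cohort(cfg, seed = 1)
#' table(coh$phenotype$smoking_status)
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed,
                            expression = FALSE) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_never + cfg$n_former + cfg$n_current
  status <- rep(c("never", "former", "current"),
                c(cfg$n_never, cfg$n_former, cfg$n_current))
  ever <- status != "never"

  weights <- synthetic_weight_table(cfg$n_probes, cfg$effect_sd,
                                    with_positions = TRUE)
  b0 <- stats::runif(cfg$n_probes, 0.1, 0.9)

  py <- numeric(n)
  py[ever] <- .clip_norm(sum(ever), cfg$packyears_mean, cfg$packyears_sd,
                         cfg$packyears_min, cfg$packyears_max)
  offset <- unname(c(never = 0, former = cfg$effect_former,
                     current = cfg$effect_current)[status])
  py_c <- py
  py_c[ever] <- py[ever] - mean(py[ever])
  struct <- offset + cfg$slope_packyears * py_c * ever
  resid_var <- 1 - stats::var(struct)
  if (resid_var <= 0) {
    stop("configured effects imply structural variance >= 1; no room for residual noise")
  }
  latent <- struct + stats::rnorm(n, 0, sqrt(resid_var))

  sample_id <- sprintf("s%04d", seq_len(n))
  B1 <- .betas_from_latent(latent, weights$effect, b0, cfg)
  dimnames(B1) <- list(weights$probe_id, sample_id)

  pheno <- data.frame(sample_id = sample_id, smoking_status = status,
                      pack_years = py, family_id = sample_id,
                      stringsAsFactors = FALSE)
  truth <- list(score_w1 = latent)
  B2 <- NULL

  if (cfg$waves == 2) {
    group <- ifelse(status == "never", "never",
             ifelse(status == "former", "quit_by_w1", "current_at_w2"))
    cur <- which(status == "current")
    quitters <- cur[stats::runif(length(cur)) < cfg$quit_fraction]
    group[quitters] <- "quit_between"
    dpy <- numeric(n)
    cont <- group == "current_at_w2"
    dpy[cont] <- pmax(0.05, stats::rnorm(sum(cont), cfg$dpackyears_mean,
                                         cfg$dpackyears_sd))
    # nicotine dependence among baseline current-smokers: liability is a
    # mix of cumulative exposure and a persistent individual component
    dep_w1 <- dep_w2 <- rep(FALSE, n)
    persist <- stats::rnorm(n)
    lia1 <- lia2 <- rep(NA_real_, n)
    smk1 <- status == "current"
    lia1[smk1] <- cfg$dep_cor * scale(py[smk1])[, 1] +
      sqrt(1 - cfg$dep_cor^2) * (0.7 * persist[smk1] +
                                 sqrt(1 - 0.49) * stats::rnorm(sum(smk1)))
    dep_w1[smk1] <- lia1[smk1] > stats::qnorm(cfg$dep_threshold)
    lia2[cont] <- cfg$dep_cor * scale(py[cont] + dpy[cont])[, 1] +
      sqrt(1 - cfg$dep_cor^2) * (0.7 * persist[cont] +
                                 sqrt(1 - 0.49) * stats::rnorm(sum(cont)))
    dep_w2[cont] <- lia2[cont] > stats::qnorm(cfg$dep_threshold)

    dlatent <- cfg$drift +
      cfg$change_slope * dpy +
      cfg$recovery * (group == "quit_between") +
      cfg$dep_direct_w2 * (!dep_w1 & dep_w2) +
      cfg$dep_direct_both * (dep_w1 & dep_w2)
    latent2 <- latent + dlatent
    B2 <- .betas_from_latent(latent2, weights$effect, b0, cfg)
    dimnames(B2) <- dimnames(B1)

    pheno$group <- group
    pheno$dpack_years <- dpy
    pheno$pack_years_w2 <- py + dpy
    pheno$dependent_w1 <- dep_w1
    pheno$dependent_w2 <- dep_w2
    # dependence patterns are defined for persistent smokers (current at
    # both waves); quitters and never-smokers carry NA
    pheno$dep_pattern <- ifelse(!(smk1 & cont), NA_character_,
      ifelse(dep_w1 & dep_w2, "both", ifelse(dep_w1, "w1_only",
        ifelse(dep_w2, "w2_only", "never_dependent"))))
    truth$score_w2 <- latent2
  }

  expr <- gene_annot <- NULL
  if (expression) {
    gen <- .simulate_expression(B1, weights, cfg)
    expr <- gen$expression
    gene_annot <- gen$annotation
  }

  structure(list(betas = as_beta_matrix(B1),
                 betas_w2 = if (!is.null(B2)) as_beta_matrix(B2) else NULL,
                 phenotype = pheno, weights = weights,
                 expression = expr, gene_annotation = gene_annot,
                 probe_annotation = weights[, c("probe_id", "chrom", "pos")],
                 truth = truth, config = cfg, seed = seed),
            class = "sim_cohort")
}

# Linked expression matrix: each linked probeset tracks the beta values of
# one weight-table probe at correlation expr_cor; remaining probesets are
# independent noise. A configurable number of linked pairs is placed cis
# (gene start near the probe), the rest trans (other chromosomes).
.simulate_expression <- function(B, weights, cfg) {
  k <- cfg$n_probesets
  n <- ncol(B)
  ps_id <- sprintf("ps%05d_at", seq_len(k))
  E <- matrix(stats::rnorm(k * n), k, n, dimnames = list(ps_id, colnames(B)))
  n_link <- min(cfg$expr_linked, k, nrow(B))
  link_probe <- sample(nrow(B), n_link)
  link_ps <- sample(k, n_link)
  for (i in seq_len(n_link)) {
    x <- scale(B[link_probe[i], ])[, 1]
    E[link_ps[i], ] <- cfg$expr_cor * x +
      sqrt(1 - cfg$expr_cor^2) * stats::rnorm(n)
  }
  gene <- sprintf("GENE%03d", seq_len(k))
  chrom <- paste0("chr", sample(1:22, k, replace = TRUE))
  start <- sample.int(2.4e8, k, replace = TRUE)
  # place the first expr_cis linked pairs cis to their probe
  n_cis <- min(cfg$expr_cis, n_link)
  if (n_cis > 0) {
    for (i in seq_len(n_cis)) {
      j <- link_ps[i]; p <- link_probe[i]
      chrom[j] <- weights$chrom[p]
      start[j] <- weights$pos[p] + 124L   # probe just upstream of the start
    }
  }
  if (n_link > n_cis) {
    for (i in seq(n_cis + 1, n_link)) {   # force trans: different chromosome
      j <- link_ps[i]; p <- link_probe[i]
      others <- setdiff(paste0("chr", 1:22), weights$chrom[p])
      chrom[j] <- sample(others, 1)
    }
  }
  ann <- data.frame(probeset_id = ps_id, gene = gene, chrom = chrom,
                    gene_start = start,
                    linked_probe = NA_character_,
                    stringsAsFactors = FALSE)
  ann$linked_probe[link_ps] <- rownames(B)[link_probe]
  list(expression = E, annotation = ann)
}

#' Simulate a twin cohort with ACE structure
#'
#' Generates MZ and DZ twin pairs whose (standardized) score propensity
#' and pack-years follow the classical biometric ACE model: MZ pairs
#' correlate `a2 + c2`, DZ pairs `a2/2 + c2`. The two traits are coupled
#' through cross-paths on the additive-genetic and unique-environment
#' components, solved numerically so that the within-twin-pair regression
#' of score on pack-years matches the configured MZ-only and pooled
#' slopes while the score's total variance fractions stay at
#' `score_ace`. Probe-level betas are generated from the score propensity
#' exactly as in [simulate_cohort()].
#'
#' @inheritParams simulate_cohort
#' @param betas generate the probe-level beta matrix (set `FALSE` for
#'   large phenotype-only simulations).
#' @return A `sim_cohort` whose `phenotype` has one row per twin with
#'   columns `sample_id`, `family_id`, `zygosity`, `twin`, `pack_years`,
#'   and latent scores in `truth`.
#' @export
simulate_twins <- function(config = sim_config(), seed = config$seed,
                           betas = TRUE) {
  cfg <- config
  if (cfg$n_mz < 2 || cfg$n_dz < 2) stop("need at least 2 pairs per zygosity")
  set.seed(seed)
  sa <- cfg$score_ace; pa <- cfg$packyears_ace
  aP <- sqrt(pa[1]); cP <- sqrt(pa[2]); eP <- sqrt(pa[3])
  # cross-paths from the configured within-pair slopes (standardized scale)
  sd_py <- cfg$twin_packyears_sd
  ke <- cfg$within_slope_mz * sd_py * eP
  fMZ <- cfg$n_mz / (cfg$n_mz + cfg$n_dz); fDZ <- 1 - fMZ
  target <- cfg$within_slope_pooled * sd_py *
    (fMZ * eP^2 + fDZ * (0.5 * aP^2 + eP^2))
  ka <- if (aP > 0 && fDZ > 0) {
    (target - (fMZ + fDZ) * ke * eP) / (fDZ * 0.5 * aP)
  } else 0
  if (ka^2 > sa[1] || ke^2 > sa[3]) {
    stop("within-pair slope targets are incompatible with the configured ACE fractions")
  }
  a_s <- sqrt(sa[1] - ka^2); c_s <- sqrt(sa[2]); e_s <- sqrt(sa[3] - ke^2)

  gen_zyg <- function(npair, mz) {
    Ash <- stats::rnorm(npair); C1 <- stats::rnorm(npair)
    Ash2 <- stats::rnorm(npair); C2 <- stats::rnorm(npair)
    one <- function() {
      A1 <- if (mz) Ash else sqrt(0.5) * Ash + sqrt(0.5) * stats::rnorm(npair)
      A2 <- if (mz) Ash2 else sqrt(0.5) * Ash2 + sqrt(0.5) * stats::rnorm(npair)
      E1 <- stats::rnorm(npair); E2 <- stats::rnorm(npair)
      P <- aP * A1 + cP * C1 + eP * E1
      S <- ka * A1 + ke * E1 + a_s * A2 + c_s * C2 + e_s * E2
      list(P = P, S = S)
    }
    t1 <- one(); t2 <- one()
    list(t1 = t1, t2 = t2)
  }
  mz <- gen_zyg(cfg$n_mz, TRUE)
  dz <- gen_zyg(cfg$n_dz, FALSE)

  npair <- cfg$n_mz + cfg$n_dz
  fam <- sprintf("fam%04d", seq_len(npair))
  zyg <- rep(c("MZ", "DZ"), c(cfg$n_mz, cfg$n_dz))
  P <- c(rbind(c(mz$t1$P, dz$t1$P), c(mz$t2$P, dz$t2$P)))
  S <- c(rbind(c(mz$t1$S, dz$t1$S), c(mz$t2$S, dz$t2$S)))
  pheno <- data.frame(
    sample_id = sprintf("%s_t%d", rep(fam, each = 2), rep(1:2, npair)),
    family_id = rep(fam, each = 2),
    zygosity = rep(zyg, each = 2),
    twin = rep(1:2, npair),
    pack_years = cfg$twin_packyears_mean + cfg$twin_packyears_sd * P,
    stringsAsFactors = FALSE)

  B <- NULL; weights <- NULL
  if (betas) {
    weights <- synthetic_weight_table(cfg$n_probes, cfg$effect_sd,
                                      with_positions = TRUE)
    b0 <- stats::runif(cfg$n_probes, 0.1, 0.9)
    B <- .betas_from_latent(S, weights$effect, b0, cfg)
    dimnames(B) <- list(weights$probe_id, pheno$sample_id)
    B <- as_beta_matrix(B)
  }
  structure(list(betas = B, betas_w2 = NULL, phenotype = pheno,
                 weights = weights, expression = NULL,
                 gene_annotation = NULL,
                 probe_annotation = if (betas) weights[, c("probe_id", "chrom", "pos")] else NULL,
                 truth = list(score = S, packyears_latent = P,
                              cross_paths = c(ka = ka, ke = ke)),
                 config = cfg, seed = seed),
            class = "sim_cohort")
}

#' Simulate an adversity-mediation cohort
#'
#' Generates the confounding scenario used to study score-as-proxy
#' covariate control: an adversity count (sum of ten binary categories)
#' raises pack-years; pack-years shift a causal subset of
#' smoking-sensitive probes; the remaining probes are noise. With the
#' default `direct_adversity_slope = 0` the adversity-methylation
#' association is *fully mediated* by smoking, so it vanishes once
#' pack-years (or a methylation score built from the causal probes) is
#' adjusted for.
#'
#' @inheritParams simulate_cohort
#' @return A `sim_cohort` whose `phenotype` has columns `sample_id`,
#'   `adversity` (count 0-10) and `pack_years`; `weights` holds the
#'   causal probes' weight table.
#' @export
simulate_mediation <- function(config = sim_config(), seed = config$seed) {
  cfg <- config
  set.seed(seed)
  n <- cfg$n_mediation
  adv <- stats::rbinom(n, 10, cfg$adversity_prob)
  py <- pmax(0, cfg$packyears_per_adversity * adv +
                stats::rnorm(n, 0, cfg$packyears_noise_sd))
  latent <- scale(py)[, 1]
  if (cfg$direct_adversity_slope != 0) {
    latent <- latent + cfg$direct_adversity_slope * scale(adv)[, 1]
  }

  m <- cfg$mediation_probes
  ncaus <- min(cfg$n_causal, m)
  weights <- synthetic_weight_table(ncaus, cfg$effect_sd,
                                    with_positions = TRUE)
  b0 <- stats::runif(m, 0.1, 0.9)
  sample_id <- sprintf("s%04d", seq_len(n))
  Bc <- .betas_from_latent(latent, weights$effect, b0[seq_len(ncaus)], cfg)
  Bn <- stats::plogis(qlogis(b0[-seq_len(ncaus)]) +
                      matrix(stats::rnorm((m - ncaus) * n, 0,
                                          cfg$probe_noise_sd), m - ncaus, n))
  null_ids <- sprintf("cgn%06d", seq_len(m - ncaus))
  B <- rbind(Bc, Bn)
  dimnames(B) <- list(c(weights$probe_id, null_ids), sample_id)

  pheno <- data.frame(sample_id = sample_id, adversity = adv,
                      pack_years = py, family_id = sample_id,
                      stringsAsFactors = FALSE)
  structure(list(betas = as_beta_matrix(B), betas_w2 = NULL,
                 phenotype = pheno, weights = weights, expression = NULL,
                 gene_annotation = NULL,
                 probe_annotation = weights[, c("probe_id", "chrom", "pos")],
                 truth = list(latent = latent, causal = weights$probe_id),
                 config = cfg, seed = seed),
            class = "sim_cohort")
}

#' Score a simulated cohort with its own generating weight table
#'
#' Convenience wrapper: computes standardized [meth_score()]s for a
#' `sim_cohort` (optionally wave 2) and returns them merged with the
#' phenotype table.
#'
#' @param cohort a `sim_cohort`.
#' @param wave 1 or 2.
#' @param weights weight table; defaults to the cohort's generating table.
#' @return the phenotype data frame with `z_score` (and `raw_score`)
#'   columns appended.
#' @export
score_cohort <- function(cohort, wave = 1, weights = cohort$weights) {
  B <- if (wave == 1) cohort$betas else cohort$betas_w2
  if (is.null(B)) stop("requested wave not present in cohort")
  sc <- meth_score(B, weights)
  df <- merge(cohort$phenotype,
              as.data.frame(sc)[, c("sample_id", "raw_score", "z_score")],
              by = "sample_id", sort = FALSE)
  df[match(cohort$phenotype$sample_id, df$sample_id), , drop = FALSE]
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort\n")
  cat(sprintf("  samples: %d; probes: %s; waves: %d\n",
              nrow(x$phenotype),
              if (is.null(x$betas)) "none" else nrow(x$betas),
              1L + !is.null(x$betas_w2)))
  if (!is.null(x$phenotype$zygosity)) {
    cat(sprintf("  twin pairs: %d MZ, %d DZ\n",
                sum(x$phenotype$zygosity == "MZ") / 2,
                sum(x$phenotype$zygosity == "DZ") / 2))
  }
  if (!is.null(x$expression)) {
    cat(sprintf("  expression probesets: %d\n", nrow(x$expression)))
  }
  cat(sprintf("  seed: %s\n", x$seed))
  invisible(x)
}
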