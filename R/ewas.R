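#' Probe-wise EWAS of an exposure
#'
#' Regresses each probe's methylation beta value on an exposure (plus
#' optional covariates) and reports per-probe estimate, SE, p-value and
#' a family-wise significance flag. All probes share one design matrix,
#' so the fits are computed in a single multi-response least-squares
#' pass. With `cluster` given (e.g. family ids in a twin sample),
#' standard errors are the cluster-robust sandwich estimator and
#' p-values are normal-based; otherwise classical t-based.
#'
#' Probes with zero variance are dropped with a message before testing.
#' The default family-wise rule is Bonferroni: per-test threshold
#' `alpha_family / n_probes_tested`.
#'
#' @param betas probes-by-samples beta matrix.
#' @param exposure numeric exposure per sample (e.g. adversity count).
#' @param covariates optional data frame / matrix of covariates (e.g.
#'   pack-years, or a methylation score used as a smoking proxy).
#' @param cluster optional cluster ids for robust SEs.
#' @param alpha_family family-wise alpha (default 0.05).
#' @param model tag recorded in the result (e.g. `"unadjusted"`,
#'   `"packyears-adjusted"`, `"score-adjusted"`).
#' @return An `ewas_result` data frame with one row per tested probe:
#'   `probe_id`, `estimate`, `se`, `statistic`, `p`, `neg_log10_p`,
#'   `significant`; attributes record `alpha_family`, the per-test
#'   `threshold` and `n_tested`.
#' @export
run_ewas <- function(betas, exposure, covariates = NULL, cluster = NULL,
                     alpha_family = 0.05, model = "unadjusted") {
  B <- unclass(betas)
  stopifnot(ncol(B) == length(exposure))
  if (stats::var(exposure, na.rm = TRUE) == 0) {
    stop("exposure has zero variance")
  }
  X <- cbind(`(Intercept)` = 1, exposure = exposure)
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  }
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]; B <- B[, ok, drop = FALSE]
  if (!is.null(cluster)) cluster <- cluster[ok]

  v <- apply(B, 1, stats::var)
  if (any(v == 0 | is.na(v))) {
    drop <- which(v == 0 | is.na(v))
    message(sprintf("dropping %d zero-variance probe(s) before testing",
                    length(drop)))
    B <- B[-drop, , drop = FALSE]
  }
  if (nrow(B) == 0) stop("no probes with variance to test")

  fit <- .mass_lm(t(B), X, which_coef = 2L)
  est <- fit$estimate; se <- fit$se; p <- fit$p; stat <- fit$statistic
  if (!is.null(cluster)) {
    se <- .mass_lm_cluster_se(fit, X, cluster, which_coef = 2L)
    stat <- est / se
    p <- 2 * stats::pnorm(-abs(stat))
  }
  thr <- alpha_family / nrow(B)
  out <- data.frame(probe_id = rownames(B), estimate = unname(est),
                    se = unname(se), statistic = unname(stat),
                    p = unname(p), neg_log10_p = -log10(unname(p)),
                    significant = unname(p < thr), model = model,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("ewas_result", "data.frame"),
            alpha_family = alpha_family, threshold = thr,
            n_tested = nrow(B))
}

#' @export
print.ewas_result <- function(x, ...) {
  cat(sprintf("EWAS (%s): %d probes tested, Bonferroni threshold %.3g\n",
              x$model[1], attr(x, "n_tested"), attr(x, "threshold")))
  cat(sprintf("  significant probes: %d\n", sum(x$significant)))
  top <- as.data.frame(x)[order(x$p)[seq_len(min(5, nrow(x)))],
                          c("probe_id", "estimate", "se", "p")]
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare two EWAS runs for attenuation
#'
#' Pairs the per-probe results of two EWAS runs on the same probe
#' universe (typically unadjusted vs covariate-adjusted, or two
#' adjustment strategies such as observed pack-years vs a methylation
#' score used as a smoking proxy) and summarizes how the significant
#' hits of the first behave in the second: retained vs lost, plus the
#' Spearman rank correlation of the two p-value vectors.
#'
#' @param ewas_a,ewas_b two [run_ewas()] results over identical probes.
#' @return An `attenuation_comparison` list with the paired `table`
#'   (`probe_id`, `neg_log10_p_a`, `neg_log10_p_b`, flags), hit counts
#'   (`hits_a`, `hits_b`, `retained`, `lost`) and `rank_correlation`.
#'   `plot()` draws the quadrant scatter of -log10 p-values.
#' @export
attenuation_compare <- function(ewas_a, ewas_b) {
  if (!setequal(ewas_a$probe_id, ewas_b$probe_id)) {
    stop("the two EWAS results cover different probe sets")
  }
  b <- ewas_b[match(ewas_a$probe_id, ewas_b$probe_id), ]
  tab <- data.frame(probe_id = ewas_a$probe_id,
                    neg_log10_p_a = ewas_a$neg_log10_p,
                    neg_log10_p_b = b$neg_log10_p,
                    significant_a = ewas_a$significant,
                    significant_b = b$significant,
                    stringsAsFactors = FALSE)
  hits_a <- sum(tab$significant_a)
  retained <- sum(tab$significant_a & tab$significant_b)
  structure(list(table = tab,
                 hits_a = hits_a, hits_b = sum(tab$significant_b),
                 retained = retained, lost = hits_a - retained,
                 rank_correlation = stats::cor(ewas_a$p, b$p,
                                               method = "spearman"),
                 threshold_a = attr(ewas_a, "threshold"),
                 threshold_b = attr(ewas_b, "threshold"),
                 models = c(ewas_a$model[1], b$model[1])),
            class = "attenuation_comparison")
}

#' @export
print.attenuation_comparison <- function(x, ...) {
  cat(sprintf("EWAS attenuation: '%s' vs '%s'\n", x$models[1], x$models[2]))
  cat(sprintf("  hits in first: %d; retained in second: %d; lost: %d\n",
              x$hits_a, x$retained, x$lost))
  cat(sprintf("  Spearman rank correlation of p-values: %.3f\n",
              x$rank_correlation))
  invisible(x)
}

#' @export
plot.attenuation_comparison <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$neg_log10_p_a, tab$neg_log10_p_b,
                 pch = 16, col = ifelse(tab$significant_a, "blue", "grey60"),
                 xlab = sprintf("-log10 p (%s)", x$models[1]),
                 ylab = sprintf("-log10 p (%s)", x$models[2]), ...)
  graphics::abline(v = -log10(x$threshold_a), h = -log10(x$threshold_b),
                   lty = 2)
  invisible(x)
}
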