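#' Transcriptome-wide association with a methylation score
#'
#' Regresses each expression probeset on the (standardized) methylation
#' score, optionally with covariates, across the samples common to both
#' inputs. Discoveries are flagged by Benjamini-Hochberg FDR at `q`
#' (default 0.05). Constant probesets are excluded with a message.
#'
#' @param expr probesets-by-samples expression matrix (named dims).
#' @param z_scores named numeric vector of scores (names = sample ids),
#'   or a [meth_score()] object.
#' @param covariates optional per-sample covariates (named rows or same
#'   order as `names(z_scores)`).
#' @param q FDR level for the discovery flag.
#' @return A `twas_result` data frame: `probeset_id`, `estimate`, `se`,
#'   `statistic`, `p`, `q_value`, `significant`.
#' @export
transcriptome_association <- function(expr, z_scores, covariates = NULL,
                                      q = 0.05) {
  if (inherits(z_scores, "meth_score")) {
    z_scores <- stats::setNames(z_scores$z_score, z_scores$sample_id)
  }
  common <- intersect(colnames(expr), names(z_scores))
  if (length(common) == 0) stop("no samples shared by expression and scores")
  if (length(common) < 10) stop("need at least 10 shared samples")
  E <- expr[, common, drop = FALSE]
  z <- z_scores[common]
  keep <- apply(E, 1, stats::var) > 0
  if (any(!keep)) {
    message(sprintf("excluding %d constant probeset(s)", sum(!keep)))
    E <- E[keep, , drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, score = z)
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    if (!is.null(rownames(cv))) cv <- cv[common, , drop = FALSE]
    X <- cbind(X, cv)
  }
  fit <- .mass_lm(t(E), X, which_coef = 2L)
  qv <- stats::p.adjust(fit$p, method = "BH")
  out <- data.frame(probeset_id = rownames(E), estimate = unname(fit$estimate),
                    se = unname(fit$se), statistic = unname(fit$statistic),
                    p = unname(fit$p), q_value = unname(qv),
                    significant = unname(qv < q),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("twas_result", "data.frame"),
            q = q, n_samples = length(common))
}

#' Number of tests in a methylation-by-expression screen
#'
#' The screen tests every (probe, probeset) pair, so the family size is
#' the exact integer product of the two grid dimensions.
#'
#' @param n_probes,n_probesets grid dimensions.
#' @return integer-valued count `n_probes * n_probesets`.
#' @examples
#' screen_tests(2623, 143)  # 375089
#' @export
screen_tests <- function(n_probes, n_probesets) {
  stopifnot(n_probes >= 1, n_probesets >= 1)
  as.numeric(n_probes) * as.numeric(n_probesets)
}

#' Bonferroni per-test threshold
#'
#' @param alpha_family family-wise alpha (default 0.05).
#' @param n_tests family size (e.g. [screen_tests()]).
#' @return the exact per-test threshold `alpha_family / n_tests` (full
#'   precision; round only for display).
#' @examples
#' signif(bonferroni_threshold(0.05, 375089), 3)  # 1.33e-07
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_tests) {
  stopifnot(n_tests >= 1)
  alpha_family / n_tests
}

# correlation matrix with t-based p-values between rows of A and rows of B
.cor_grid <- function(A, B, method = "pearson") {
  if (method == "spearman") {
    A <- t(apply(A, 1, rank)); B <- t(apply(B, 1, rank))
  }
  n <- ncol(A)
  R <- stats::cor(t(A), t(B))
  tt <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tt), n - 2)
  P[abs(R) >= 1] <- 0
  list(r = R, p = P, n = n)
}

#' Stratified methylation-expression correlation screen
#'
#' Tests the correlation between every methylation probe and every
#' expression probeset, separately within two strata (typically
#' never-smokers and current-smokers), and flags pairs significant in
#' *both* strata after Bonferroni correction over the full grid
#' (`alpha_family / (n_probes x n_probesets)`, kept at full precision).
#' A pair surviving in both strata indicates a methylation-expression
#' relationship not attributable solely to the shared influence of
#' smoking.
#'
#' @param meth probes-by-samples beta matrix.
#' @param expr probesets-by-samples expression matrix.
#' @param strata factor/character over the shared samples with exactly
#'   two non-empty levels, or a named vector (names = sample ids).
#' @param alpha_family family-wise alpha (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param min_n minimum samples per stratum (default 10).
#' @return A `screen_result` data frame with one row per (probe,
#'   probeset) pair: per-stratum `r_*` and `p_*`, and
#'   `significant_both`; attributes `n_tests`, `threshold`,
#'   `strata_levels`, per-stratum sample counts.
#' @export
correlation_screen <- function(meth, expr, strata, alpha_family = 0.05,
                               method = c("pearson", "spearman"),
                               min_n = 10) {
  method <- match.arg(method)
  common <- intersect(colnames(meth), colnames(expr))
  if (length(common) == 0) stop("no shared samples")
  if (!is.null(names(strata))) strata <- strata[common]
  strata <- factor(as.character(strata))
  if (nlevels(strata) != 2) stop("strata must have exactly two levels")
  lev <- levels(strata)
  M <- unclass(meth)[, common, drop = FALSE]
  E <- expr[, common, drop = FALSE]
  res <- list()
  for (l in lev) {
    sel <- which(strata == l)
    if (length(sel) < min_n) {
      stop(sprintf("stratum '%s' has %d samples; need >= %d", l,
                   length(sel), min_n))
    }
    res[[l]] <- .cor_grid(M[, sel, drop = FALSE], E[, sel, drop = FALSE],
                          method)
  }
  n_tests <- screen_tests(nrow(M), nrow(E))
  thr <- bonferroni_threshold(alpha_family, n_tests)
  grid <- expand.grid(probe_id = rownames(M), probeset_id = rownames(E),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(grid,
                    r_1 = as.vector(res[[1]]$r), p_1 = as.vector(res[[1]]$p),
                    r_2 = as.vector(res[[2]]$r), p_2 = as.vector(res[[2]]$p),
                    stringsAsFactors = FALSE)
  out$significant_both <- out$p_1 < thr & out$p_2 < thr
  structure(out, class = c("screen_result", "data.frame"),
            n_tests = n_tests, threshold = thr, strata_levels = lev,
            n_per_stratum = stats::setNames(as.integer(table(strata)), lev),
            method = method, alpha_family = alpha_family)
}

#' @export
print.screen_result <- function(x, ...) {
  if (is.null(attr(x, "n_tests"))) {        # subset lost its attributes
    return(print(as.data.frame(x)))
  }
  cat(sprintf("Methylation x expression screen: %s tests\n",
              format(attr(x, "n_tests"), big.mark = ",")))
  cat(sprintf("  Bonferroni per-test threshold: %.3g (alpha = %.3g)\n",
              signif(attr(x, "threshold"), 3), attr(x, "alpha_family")))
  cat(sprintf("  strata: %s (n = %s)\n",
              paste(attr(x, "strata_levels"), collapse = " / "),
              paste(attr(x, "n_per_stratum"), collapse = " / ")))
  cat(sprintf("  pairs significant in both strata: %d\n",
              sum(x$significant_both)))
  invisible(x)
}

#' Annotate screen pairs as cis or trans
#'
#' A (probe, probeset) pair is *cis* when the probe lies on the same
#' chromosome as the probeset's gene and within `window` bp of the gene
#' start (inclusive); otherwise *trans*. The reported distance is
#' signed: negative means the probe is upstream of (before) the gene
#' start. Pairs with missing coordinates are labeled `"unknown"`.
#'
#' @param pairs data frame with `probe_id` and `probeset_id` columns
#'   (e.g. a [correlation_screen()] result, possibly filtered).
#' @param probe_annotation data frame: `probe_id`, `chrom`, `pos`
#'   (1-based).
#' @param gene_annotation data frame: `probeset_id`, `gene`, `chrom`,
#'   `gene_start` (1-based).
#' @param window cis window in bp (default 250000).
#' @return `pairs` with `distance` (signed bp) and `cis_trans`
#'   (`"cis"`/`"trans"`/`"unknown"`) columns appended.
#' @export
cis_trans_annotate <- function(pairs, probe_annotation, gene_annotation,
                               window = 250000) {
  .stop_if_missing_cols(pairs, c("probe_id", "probeset_id"), "pair table")
  .stop_if_missing_cols(probe_annotation, c("probe_id", "chrom", "pos"),
                        "probe annotation")
  .stop_if_missing_cols(gene_annotation,
                        c("probeset_id", "chrom", "gene_start"),
                        "gene annotation")
  pi <- match(pairs$probe_id, probe_annotation$probe_id)
  gi <- match(pairs$probeset_id, gene_annotation$probeset_id)
  pchr <- probe_annotation$chrom[pi]; ppos <- probe_annotation$pos[pi]
  gchr <- gene_annotation$chrom[gi]; gpos <- gene_annotation$gene_start[gi]
  dist <- ppos - gpos
  known <- !(is.na(pchr) | is.na(ppos) | is.na(gchr) | is.na(gpos))
  lab <- rep("unknown", nrow(pairs))
  same <- known & pchr == gchr
  lab[known] <- "trans"
  lab[same & abs(dist) <= window] <- "cis"
  pairs <- as.data.frame(pairs)
  pairs$distance <- ifelse(same, dist, NA_integer_)
  pairs$cis_trans <- lab
  pairs
}

#' Covariate-adjusted correlation sensitivity analysis
#'
#' Recomputes the screen correlations within one stratum as partial
#' correlations given a covariate (residual-on-residual), and reports
#' the Spearman rank correlation between the adjusted and unadjusted
#' correlation vectors. The canonical use is checking that
#' methylation-expression correlations among never-smokers are not
#' driven by second-hand smoke exposure: if the covariate is irrelevant
#' the two vectors agree almost perfectly.
#'
#' Pairs whose methylation probe is collinear with the covariate
#' (residual variance zero) are skipped and recorded.
#'
#' @param meth probes-by-samples beta matrix (stratum samples).
#' @param expr probesets-by-samples expression matrix (same samples).
#' @param covariate numeric covariate over the same samples.
#' @return A `sensitivity_result` list: `table` (pairwise marginal and
#'   partial correlations), `rho` (Spearman agreement of the two
#'   vectors), its `p`, and `skipped` pair indices.
#' @export
sensitivity_partial <- function(meth, expr, covariate) {
  M <- unclass(meth); E <- expr
  stopifnot(ncol(M) == ncol(E), ncol(M) == length(covariate))
  marg <- .cor_grid(M, E)
  X <- cbind(1, covariate)
  resid_rows <- function(A) {
    t(stats::lm.fit(X, t(A))$residuals)
  }
  Mr <- resid_rows(M); Er <- resid_rows(E)
  bad <- apply(Mr, 1, stats::sd) < 1e-12
  skipped <- character(0)
  if (any(bad)) {
    skipped <- rownames(M)[bad]
    warning(sprintf("skipping %d probe(s) collinear with the covariate: %s",
                    sum(bad), paste(utils::head(skipped, 3), collapse = ", ")))
    Mr <- Mr[!bad, , drop = FALSE]
  }
  part <- .cor_grid(Mr, Er)
  keep_probes <- rownames(M)[!bad]
  grid <- expand.grid(probe_id = keep_probes, probeset_id = rownames(E),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  marg_keep <- marg$r[!bad, , drop = FALSE]
  tab <- data.frame(grid, r_marginal = as.vector(marg_keep),
                    r_partial = as.vector(part$r),
                    p_partial = as.vector(part$p),
                    stringsAsFactors = FALSE)
  ct <- stats::cor.test(tab$r_marginal, tab$r_partial, method = "spearman",
                        exact = FALSE)
  structure(list(table = tab, rho = unname(ct$estimate),
                 p = ct$p.value, skipped = skipped),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Adjusted vs unadjusted correlations: Spearman rho = %.3f (p = %.3g)\n",
              x$rho, x$p))
  if (length(x$skipped)) {
    cat(sprintf("  %d collinear probe(s) skipped\n", length(x$skipped)))
  }
  invisible(x)
}
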