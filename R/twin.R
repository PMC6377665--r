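#' Twin pair tables
#'
#' A twin pair table has one row per pair: `pair_id`, `zygosity`
#' (`"MZ"`/`"DZ"`) and the phenotype of each twin (`value1`, `value2`),
#' optionally with a second predictor phenotype (`pred1`, `pred2`).
#'
#' @param pair_id pair identifiers (unique).
#' @param zygosity `"MZ"` or `"DZ"` per pair.
#' @param value1,value2 phenotype values of twin 1 and twin 2.
#' @param pred1,pred2 optional predictor values (e.g. pack-years).
#' @return A `twin_pairs` data frame.
#' @export
twin_pairs <- function(pair_id, zygosity, value1, value2,
                       pred1 = NULL, pred2 = NULL) {
  zygosity <- as.character(zygosity)
  if (!all(zygosity %in% c("MZ", "DZ"))) {
    stop("zygosity must be 'MZ' or 'DZ'")
  }
  if (anyDuplicated(pair_id)) stop("pair ids must be unique")
  out <- data.frame(pair_id = as.character(pair_id), zygosity = zygosity,
                    value1 = value1, value2 = value2,
                    stringsAsFactors = FALSE)
  if (!is.null(pred1)) { out$pred1 <- pred1; out$pred2 <- pred2 }
  class(out) <- c("twin_pairs", "data.frame")
  out
}

#' Build a twin pair table from a per-twin cohort table
#'
#' Reshapes a long per-twin data frame (as produced by
#' [simulate_twins()], or any table with `family_id`, `zygosity` and
#' `twin` columns) into a [twin_pairs()] table for the given phenotype
#' column(s). Pairs with missing values in either twin are dropped.
#'
#' @param data per-twin data frame with `family_id`, `zygosity`, `twin`.
#' @param value_col name of the phenotype column.
#' @param pred_col optional name of a predictor column.
#' @return A `twin_pairs` table.
#' @export
pairs_from_long <- function(data, value_col, pred_col = NULL) {
  .stop_if_missing_cols(data, c("family_id", "zygosity", "twin", value_col),
                        "per-twin table")
  d1 <- data[data$twin == 1, ]
  d2 <- data[data$twin == 2, ]
  common <- intersect(d1$family_id, d2$family_id)
  d1 <- d1[match(common, d1$family_id), ]
  d2 <- d2[match(common, d2$family_id), ]
  tp <- twin_pairs(common, d1$zygosity, d1[[value_col]], d2[[value_col]],
                   pred1 = if (!is.null(pred_col)) d1[[pred_col]] else NULL,
                   pred2 = if (!is.null(pred_col)) d2[[pred_col]] else NULL)
  ok <- stats::complete.cases(tp$value1, tp$value2)
  tp[ok, , drop = FALSE]
}

#' Double-entry intraclass correlation
#'
#' Twin intraclass correlation computed as the Pearson correlation of the
#' double-entered pairs: every pair contributes both orderings
#' `(x1, x2)` and `(x2, x1)`, making the statistic symmetric under twin
#' order by construction. The confidence interval uses the Fisher
#' z-transform with the number of *pairs* as the effective sample size.
#'
#' @param pairs a [twin_pairs()] table.
#' @param zygosity which pairs to use: `"MZ"`, `"DZ"` or `"all"`.
#' @param alpha two-sided alpha.
#' @return An `icc_result` list: `r`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
intraclass_correlation <- function(pairs, zygosity = c("MZ", "DZ", "all"),
                                   alpha = 0.05) {
  zygosity <- match.arg(zygosity)
  p <- if (zygosity == "all") pairs else pairs[pairs$zygosity == zygosity, ]
  n <- nrow(p)
  if (n < 3) stop("need at least 3 complete pairs")
  x <- c(p$value1, p$value2)
  y <- c(p$value2, p$value1)
  if (stats::sd(x) == 0) stop("phenotype has zero variance across twins")
  r <- stats::cor(x, y)
  if (n > 3 && abs(r) < 1) {
    zr <- atanh(r); sez <- 1 / sqrt(n - 3)
    zq <- stats::qnorm(1 - alpha / 2)
    ci <- tanh(c(zr - zq * sez, zr + zq * sez))
  } else ci <- c(NA_real_, NA_real_)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], n_pairs = n,
                 zygosity = zygosity),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("Double-entry ICC (%s): r = %.3f [%.3f, %.3f], %d pairs\n",
              x$zygosity, x$r, x$ci_low, x$ci_high, x$n_pairs))
  invisible(x)
}

#' Falconer ACE decomposition from twin correlations
#'
#' The closed-form biometric decomposition: additive genetic variance
#' `a2 = 2 (rMZ - rDZ)`, shared environment `c2 = 2 rDZ - rMZ`,
#' non-shared environment `e2 = 1 - rMZ`. Components always sum to 1
#' before truncation; negative components are truncated at 0 and the
#' remainder renormalized, with the truncation flagged.
#'
#' @param rmz,rdz MZ and DZ intraclass correlations, in `[-1, 1]`.
#' @return An `ace_estimate` list: `a2`, `c2`, `e2`, `method`,
#'   `truncated`.
#' @examples
#' falconer_decomposition(0.87, 0.52)  # a2 = 0.70, c2 = 0.17, e2 = 0.13
#' @export
falconer_decomposition <- function(rmz, rdz) {
  stopifnot(abs(rmz) <= 1, abs(rdz) <= 1)
  comp <- c(a2 = 2 * (rmz - rdz), c2 = 2 * rdz - rmz, e2 = 1 - rmz)
  truncated <- any(comp < 0)
  if (truncated) {
    comp <- pmax(comp, 0)
    comp <- comp / sum(comp)
    message("Falconer component(s) below 0 truncated and renormalized")
  }
  structure(list(a2 = unname(comp[1]), c2 = unname(comp[2]),
                 e2 = unname(comp[3]), ci = NULL, method = "falconer",
                 truncated = truncated, rmz = rmz, rdz = rdz),
            class = "ace_estimate")
}

# negative log-likelihood of standardized twin pairs under the ACE model;
# sufficient statistics per zygosity: n, sum(x^2 + y^2), sum(xy)
.ace_nll <- function(a2, c2, stats_mz, stats_dz) {
  nll_r <- function(r, st) {
    if (r >= 1 - 1e-10) r <- 1 - 1e-10
    if (r <= -1 + 1e-10) r <- -1 + 1e-10
    st$n * log(1 - r^2) / 2 +
      (st$sxx - 2 * r * st$sxy) / (2 * (1 - r^2))
  }
  nll_r(a2 + c2, stats_mz) + nll_r(a2 / 2 + c2, stats_dz)
}

#' Maximum-likelihood ACE fit from twin pairs
#'
#' Fits the biometric ACE model by maximizing the joint bivariate-normal
#' likelihood over MZ and DZ pairs, with expected pair correlations
#' `a2 + c2` (MZ) and `a2/2 + c2` (DZ). The phenotype is standardized
#' internally (double-entry mean/SD); variance components are optimized
#' on an unconstrained (softmax) scale, which enforces non-negativity
#' and the unit-sum constraint. Confidence intervals are
#' profile-likelihood intervals; boundary solutions are flagged.
#'
#' @param pairs a [twin_pairs()] table with both zygosities.
#' @param alpha two-sided alpha for the profile CIs.
#' @param ci compute profile-likelihood CIs (default `TRUE`).
#' @return An `ace_estimate` with `a2`, `c2`, `e2`, per-component `ci`,
#'   `method = "ml"`, `boundary` flag, the achieved log-likelihood and
#'   the implied `rmz`, `rdz`.
#' @export
ml_ace_fit <- function(pairs, alpha = 0.05, ci = TRUE) {
  for (z in c("MZ", "DZ")) {
    if (sum(pairs$zygosity == z) < 20) {
      stop(sprintf("need at least 20 %s pairs", z))
    }
  }
  all_v <- c(pairs$value1, pairs$value2)
  mu <- mean(all_v); sdv <- stats::sd(all_v)
  if (sdv == 0) stop("phenotype has zero variance")
  st <- function(z) {
    p <- pairs[pairs$zygosity == z, ]
    x <- (p$value1 - mu) / sdv; y <- (p$value2 - mu) / sdv
    list(n = nrow(p), sxx = sum(x^2 + y^2), sxy = sum(x * y))
  }
  smz <- st("MZ"); sdz <- st("DZ")

  nll_theta <- function(th) {
    e <- exp(c(th, 0)); f <- e / sum(e)
    .ace_nll(f[1], f[2], smz, sdz)
  }
  opt <- stats::optim(c(0, 0), nll_theta, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  e <- exp(c(opt$par, 0)); f <- e / sum(e)
  a2 <- f[1]; c2 <- f[2]; e2 <- f[3]
  boundary <- any(f < 1e-4)

  ci_tab <- NULL
  if (ci) {
    qc <- stats::qchisq(1 - alpha, 1)
    prof <- function(component) {
      # profile nll at a fixed value of one component
      pn <- function(v) {
        if (component == "a2") {
          o <- stats::optimize(function(c2f) .ace_nll(v, c2f * (1 - v),
                                                      smz, sdz), c(0, 1))
        } else {
          o <- stats::optimize(function(a2f) .ace_nll(a2f * (1 - v), v,
                                                      smz, sdz), c(0, 1))
        }
        o$objective
      }
      target <- opt$value + qc / 2
      hat <- if (component == "a2") a2 else c2
      lo <- if (pn(1e-9) < target) 0 else
        stats::uniroot(function(v) pn(v) - target, c(1e-9, hat))$root
      hi <- if (pn(1 - 1e-9) < target) 1 else
        stats::uniroot(function(v) pn(v) - target, c(hat, 1 - 1e-9))$root
      c(lo, hi)
    }
    ca <- prof("a2"); cc <- prof("c2")
    # e2 profile: e2 = 1 - rMZ under the model; profile over e2 directly
    pn_e <- function(v) {
      stats::optimize(function(a2f) .ace_nll(a2f * (1 - v),
                                             (1 - a2f) * (1 - v),
                                             smz, sdz), c(0, 1))$objective
    }
    target <- opt$value + qc / 2
    lo_e <- if (pn_e(1e-9) < target) 0 else
      stats::uniroot(function(v) pn_e(v) - target, c(1e-9, e2))$root
    hi_e <- if (pn_e(1 - 1e-9) < target) 1 else
      stats::uniroot(function(v) pn_e(v) - target, c(e2, 1 - 1e-9))$root
    ci_tab <- rbind(a2 = ca, c2 = cc, e2 = c(lo_e, hi_e))
    colnames(ci_tab) <- c("lower", "upper")
  }

  structure(list(a2 = a2, c2 = c2, e2 = e2, ci = ci_tab, method = "ml",
                 boundary = boundary, logLik = -opt$value,
                 rmz = a2 + c2, rdz = a2 / 2 + c2,
                 n_mz = smz$n, n_dz = sdz$n, convergence = opt$convergence),
            class = "ace_estimate")
}

#' @export
print.ace_estimate <- function(x, ...) {
  cat(sprintf("ACE decomposition (%s)\n", x$method))
  comp <- c(a2 = x$a2, c2 = x$c2, e2 = x$e2)
  for (i in seq_along(comp)) {
    line <- sprintf("  %s = %.3f", names(comp)[i], comp[i])
    if (!is.null(x$ci)) {
      line <- paste0(line, sprintf(" [%.3f, %.3f]", x$ci[i, 1], x$ci[i, 2]))
    }
    cat(line, "\n")
  }
  if (isTRUE(x$truncated)) cat("  (negative component truncated)\n")
  if (isTRUE(x$boundary)) cat("  (boundary solution)\n")
  invisible(x)
}

#' @export
coef.ace_estimate <- function(object, ...) {
  c(a2 = object$a2, c2 = object$c2, e2 = object$e2)
}

#' Between/within twin-pair effect decomposition
#'
#' Parses the effect of a predictor (e.g. pack-years) on an outcome
#' (e.g. a methylation score) into a between-pair effect (on the pair
#' mean of the predictor) and a within-pair effect (on each twin's
#' deviation from the pair mean), fitted jointly by least squares with
#' cluster-robust (pair) standard errors. Because the deviation is
#' orthogonal to the pair mean, the within coefficient equals the
#' through-origin regression of outcome differences on predictor
#' differences for complete pairs. Restricting to MZ pairs removes all
#' genetic and shared-environment confounding from the within effect.
#'
#' @param pairs a [twin_pairs()] table carrying both `value*` (outcome)
#'   and `pred*` (predictor) columns.
#' @param subset `"all"` or `"MZ"` (MZ pairs only).
#' @param alpha two-sided alpha.
#' @return A `bw_decomposition` list with `between` and `within` rows
#'   (estimate, se, ci, p), the subset tag and the underlying fit.
#' @export
between_within_decomposition <- function(pairs, subset = c("all", "MZ"),
                                         alpha = 0.05) {
  subset <- match.arg(subset)
  .stop_if_missing_cols(pairs, c("pred1", "pred2"), "twin pair table")
  p <- if (subset == "MZ") pairs[pairs$zygosity == "MZ", ] else pairs
  if (nrow(p) < 3) stop("need at least 3 pairs")
  pm <- (p$pred1 + p$pred2) / 2
  long <- data.frame(
    y = c(p$value1, p$value2),
    pair_mean = c(pm, pm),
    deviation = c(p$pred1 - pm, p$pred2 - pm),
    pair = c(p$pair_id, p$pair_id))
  if (all(abs(long$deviation) < 1e-12)) {
    stop("predictor is identical within every pair; within effect undefined")
  }
  fit <- stats::lm(y ~ pair_mean + deviation, data = long)
  V <- sandwich::vcovCL(fit, cluster = long$pair)
  cf <- stats::coef(fit)[c("pair_mean", "deviation")]
  se <- sqrt(diag(V))[c("pair_mean", "deviation")]
  ci <- .wald_ci(cf, se, alpha)
  tab <- data.frame(term = c("between", "within"),
                    estimate = unname(cf), se = unname(se),
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    p = unname(.wald_p(cf, se)))
  structure(list(table = tab, subset = subset, n_pairs = nrow(p),
                 fit = fit), class = "bw_decomposition")
}

#' @export
print.bw_decomposition <- function(x, ...) {
  cat(sprintf("Between/within twin-pair decomposition (%s pairs, n = %d)\n",
              x$subset, x$n_pairs))
  df <- x$table
  df$estimate <- sprintf("%.3f [%.3f, %.3f]", df$estimate, df$ci_low,
                         df$ci_high)
  print(df[, c("term", "estimate", "p")], row.names = FALSE)
  invisible(x)
}
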