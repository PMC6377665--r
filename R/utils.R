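# Internal helpers shared across modules.

# Wald interval with normal quantiles; alpha is two-sided.
.wald_ci <- function(est, se, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  cbind(lower = est - z * se, upper = est + z * se)
}

.wald_p <- function(est, se) {
  z <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  2 * stats::pnorm(-abs(z))
}

# Multi-response least squares: Y is n x p (one column per response),
# X is n x k. Returns coefficients, classical SEs, t statistics and
# two-sided p-values for a single coefficient of interest, plus residuals.
# Used by the EWAS and transcriptome screens where thousands of small
# regressions share one design matrix.
.mass_lm <- function(Y, X, which_coef = 2L) {
  n <- nrow(X)
  k <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < k) {
    stop("design matrix is rank deficient (collinear predictors)")
  }
  B <- qr.coef(qrX, Y)                      # k x p
  fitted <- X %*% B
  R <- Y - fitted                           # residuals, n x p
  df <- n - k
  rss <- colSums(R^2)
  XtXinv <- chol2inv(qr.R(qrX))
  se2_unit <- XtXinv[which_coef, which_coef]
  sigma2 <- rss / df
  se <- sqrt(sigma2 * se2_unit)
  est <- B[which_coef, ]
  tstat <- ifelse(se > 0, est / se, NA_real_)
  p <- 2 * stats::pt(-abs(tstat), df)
  list(estimate = est, se = se, statistic = tstat, p = p,
       residuals = R, coefficients = B, df = df, XtXinv = XtXinv)
}

# Cluster-robust (sandwich, CR0) SE for the mass regression above.
# Scores are aggregated per cluster with rowsum(), so no per-probe loop.
.mass_lm_cluster_se <- function(fit, X, cluster, which_coef = 2L) {
  k <- ncol(X)
  cl <- as.factor(cluster)
  # G[[a]] : (n_clusters x p) matrix of cluster-summed scores X[,a] * r
  G <- lapply(seq_len(k), function(a) rowsum(X[, a] * fit$residuals, cl))
  A <- fit$XtXinv
  p <- ncol(fit$residuals)
  var_out <- numeric(p)
  # vcov = A (sum_c g_c g_c') A ; we only need element [which_coef, which_coef]
  # row of A applied to scores: h_c = sum_a A[which_coef, a] * G[[a]]
  H <- matrix(0, nrow = nlevels(cl), ncol = p)
  for (a in seq_len(k)) H <- H + A[which_coef, a] * G[[a]]
  var_out <- colSums(H^2)
  sqrt(var_out)
}

.stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")))
  }
}
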