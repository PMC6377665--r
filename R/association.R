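#' Group contrasts of standardized scores
#'
#' Mean difference of each smoking group versus a reference group (never
#' smokers, by default), estimated from a linear model with group
#' indicators. Confidence intervals are Wald intervals with normal
#' quantiles; with `cluster` given, cluster-robust (sandwich) standard
#' errors are used to account for family clustering.
#'
#' @param scores numeric vector of (standardized) scores.
#' @param group factor/character of group labels, same length.
#' @param reference reference group label (default `"never"`).
#' @param cluster optional cluster ids (e.g. family) for robust SEs.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @return A `contrast_result` data frame: one row per non-reference
#'   group with `estimate` (SD units when scores are standardized),
#'   `se`, `ci_low`, `ci_high`, `p`, and per-group `n`.
#' @examples
#' group_contrast(c(0, 0, 1, 1, 1.5, 2.1),
#'                c("never", "never", "former", "former",
#'                  "current", "current"))
#' @export
group_contrast <- function(scores, group, reference = "never",
                           cluster = NULL, alpha = 0.05) {
  stopifnot(length(scores) == length(group))
  group <- as.character(group)
  if (!reference %in% group) stop("reference group is empty")
  tab <- table(group)
  if (any(tab < 2)) {
    stop(sprintf("group(s) with fewer than 2 samples: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  f <- stats::relevel(factor(group), ref = reference)
  fit <- stats::lm(scores ~ f)
  V <- if (is.null(cluster)) stats::vcov(fit) else
    sandwich::vcovCL(fit, cluster = cluster)
  cf <- stats::coef(fit)[-1]
  se <- sqrt(diag(V))[-1]
  ci <- .wald_ci(cf, se, alpha)
  lev <- levels(f)[-1]
  out <- data.frame(group = lev, reference = reference,
                    estimate = unname(cf), se = unname(se),
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    p = unname(.wald_p(cf, se)),
                    n = as.integer(tab[lev]),
                    n_reference = as.integer(tab[reference]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("Group contrasts vs '%s' (Wald 95%% CI)\n", x$reference[1]))
  df <- as.data.frame(x)
  df$estimate <- sprintf("%.3f [%.3f, %.3f]", df$estimate, df$ci_low,
                         df$ci_high)
  print(df[, c("group", "estimate", "p", "n")], row.names = FALSE)
  invisible(x)
}

#' ROC AUC for score-based discrimination
#'
#' Area under the ROC curve for discriminating cases from controls,
#' computed by the midrank Mann-Whitney statistic:
#' `AUC = P(score_case > score_control) + 0.5 P(tie)`. The confidence
#' interval uses the DeLong placement-variance estimator. The AUC is
#' invariant under any strictly monotone transform of the scores.
#'
#' @param scores numeric scores.
#' @param labels logical or two-level factor; `TRUE` (or the second
#'   level) marks cases.
#' @param alpha two-sided alpha (default 0.05).
#' @return An `auc_result` list: `auc`, `se`, `ci_low`, `ci_high`,
#'   `n_cases`, `n_controls`.
#' @examples
#' auc_discrimination(c(0.1, 0.4, 0.35, 0.8, 0.3),
#'                    c(FALSE, FALSE, FALSE, TRUE, TRUE))
#' @export
auc_discrimination <- function(scores, labels, alpha = 0.05) {
  if (is.factor(labels) || is.character(labels)) {
    labels <- factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    labels <- labels == levels(labels)[2]
  }
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  cs <- scores[labels]; ct <- scores[!labels]
  v10 <- vapply(cs, function(x) mean((x > ct) + 0.5 * (x == ct)), 0)
  v01 <- vapply(ct, function(x) mean((cs > x) + 0.5 * (cs == x)), 0)
  v <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
       (if (n0 > 1) stats::var(v01) / n0 else 0)
  se <- sqrt(v)
  z <- stats::qnorm(1 - alpha / 2)
  out <- list(auc = auc, se = se,
              ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
              n_cases = n1, n_controls = n0)
  class(out) <- "auc_result"
  out
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f [%.3f, %.3f] (%d cases, %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

#' Dose-response slope of score on pack-years
#'
#' Linear regression of (standardized) score on cumulative pack-years,
#' optionally with covariates, within a chosen subset (typically
#' ever-smokers). Reports the slope in SD units per pack-year with a
#' Wald CI.
#'
#' @param scores numeric (standardized) scores.
#' @param pack_years numeric cumulative exposure.
#' @param covariates optional data frame / matrix of covariates.
#' @param subset optional logical vector selecting the analysis sample.
#' @param cluster optional cluster ids for robust SEs.
#' @param alpha two-sided alpha.
#' @return A `dose_response` list with `slope`, `se`, `ci_low`,
#'   `ci_high`, `p`, `n`, and the underlying `lm` fit.
#' @export
dose_response <- function(scores, pack_years, covariates = NULL,
                          subset = NULL, cluster = NULL, alpha = 0.05) {
  stopifnot(length(scores) == length(pack_years))
  keep <- if (is.null(subset)) rep(TRUE, length(scores)) else subset
  y <- scores[keep]; x <- pack_years[keep]
  if (stats::var(x, na.rm = TRUE) == 0) {
    stop("pack_years has zero variance in the analysis subset")
  }
  dat <- data.frame(y = y, pack_years = x)
  if (!is.null(covariates)) {
    dat <- cbind(dat, as.data.frame(covariates)[keep, , drop = FALSE])
  }
  fit <- stats::lm(y ~ ., data = dat)
  V <- if (is.null(cluster)) stats::vcov(fit) else
    sandwich::vcovCL(fit, cluster = cluster[keep])
  b <- stats::coef(fit)["pack_years"]
  se <- sqrt(V["pack_years", "pack_years"])
  ci <- .wald_ci(b, se, alpha)
  out <- list(slope = unname(b), se = unname(se),
              ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
              p = unname(.wald_p(b, se)), n = nrow(dat), fit = fit)
  class(out) <- "dose_response"
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Slope: %.4f per pack-year [%.4f, %.4f], p = %.3g (n = %d)\n",
              x$slope, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Fits a marginal linear model by generalized estimating equations
#' (identity link, Gaussian variance) to account for clustering within
#' families. The working correlation is exchangeable by default;
#' `"independence"` reproduces ordinary least squares point estimates
#' exactly. Standard errors are always the cluster-robust sandwich
#' estimator.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param id cluster identifier: a vector, or the (quoted or bare) name
#'   of a column of `data`.
#' @param corstr working correlation: `"exchangeable"` or
#'   `"independence"`.
#' @param tol,maxit convergence tolerance and iteration cap.
#' @return An object of class `gee_fit` with `coefficients`, robust
#'   `vcov`, the working-correlation estimate `alpha`, and fitting
#'   metadata. Methods: `print`, `summary`, `coef`, `vcov`, `confint`.
#' @examples
#' d <- data.frame(y = rnorm(20), x = rnorm(20), fam = rep(1:10, each = 2))
#' gee_fit(y ~ x, d, id = fam)
#' @export
gee_fit <- function(formula, data, id,
                    corstr = c("exchangeable", "independence"),
                    tol = 1e-10, maxit = 50) {
  corstr <- match.arg(corstr)
  id <- eval(substitute(id), data, parent.frame())
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (!is.null(attr(mf, "na.action"))) id <- id[-attr(mf, "na.action")]
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  cl <- as.factor(as.character(id))
  if (nlevels(cl) < 2) stop("need at least two clusters")
  idx <- split(seq_along(y), cl)

  beta <- qr.coef(qr(X), y)
  alpha <- 0
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    sigma2 <- sum(r^2) / (length(y) - ncol(X))
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        k <- length(ix)
        if (k < 2) next
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        den <- den + k * (k - 1) / 2
      }
      alpha <- if (den > 0 && sigma2 > 0) num / (den * sigma2) else 0
      alpha <- max(min(alpha, 0.99), -0.99)
    }
    A <- matrix(0, ncol(X), ncol(X)); b <- numeric(ncol(X))
    for (ix in idx) {
      k <- length(ix)
      Ri <- matrix(alpha, k, k); diag(Ri) <- 1
      Riinv <- solve(Ri)
      Xi <- X[ix, , drop = FALSE]
      A <- A + crossprod(Xi, Riinv %*% Xi)
      b <- b + crossprod(Xi, Riinv %*% y[ix])
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
    if (corstr == "independence") break
  }
  r <- y - X %*% beta
  A <- matrix(0, ncol(X), ncol(X))
  M <- matrix(0, ncol(X), ncol(X))
  for (ix in idx) {
    k <- length(ix)
    Ri <- matrix(if (corstr == "exchangeable") alpha else 0, k, k)
    diag(Ri) <- 1
    Riinv <- solve(Ri)
    Xi <- X[ix, , drop = FALSE]
    g <- crossprod(Xi, Riinv %*% r[ix])
    A <- A + crossprod(Xi, Riinv %*% Xi)
    M <- M + tcrossprod(g)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  beta <- drop(beta)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = V, alpha = alpha,
                 corstr = corstr, n = length(y), n_clusters = nlevels(cl),
                 iterations = it, formula = formula),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
confint.gee_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  ci <- .wald_ci(object$coefficients, se, 1 - level)
  rownames(ci) <- names(object$coefficients)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE (Gaussian, %s working correlation), %d obs in %d clusters\n",
              x$corstr, x$n, x$n_clusters))
  if (x$corstr == "exchangeable") {
    cat(sprintf("  estimated working correlation: %.3f\n", x$alpha))
  }
  se <- sqrt(diag(x$vcov))
  tab <- cbind(Estimate = x$coefficients, `Robust SE` = se,
               z = x$coefficients / se,
               `p` = .wald_p(x$coefficients, se))
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.gee_fit <- function(object, ...) print(object)
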