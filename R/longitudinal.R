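#' Two-wave records
#'
#' Assembles a two-wave analysis table: one row per sample with the
#' outcome at each wave, the smoking-history group, and optional
#' exposure-change and dependence columns. Only samples with both waves
#' present are kept. By default both waves of the outcome are
#' standardized using the *wave-1* mean and SD, so changes are expressed
#' in baseline SD units; set `standardize = "none"` for outcomes in
#' native units (lung function, attachment loss) or `"pooled"` to use
#' the mean/SD of both waves combined.
#'
#' @param sample_id sample identifiers.
#' @param y1,y2 outcome at wave 1 and wave 2.
#' @param group smoking-history group, one of `"never"`,
#'   `"quit_by_w1"`, `"quit_between"`, `"current_at_w2"` (or any subset).
#' @param dpack_years optional change in pack-years between waves.
#' @param dep_pattern optional dependence pattern
#'   (`"never_dependent"`, `"w1_only"`, `"w2_only"`, `"both"`).
#' @param standardize `"wave1"` (default), `"pooled"` or `"none"`.
#' @return A `two_wave` data frame with columns `sample_id`, `y1`, `y2`,
#'   `delta`, `group` and the optional columns.
#' @export
two_wave_records <- function(sample_id, y1, y2, group,
                             dpack_years = NULL, dep_pattern = NULL,
                             standardize = c("wave1", "pooled", "none")) {
  standardize <- match.arg(standardize)
  vocab <- c("never", "quit_by_w1", "quit_between", "current_at_w2")
  group <- as.character(group)
  if (!all(group %in% vocab | is.na(group))) {
    stop(sprintf("group labels must be among: %s",
                 paste(vocab, collapse = ", ")))
  }
  ok <- !is.na(y1) & !is.na(y2)
  if (standardize == "wave1") {
    mu <- mean(y1[ok]); s <- stats::sd(y1[ok])
    if (s == 0) stop("wave-1 outcome has zero variance")
    y1 <- (y1 - mu) / s; y2 <- (y2 - mu) / s
  } else if (standardize == "pooled") {
    v <- c(y1[ok], y2[ok]); mu <- mean(v); s <- stats::sd(v)
    if (s == 0) stop("outcome has zero variance")
    y1 <- (y1 - mu) / s; y2 <- (y2 - mu) / s
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    y1 = y1, y2 = y2, delta = y2 - y1, group = group,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  if (!is.null(dpack_years)) out$dpack_years <- dpack_years[ok]
  if (!is.null(dep_pattern)) out$dep_pattern <- as.character(dep_pattern)[ok]
  class(out) <- c("two_wave", "data.frame")
  out
}

#' Per-group change trajectories with never-smoker contrasts
#'
#' Mean within-person change (wave 2 minus wave 1) per smoking-history
#' group with Wald CIs, plus the contrast of each group's mean change
#' against the never-smoker group (difference of mean changes, two-sample
#' Wald CI). Mirrors the classic quit/continue trajectory display: never
#' and early quitters flat, continuing smokers rising, between-wave
#' quitters declining.
#'
#' @param records a [two_wave_records()] table.
#' @param reference reference group (default `"never"`).
#' @param alpha two-sided alpha.
#' @return A `trajectory_result` list with `groups` (per-group mean
#'   change table) and `contrasts` (vs reference). `plot()` draws the
#'   two-wave mean trajectories.
#' @export
group_trajectories <- function(records, reference = "never", alpha = 0.05) {
  if (!reference %in% records$group) stop("reference group is empty")
  tab <- table(records$group)
  if (any(tab < 2)) {
    stop(sprintf("group(s) with fewer than 2 samples: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  per <- do.call(rbind, lapply(names(tab), function(g) {
    d <- records$delta[records$group == g]
    se <- stats::sd(d) / sqrt(length(d))
    ci <- .wald_ci(mean(d), se, alpha)
    data.frame(group = g, mean_change = mean(d), se = se,
               ci_low = ci[, 1], ci_high = ci[, 2],
               mean_w1 = mean(records$y1[records$group == g]),
               mean_w2 = mean(records$y2[records$group == g]),
               n = length(d), stringsAsFactors = FALSE)
  }))
  ref <- per[per$group == reference, ]
  oth <- per[per$group != reference, ]
  est <- oth$mean_change - ref$mean_change
  se <- sqrt(oth$se^2 + ref$se^2)
  ci <- .wald_ci(est, se, alpha)
  contrasts <- data.frame(group = oth$group, reference = reference,
                          estimate = est, se = se,
                          ci_low = ci[, 1], ci_high = ci[, 2],
                          p = .wald_p(est, se), stringsAsFactors = FALSE)
  structure(list(groups = per, contrasts = contrasts, alpha = alpha),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("Per-group mean change (wave 2 - wave 1):\n")
  g <- x$groups
  g$mean_change <- sprintf("%.3f [%.3f, %.3f]", g$mean_change, g$ci_low,
                           g$ci_high)
  print(g[, c("group", "mean_change", "n")], row.names = FALSE)
  cat("Contrasts vs reference:\n")
  ct <- x$contrasts
  ct$estimate <- sprintf("%.3f [%.3f, %.3f]", ct$estimate, ct$ci_low,
                         ct$ci_high)
  print(ct[, c("group", "estimate", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.trajectory_result <- function(x, ...) {
  g <- x$groups
  graphics::matplot(rbind(g$mean_w1, g$mean_w2), type = "b", pch = 16,
                    lty = 1, xaxt = "n", xlab = "wave",
                    ylab = "group mean outcome", ...)
  graphics::axis(1, at = 1:2, labels = c("wave 1", "wave 2"))
  graphics::legend("topleft", legend = g$group, col = seq_len(nrow(g)),
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}

#' Change-on-change regression
#'
#' OLS slope of within-person outcome change on within-person exposure
#' change, with a Wald CI. The outcome can be anything numeric: a
#' methylation score, lung function (DLco/VA), periodontal attachment
#' loss. Adding a constant to either wave of the outcome leaves the
#' slope unchanged.
#'
#' @param delta_outcome numeric change in outcome (wave 2 - wave 1).
#' @param delta_exposure numeric change in exposure (e.g. added
#'   pack-years).
#' @param subset optional logical filter (e.g. accumulators only).
#' @param alpha two-sided alpha.
#' @return A `dose_response`-style list: `slope`, `se`, `ci_low`,
#'   `ci_high`, `p`, `n`.
#' @export
change_on_change <- function(delta_outcome, delta_exposure, subset = NULL,
                             alpha = 0.05) {
  keep <- if (is.null(subset)) rep(TRUE, length(delta_outcome)) else subset
  y <- delta_outcome[keep]; x <- delta_exposure[keep]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 samples with both changes")
  if (stats::var(x) == 0) stop("exposure change has zero variance")
  fit <- stats::lm(y ~ x)
  b <- stats::coef(fit)[2]
  se <- sqrt(stats::vcov(fit)[2, 2])
  ci <- .wald_ci(b, se, alpha)
  out <- list(slope = unname(b), se = unname(se), ci_low = unname(ci[, 1]),
              ci_high = unname(ci[, 2]), p = unname(.wald_p(b, se)),
              n = length(y), fit = fit)
  class(out) <- "dose_response"
  out
}

#' Dependence-pattern contrasts of score change
#'
#' Among current smokers, contrasts the mean score change of each
#' nicotine-dependence pattern (dependent at wave 1 only, wave 2 only,
#' or both) against never-dependent smokers, via a linear model on
#' pattern indicators. With `adjust_dpack_years = TRUE` the change in
#' pack-years between waves is included as a covariate, isolating the
#' dependence effect from the density of consumption it carries.
#'
#' @param records a [two_wave_records()] table with `dep_pattern` (and
#'   `dpack_years` when adjusting). Rows with `NA` pattern are ignored.
#' @param adjust_dpack_years include change in pack-years as a
#'   covariate.
#' @param reference reference pattern (default `"never_dependent"`).
#' @param alpha two-sided alpha.
#' @return A `contrast_result` data frame of pattern contrasts.
#' @export
dependence_contrast <- function(records, adjust_dpack_years = FALSE,
                                reference = "never_dependent",
                                alpha = 0.05) {
  .stop_if_missing_cols(records, "dep_pattern", "two-wave table")
  d <- records[!is.na(records$dep_pattern), , drop = FALSE]
  if (!reference %in% d$dep_pattern) stop("reference pattern is empty")
  tab <- table(d$dep_pattern)
  empty <- setdiff(c("never_dependent", "w1_only", "w2_only", "both"),
                   names(tab))
  if (length(empty)) {
    warning(sprintf("pattern group(s) absent and skipped: %s",
                    paste(empty, collapse = ", ")))
  }
  f <- stats::relevel(factor(d$dep_pattern), ref = reference)
  if (adjust_dpack_years) {
    .stop_if_missing_cols(d, "dpack_years", "two-wave table")
    fit <- stats::lm(delta ~ f + dpack_years, data = cbind(d, f = f))
  } else {
    fit <- stats::lm(delta ~ f, data = cbind(d, f = f))
  }
  keep <- grep("^f", names(stats::coef(fit)))
  cf <- stats::coef(fit)[keep]
  se <- sqrt(diag(stats::vcov(fit)))[keep]
  ci <- .wald_ci(cf, se, alpha)
  out <- data.frame(group = sub("^f", "", names(cf)), reference = reference,
                    estimate = unname(cf), se = unname(se),
                    ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                    p = unname(.wald_p(cf, se)),
                    n = as.integer(tab[sub("^f", "", names(cf))]),
                    n_reference = as.integer(tab[reference]),
                    adjusted = adjust_dpack_years,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("contrast_result", "data.frame")
  out
}
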