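#' Compute a polyepigenetic methylation score
#'
#' Computes, for every sample, the weighted-product average that defines a
#' polyepigenetic methylation score: each probe's beta value is multiplied
#' by that probe's effect size from the weight table, and the products are
#' averaged (unweighted arithmetic mean) across the probe set. Raw scores
#' are then standardized to mean 0, SD 1 within the cohort, so results are
#' reported in cohort SD units.
#'
#' Probes in the weight table that are absent from the beta matrix, or
#' missing for a given sample, are dropped from that sample's average;
#' the denominator is the number of probes actually used. Per-sample
#' probe coverage (fraction of weight-table probes available) is recorded.
#' Samples below `min_coverage` trigger a warning and are flagged or
#' dropped according to `low_coverage`; coverage below 0.5 is an error.
#'
#' Because each sample's score is standardized within the cohort, the
#' choice of beta scale (fraction in `[0,1]` versus percent) has no effect
#' on any downstream analysis: multiplying all betas by a constant rescales
#' every raw score by the same constant and leaves z-scores unchanged.
#'
#' @param betas a probes-by-samples matrix of beta values in `[0, 1]`
#'   (see [as_beta_matrix()]); missing values allowed.
#' @param weights a [probe_weights()] table.
#' @param min_coverage minimum acceptable fraction of weight-table probes
#'   present and non-missing per sample (default 0.95). Samples below it
#'   are warned about; samples below 0.5 are an error.
#' @param standardize standardize raw scores to cohort mean 0 / SD 1
#'   (default `TRUE`). Requires at least two samples with distinct raw
#'   scores.
#' @param low_coverage what to do with samples between 0.5 and
#'   `min_coverage`: `"flag"` (keep, with a warning) or `"drop"`.
#' @return An object of class `meth_score`: a data frame with columns
#'   `sample_id`, `raw_score`, `z_score` (NA when `standardize = FALSE`),
#'   `n_probes_used` and `coverage`, with attributes recording the weight
#'   table size and probe overlap.
#' @examples
#' w <- probe_weights(c("cg1", "cg2", "cg3"), c(0.5, -1.0, 0.25))
#' b <- as_beta_matrix(matrix(c(0.2, 0.4, 0.8, 0.1, 0.6, 0.3), nrow = 3,
#'        dimnames = list(c("cg1", "cg2", "cg3"), c("s1", "s2"))))
#' s <- meth_score(b, w)
#' s
#' @export
meth_score <- function(betas, weights, min_coverage = 0.95,
                       standardize = TRUE,
                       low_coverage = c("flag", "drop")) {
  low_coverage <- match.arg(low_coverage)
  if (!inherits(weights, "probe_weights")) {
    weights <- probe_weights(weights$probe_id, weights$effect,
                             chrom = weights$chrom, pos = weights$pos)
  }
  if (!inherits(betas, "beta_matrix")) betas <- as_beta_matrix(betas)
  stopifnot(min_coverage >= 0, min_coverage <= 1)

  common <- intersect(weights$probe_id, rownames(betas))
  if (length(common) == 0L) {
    stop("no overlap between weight-table probes and beta-matrix probes")
  }
  w <- weights$effect[match(common, weights$probe_id)]
  B <- unclass(betas)[common, , drop = FALSE]

  products <- B * w
  used <- colSums(!is.na(B))
  coverage <- used / nrow(weights)
  raw <- colSums(products, na.rm = TRUE) / used
  raw[used == 0L] <- NA_real_

  if (any(coverage < 0.5)) {
    bad <- colnames(B)[coverage < 0.5]
    stop(sprintf(
      "probe coverage below 0.5 for sample(s): %s (have %d weight probes)",
      paste(utils::head(bad, 5), collapse = ", "), nrow(weights)))
  }
  low <- coverage < min_coverage
  if (any(low)) {
    warning(sprintf("%d sample(s) below min_coverage = %.2f%s", sum(low),
                    min_coverage,
                    if (low_coverage == "drop") " (dropped)" else " (flagged)"))
  }

  out <- data.frame(sample_id = colnames(B), raw_score = unname(raw),
                    z_score = NA_real_, n_probes_used = as.integer(used),
                    coverage = unname(coverage), low_coverage = unname(low),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (low_coverage == "drop") out <- out[!out$low_coverage, , drop = FALSE]

  if (standardize) out$z_score <- standardize_scores(out$raw_score)

  structure(out,
            class = c("meth_score", "data.frame"),
            n_weight_probes = nrow(weights),
            n_overlap = length(common),
            standardized = standardize)
}

#' Standardize scores to mean 0, SD 1
#'
#' Centers and scales a numeric vector using the sample standard deviation
#' (n - 1 denominator). Rank order is preserved. Errors on constant input
#' (zero SD) or fewer than two values.
#'
#' @param x numeric vector of raw scores (NA allowed; NAs propagate).
#' @return numeric vector of z-scores with mean 0 and sample SD 1.
#' @examples
#' standardize_scores(c(1, 2, 3))  # -1, 0, 1
#' @export
standardize_scores <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("need at least two non-missing scores to standardize")
  s <- stats::sd(x[ok])
  if (s == 0) stop("cannot standardize: scores have zero variance")
  (x - mean(x[ok])) / s
}

#' @export
print.meth_score <- function(x, ...) {
  cat(sprintf("Polyepigenetic methylation scores: %d samples\n", nrow(x)))
  cat(sprintf("  weight table: %d probes, %d found in beta matrix\n",
              attr(x, "n_weight_probes"), attr(x, "n_overlap")))
  if (isTRUE(attr(x, "standardized"))) {
    cat("  scores standardized to cohort mean 0, SD 1\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat(sprintf("  ... %d more samples\n", nrow(x) - 8L))
  invisible(x)
}

#' @export
summary.meth_score <- function(object, ...) {
  cat(sprintf("Scores for %d samples (coverage %.3f-%.3f)\n",
              nrow(object), min(object$coverage), max(object$coverage)))
  print(summary(object$raw_score))
  invisible(object)
}

#' Plot method for methylation scores
#'
#' Draws score distributions, optionally split by a grouping factor such
#' as smoking status (strip chart with group means, mirroring the usual
#' presentation of smoking-score cohort contrasts).
#'
#' @param x a `meth_score` object.
#' @param group optional factor of length `nrow(x)` (e.g. smoking status).
#' @param ... passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.meth_score <- function(x, group = NULL, ...) {
  y <- if (isTRUE(attr(x, "standardized"))) x$z_score else x$raw_score
  lab <- if (isTRUE(attr(x, "standardized"))) "score (SD units)" else "raw score"
  if (is.null(group)) {
    graphics::hist(y, main = "Polyepigenetic score", xlab = lab, ...)
  } else {
    group <- as.factor(group)
    graphics::stripchart(y ~ group, vertical = TRUE, method = "jitter",
                         pch = 16, col = grDevices::adjustcolor(1, 0.3),
                         ylab = lab, ...)
    mu <- tapply(y, group, mean, na.rm = TRUE)
    graphics::segments(seq_along(mu) - 0.2, mu, seq_along(mu) + 0.2, mu,
                       lwd = 3)
  }
  invisible(x)
}

#' Write scores to a TSV file
#'
#' @param x a `meth_score` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
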