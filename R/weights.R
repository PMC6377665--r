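#' CpG probe weight tables
#'
#' A probe weight table holds the coefficients of a polyepigenetic score:
#' one row per CpG probe, with the probe identifier and the effect size
#' (weight) applied to that probe's methylation beta value. Weights are
#' typically taken from a published EWAS meta-analysis of the exposure of
#' interest (for smoking, the genome-wide significant probes of a large
#' current-vs-never meta-analysis). Optional chromosome/position columns
#' are carried along for cis/trans annotation.
#'
#' @param probe_id character vector of CpG identifiers (e.g. "cg05575921").
#'   Must be unique and non-empty.
#' @param effect numeric vector of finite effect sizes, one per probe.
#' @param chrom optional chromosome labels.
#' @param pos optional 1-based genomic coordinates.
#' @return A `probe_weights` data frame with columns `probe_id`, `effect`
#'   and, when supplied, `chrom` and `pos`.
#' @examples
#' w <- probe_weights(c("cg0001", "cg0002"), c(0.5, -1.0))
#' w
#' @seealso [read_weight_table()] to parse a delimited file,
#'   [meth_score()] to apply the weights to a beta matrix.
#' @export
probe_weights <- function(probe_id, effect, chrom = NULL, pos = NULL) {
  probe_id <- as.character(probe_id)
  if (length(probe_id) == 0L) {
    stop("weight table must contain at least one probe")
  }
  if (anyNA(probe_id) || any(!nzchar(probe_id))) {
    bad <- which(is.na(probe_id) | !nzchar(probe_id))
    stop(sprintf("empty probe id at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(probe_id)) {
    dup <- probe_id[duplicated(probe_id)]
    stop(sprintf("duplicate probe id(s): %s",
                 paste(unique(utils::head(dup, 5)), collapse = ", ")))
  }
  effect <- suppressWarnings(as.numeric(effect))
  if (length(effect) != length(probe_id)) {
    stop("probe_id and effect must have the same length")
  }
  if (anyNA(effect) || any(!is.finite(effect))) {
    bad <- probe_id[which(is.na(effect) | !is.finite(effect))]
    stop(sprintf("non-numeric or non-finite effect size for probe(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- data.frame(probe_id = probe_id, effect = effect,
                    stringsAsFactors = FALSE)
  if (!is.null(chrom)) out$chrom <- as.character(chrom)
  if (!is.null(pos)) out$pos <- as.integer(pos)
  class(out) <- c("probe_weights", "data.frame")
  out
}

#' Read a probe weight table from a delimited file
#'
#' Parses a CSV/TSV file with a header into a validated [probe_weights()]
#' table. Column names can be remapped for files that use different
#' headers (e.g. `Probe.ID`, `Effect`).
#'
#' @param path file path (or connection) to a delimited text file with a
#'   header row.
#' @param probe_col name of the probe-identifier column. Default
#'   `"probe_id"`.
#' @param effect_col name of the effect-size column. Default `"effect"`.
#' @param chrom_col,pos_col optional names of chromosome/position columns.
#' @param sep field separator; `NULL` (default) chooses tab when the
#'   file extension is `.tsv`/`.txt`, comma otherwise.
#' @param quiet suppress the row-count message.
#' @return A `probe_weights` data frame; the number of parsed rows is
#'   reported with a message.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(probe_id = c("cg1", "cg2"), effect = c(0.2, -0.4)),
#'           tf, row.names = FALSE)
#' read_weight_table(tf)
#' @export
read_weight_table <- function(path, probe_col = "probe_id",
                              effect_col = "effect",
                              chrom_col = NULL, pos_col = NULL,
                              sep = NULL, quiet = FALSE) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  .stop_if_missing_cols(df, c(probe_col, effect_col), "weight table")
  if (nrow(df) == 0L) {
    stop(sprintf("weight table '%s' has a header but no rows", path))
  }
  w <- probe_weights(
    probe_id = df[[probe_col]],
    effect = df[[effect_col]],
    chrom = if (!is.null(chrom_col)) df[[chrom_col]] else NULL,
    pos = if (!is.null(pos_col)) df[[pos_col]] else NULL
  )
  if (!quiet) message(sprintf("read %d probe weights from %s", nrow(w), path))
  w
}

#' @export
print.probe_weights <- function(x, ...) {
  cat(sprintf("Probe weight table: %d probes\n", nrow(x)))
  cat(sprintf("  effect sizes: min %.4g, median %.4g, max %.4g\n",
              min(x$effect), stats::median(x$effect), max(x$effect)))
  if (!is.null(x$chrom)) cat("  genomic coordinates present\n")
  NextMethod()
}

#' Synthetic stand-in weight table
#'
#' Generates a synthetic probe weight table with the shape of a published
#' smoking-EWAS weight set: `n` CpG identifiers with signed effect sizes
#' on the per-beta-unit scale. This is a synthetic stand-in -- the probe
#' ids and weights are randomly generated, not taken from any real EWAS --
#' intended for simulation, examples and tests at the realistic table
#' size (2623 genome-wide-significant probes).
#'
#' @param n number of probes (default 2623, the size of the reference
#'   genome-wide-significant probe set).
#' @param effect_sd standard deviation of the Gaussian effect sizes.
#' @param with_positions attach synthetic chromosome/position columns.
#' @param seed optional integer seed for reproducibility.
#' @return A [probe_weights()] table with `n` rows.
#' @export
synthetic_weight_table <- function(n = 2623, effect_sd = 0.05,
                                   with_positions = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("cgs%07d", sample.int(9999999L, n))
  eff <- stats::rnorm(n, 0, effect_sd)
  if (with_positions) {
    chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
    pos <- sample.int(2.4e8, n, replace = TRUE)
    probe_weights(ids, eff, chrom = chrom, pos = pos)
  } else {
    probe_weights(ids, eff)
  }
}
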