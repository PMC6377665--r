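#' Methylation beta matrices
#'
#' A beta matrix stores methylation fractions (beta values, proportion of
#' methylated signal) for CpG probes (rows) by samples (columns). Values
#' must lie in `[0, 1]`; missing values are allowed. Row and column labels
#' must be unique.
#'
#' @param x numeric matrix of beta values with probe rownames and sample
#'   colnames (or coercible to one).
#' @param scale `"fraction"` (values in `[0, 1]`, the default) or
#'   `"percent"` (values in `[0, 100]`, divided by 100 on input). Since
#'   scores are cohort-standardized, the choice has no effect downstream.
#' @return The validated matrix with class `beta_matrix` prepended.
#' @export
as_beta_matrix <- function(x, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (scale == "percent") x <- x / 100
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("beta matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids in beta matrix")
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) {
    stop(sprintf("beta values must be in [0, 1]; observed range [%.4g, %.4g]",
                 rng[1], rng[2]))
  }
  class(x) <- c("beta_matrix", class(unclass(x)))
  x
}

#' Read a beta matrix from a TSV file
#'
#' The expected layout is the standard probes-by-samples export: first
#' column probe id, remaining columns one per sample, values in `[0, 1]`,
#' missing encoded as empty fields or `NA`.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A [as_beta_matrix()] validated matrix.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (ncol(df) < 2L) stop("beta matrix file needs a probe column plus samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_beta_matrix(m)
}

#' Write a beta matrix to a TSV file
#'
#' @param x a beta matrix (probes x samples).
#' @param path output path.
#' @param probe_col header for the probe-id column.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(x, path, probe_col = "probe_id") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- probe_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
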