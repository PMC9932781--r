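#' Average replicates into a timepoint matrix
#'
#' Collapses a transcripts x samples TPM matrix to transcripts x
#' timepoints by the arithmetic mean over each timepoint's replicates.
#'
#' @param se A `SummarizedExperiment` from [readQuantTables()] (assay
#'   `"TPM"`, column data with `timepoint_h`).
#' @return Numeric matrix (transcripts x timepoints) with columns named
#'   by timepoint and an attribute `timepoints_h` giving the ascending
#'   numeric time axis.
#' @export
averageReplicates <- function(se) {
  mat <- SummarizedExperiment::assay(se, "TPM")
  tp <- SummarizedExperiment::colData(se)$timepoint_h
  if (is.null(tp)) stop("column data must carry timepoint_h")
  tps <- sort(unique(tp))
  out <- vapply(tps, function(t) {
    cols <- which(tp == t)
    if (!length(cols)) stop(sprintf("timepoint %g h has no samples", t))
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), sprintf("%g", tps)))
  attr(out, "timepoints_h") <- tps
  out
}

#' Row-wise Z-score standardization
#'
#' Standardizes each transcript's time profile: subtract the mean over
#' all timepoints and divide by the standard deviation over all
#' timepoints (sample sd, n-1 denominator, by default). Rows with zero
#' variance cannot be standardized and are reported separately rather
#' than scored.
#'
#' The transform is invariant to positive affine rescaling of a row:
#' `a*x + b` (a > 0) yields the same Z profile as `x`, so TPM scale and
#' baseline do not influence downstream correlations.
#'
#' @param tm Timepoint matrix from [averageReplicates()] (or any numeric
#'   matrix with >= 2 columns).
#' @param timepoints Numeric time axis; defaults to the matrix's
#'   `timepoints_h` attribute or, failing that, its numeric column names.
#' @param sdType `"sample"` (n-1, default) or `"population"` (n) for the
#'   denominator.
#' @param log2Offset If non-`NULL`, rows are transformed to
#'   `log2(x + log2Offset)` before standardization. Default off: the
#'   Z-scores are taken on the TPM scale directly.
#' @return A [ZScoreMatrix-class] object.
#' @examples
#' tm <- matrix(c(2, 4, 6, 5, 5, 5), nrow = 2, byrow = TRUE,
#'              dimnames = list(c("t1", "t2"), c("0", "1", "3")))
#' z <- zscoreProfiles(tm)
#' zscores(z)        # t1 -> (-1, 0, 1)
#' degenerateIds(z)  # "t2": constant profile
#' @export
zscoreProfiles <- function(tm, timepoints = NULL,
                           sdType = c("sample", "population"),
                           log2Offset = NULL) {
  sdType <- match.arg(sdType)
  if (is.null(timepoints)) {
    timepoints <- attr(tm, "timepoints_h")
    if (is.null(timepoints)) timepoints <- as.numeric(colnames(tm))
  }
  if (anyNA(timepoints) || length(timepoints) != ncol(tm))
    stop("a numeric timepoint for every column is required")
  if (ncol(tm) < 2L) stop("at least 2 timepoints are required")
  if (is.null(rownames(tm))) stop("tm must have transcript rownames")
  x <- as.matrix(tm)
  if (!is.null(log2Offset)) x <- log2(x + log2Offset)
  mu <- rowMeans(x)
  n <- ncol(x)
  ss <- rowSums((x - mu)^2)
  sdv <- sqrt(ss / if (sdType == "sample") (n - 1) else n)
  degenerate <- sdv == 0 | !is.finite(sdv)
  z <- (x - mu) / sdv
  z <- z[!degenerate, , drop = FALSE]
  colnames(z) <- sprintf("%g", timepoints)
  methods::new("ZScoreMatrix",
               values = z,
               timepoints = as.numeric(timepoints),
               degenerateIds = rownames(tm)[degenerate])
}
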