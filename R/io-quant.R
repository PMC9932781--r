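#' Build and validate a sample design table
#'
#' The design table ties each quantified sample to its heat-stress
#' timepoint (hours) and biological replicate. The study layout this
#' package targets is a time course of {0, 1, 3, 6, 12, 24, 36, 48} h
#' with 3 replicates per timepoint, but any design with at least one
#' replicate per timepoint is accepted.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param timepoint_h Numeric vector of non-negative timepoints in hours.
#' @param replicate Positive integer vector of replicate indices.
#' @return A `data.frame` with columns `sample_id`, `timepoint_h`,
#'   `replicate`, ordered by ascending timepoint then replicate.
#' @examples
#' sampleDesign(paste0("s", 1:6), rep(c(0, 1), each = 3), rep(1:3, 2))
#' @export
sampleDesign <- function(sample_id, timepoint_h, replicate) {
  sample_id <- as.character(sample_id)
  timepoint_h <- as.numeric(timepoint_h)
  replicate <- as.integer(replicate)
  n <- length(sample_id)
  if (length(timepoint_h) != n || length(replicate) != n)
    stop("sample_id, timepoint_h and replicate must have equal length")
  if (anyDuplicated(sample_id))
    stop("sample_ids must be unique")
  if (any(!is.finite(timepoint_h)) || any(timepoint_h < 0))
    stop("timepoint_h must be finite and non-negative")
  if (any(is.na(replicate)) || any(replicate < 1L))
    stop("replicate must be a positive integer")
  d <- data.frame(sample_id = sample_id, timepoint_h = timepoint_h,
                  replicate = replicate, stringsAsFactors = FALSE)
  d <- d[order(d$timepoint_h, d$replicate), , drop = FALSE]
  rownames(d) <- d$sample_id
  d
}

.read_one_quant <- function(path) {
  if (!file.exists(path)) stop(sprintf("quantification file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("Name", "TPM") %in% names(tab)))
    stop(sprintf("file %s lacks required columns Name and TPM", path))
  if (anyDuplicated(tab$Name)) {
    dup <- tab$Name[duplicated(tab$Name)][1L]
    stop(sprintf("duplicate transcript id '%s' in %s", dup, path))
  }
  tpm <- suppressWarnings(as.numeric(tab$TPM))
  bad <- which(is.na(tpm) & !tab$TPM %in% c("NA", ""))
  if (length(bad))
    stop(sprintf("non-numeric TPM value '%s' in %s at line %d",
                 tab$TPM[bad[1L]], path, bad[1L] + 1L))
  if (anyNA(tpm))
    stop(sprintf("missing TPM value in %s", path))
  if (any(tpm < 0))
    stop(sprintf("negative TPM value in %s", path))
  stats::setNames(tpm, tab$Name)
}

#' Read transcript quantifications into a SummarizedExperiment
#'
#' Assembles a transcripts x samples TPM matrix either from one
#' quantification file per sample (tab-separated, quant.sf dialect with
#' at least `Name` and `TPM` columns) or from a single TSV matrix whose
#' first column holds transcript ids and whose remaining columns are
#' named by sample id.
#'
#' Transcripts absent from one sample's table are imputed as 0 TPM:
#' quantifiers omit unexpressed transcripts, and the union assembly is
#' lossless.
#'
#' @param paths Character vector of file paths. For per-sample mode,
#'   either named by `sample_id` or given in the order of `design`.
#' @param design A design table from [sampleDesign()].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"TPM"` and `design` as column data, columns in design order.
#' @seealso [writeExpressionMatrix()]
#' @export
readQuantTables <- function(paths, design) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "timepoint_h", "replicate") %in% names(design)))
  if (length(paths) == 1L && file.exists(paths[1L])) {
    # sniff the dialect: a quant.sf header names Name and TPM columns
    hdr <- strsplit(readLines(paths[1L], n = 1L), "\t", fixed = TRUE)[[1L]]
    if (!all(c("Name", "TPM") %in% hdr))
      return(.read_matrix_tsv(paths, design))
  }
  ids <- design$sample_id
  if (is.null(names(paths))) {
    if (length(paths) != nrow(design))
      stop("unnamed paths must match the design row for row")
    names(paths) <- ids
  }
  missing <- setdiff(ids, names(paths))
  if (length(missing))
    stop(sprintf("no quantification file for sample(s): %s",
                 paste(missing, collapse = ", ")))
  per <- lapply(paths[ids], .read_one_quant)
  tx <- unique(unlist(lapply(per, names), use.names = FALSE))
  mat <- matrix(0, nrow = length(tx), ncol = length(ids),
                dimnames = list(tx, ids))
  for (s in ids) {
    v <- per[[s]]
    mat[names(v), s] <- v
  }
  .tpm_se(mat, design)
}

.read_matrix_tsv <- function(path, design) {
  if (!file.exists(path)) stop(sprintf("matrix file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  tx <- as.character(tab[[1L]])
  if (anyDuplicated(tx))
    stop(sprintf("duplicate transcript id '%s' in %s",
                 tx[duplicated(tx)][1L], path))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(mat))
    stop(sprintf("non-numeric TPM values in %s", path))
  rownames(mat) <- tx
  missing <- setdiff(design$sample_id, colnames(mat))
  if (length(missing))
    stop(sprintf("matrix %s lacks sample column(s): %s", path,
                 paste(missing, collapse = ", ")))
  .tpm_se(mat[, design$sample_id, drop = FALSE], design)
}

.tpm_se <- function(mat, design) {
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("TPM values must be finite and non-negative")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(TPM = mat),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

#' Write / read an expression matrix as TSV
#'
#' `writeExpressionMatrix()` writes the TPM assay as a plain TSV matrix
#' (first column `transcript_id`, one column per sample);
#' `readQuantTables()` in single-file mode reads it back. Values survive
#' the round trip to well below 1e-9.
#'
#' @param se A `SummarizedExperiment` with a `"TPM"` assay.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  mat <- SummarizedExperiment::assay(se, "TPM")
  df <- data.frame(transcript_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
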