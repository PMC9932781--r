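#' Construct a TranscriptModels object
#'
#' Normalizes exon order to the transcript 5' to 3' direction (ascending
#' genomic start on the plus strand, descending on the minus strand) and
#' validates the structure: exons must not overlap, and CDS intervals
#' (with any separate stop-codon features already merged in) must lie
#' within exons.
#'
#' @param exons `GRangesList` of exons per transcript, named by
#'   transcript id.
#' @param cds `GRangesList` of coding intervals per transcript (may have
#'   zero-length elements); defaults to no CDS anywhere.
#' @param txGene Named character vector transcript id -> gene id; by
#'   default each transcript is its own gene.
#' @return A [TranscriptModels-class] object.
#' @export
TranscriptModels <- function(exons, cds = NULL, txGene = NULL) {
  tx <- names(exons)
  if (is.null(tx)) stop("exons must be named by transcript id")
  if (is.null(cds)) {
    cds <- GenomicRanges::GRangesList(lapply(tx, function(t) GenomicRanges::GRanges()))
    names(cds) <- tx
  }
  if (is.null(txGene)) txGene <- stats::setNames(tx, tx)
  cds <- cds[tx]
  txGene <- txGene[tx]
  exons <- .order_grl_5p_to_3p(exons)
  cds <- .order_grl_5p_to_3p(cds)
  methods::new("TranscriptModels", exons = exons, cds = cds, txGene = txGene)
}

# vectorized 5'->3' ordering of every element of a GRangesList: sort by
# ascending position, then reverse the minus-strand elements
.order_grl_5p_to_3p <- function(grl) {
  if (!length(grl)) return(grl)
  grl <- GenomicRanges::sort(grl, ignore.strand = TRUE)
  st <- unique(GenomicRanges::strand(grl))
  minus <- vapply(seq_along(grl), function(i) {
    s <- st[[i]]
    length(s) == 1L && as.character(s) == "-"
  }, logical(1))
  if (any(minus)) grl[minus] <- S4Vectors::revElements(grl[minus])
  grl
}

.order_5p_to_3p <- function(gr) {
  if (length(gr) == 0L) return(gr)
  st <- unique(as.character(GenomicRanges::strand(gr)))
  if (length(st) != 1L) stop("a transcript's intervals must share one strand")
  o <- order(GenomicRanges::start(gr), decreasing = identical(st, "-"))
  gr[o]
}

.attr_or_na <- function(gr, nm) {
  m <- S4Vectors::mcols(gr)
  if (nm %in% names(m)) as.character(m[[nm]]) else rep(NA_character_, length(gr))
}

#' Read transcript models from GTF/GFF3
#'
#' Parses exon and CDS features (via \pkg{rtracklayer}) into a
#' [TranscriptModels-class] object. Coordinates are kept 1-based
#' inclusive as in the file. Dedicated `stop_codon` features, a GTF
#' dialect that excludes the stop codon from the CDS, are merged into the
#' CDS so that the stop-codon end is uniformly the end of the last coding
#' interval.
#'
#' @param path Path to a GTF or GFF3 file.
#' @return A [TranscriptModels-class] object.
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS", "stop_codon")
  gr <- gr[keep]
  type <- type[keep]
  if (!length(gr)) stop(sprintf("no exon/CDS features in %s", path))
  tx <- .attr_or_na(gr, "transcript_id")
  if (anyNA(tx)) {
    par <- .attr_or_na(gr, "Parent")
    tx[is.na(tx)] <- sub("^transcript:", "", par[is.na(tx)])
  }
  if (anyNA(tx) || any(tx == ""))
    stop(sprintf("feature without transcript attribute in %s", path))
  gene <- .attr_or_na(gr, "gene_id")
  gene[is.na(gene)] <- tx[is.na(gene)]
  S4Vectors::mcols(gr) <- NULL
  txs <- unique(tx)
  exons <- GenomicRanges::GRangesList(lapply(stats::setNames(txs, txs), function(t) {
    gr[tx == t & type == "exon"]
  }))
  cds <- GenomicRanges::GRangesList(lapply(stats::setNames(txs, txs), function(t) {
    g <- gr[tx == t & type %in% c("CDS", "stop_codon")]
    if (length(g) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(g)
  }))
  txGene <- stats::setNames(vapply(txs, function(t) gene[tx == t][1L], ""), txs)
  TranscriptModels(exons, cds, txGene)
}

#' Write transcript models as GTF
#'
#' Emits exon and CDS lines (tab-separated, 1-based inclusive) with
#' `transcript_id` and `gene_id` attributes. Output is byte-stable for
#' identical input, so file hashes can serve as provenance.
#'
#' @param models A [TranscriptModels-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readGtf()]
#' @export
writeGtf <- function(models, path) {
  stopifnot(methods::is(models, "TranscriptModels"))
  lines <- character(0)
  for (tx in transcriptIds(models)) {
    gene <- txGeneMap(models)[[tx]]
    attr9 <- sprintf('transcript_id "%s"; gene_id "%s";', tx, gene)
    for (set in list(c("exon", "exons"), c("CDS", "cds"))) {
      g <- methods::slot(models, set[2L])[[tx]]
      if (length(g) == 0L) next
      g <- g[order(GenomicRanges::start(g))]
      lines <- c(lines, sprintf("%s\theatSpliceNet\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                as.character(GenomicRanges::seqnames(g)), set[1L],
                                GenomicRanges::start(g), GenomicRanges::end(g),
                                as.character(GenomicRanges::strand(g)), attr9))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Transcript length from exon structure
#'
#' @param models A [TranscriptModels-class] object.
#' @return Named integer vector of mature-transcript lengths (sum of exon
#'   widths).
#' @export
transcriptLengths <- function(models) {
  vapply(stats::setNames(transcriptIds(models), transcriptIds(models)),
         function(tx) sum(GenomicRanges::width(exonModels(models)[[tx]])),
         integer(1))
}
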