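#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges GRangesList start end strand width seqnames
#' @importFrom IRanges IRanges
NULL

setOldClass("hclust")

#' Transcript models: exon and CDS structure per transcript
#'
#' Holds the genomic exon and CDS intervals of a set of transcripts,
#' together with the transcript-to-gene map. Coordinates are 1-based
#' inclusive genomic positions (GTF convention); transcript coordinates
#' derived from them (see [transcriptJunctions()]) are 1-based from the
#' 5' end of the mature transcript.
#'
#' @slot exons A [GenomicRanges::GRangesList], one element per transcript,
#'   holding that transcript's exons in genomic coordinates. Element names
#'   are transcript ids.
#' @slot cds A parallel `GRangesList` with the coding intervals of each
#'   transcript (zero-length for non-coding transcripts). Any dedicated
#'   stop-codon intervals are expected to be merged into the CDS.
#' @slot txGene Named character vector mapping transcript id to gene id.
#'
#' @section Validity:
#' Exons of a transcript must not overlap each other; every CDS base must
#' fall inside an exon; names of `exons`, `cds` and `txGene` must agree.
#'
#' @seealso [readGtf()], [transcriptJunctions()], [nmdFlags()]
#' @export
setClass("TranscriptModels",
  representation(
    exons  = "GRangesList",
    cds    = "GRangesList",
    txGene = "character"
  )
)

setValidity("TranscriptModels", function(object) {
  ex <- object@exons
  cd <- object@cds
  tg <- object@txGene
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("exons must be named by unique transcript ids")
  if (!identical(names(ex), names(cd)))
    return("exons and cds must share transcript names in the same order")
  if (!identical(names(ex), names(tg)))
    return("txGene must be named by the same transcripts as exons")
  nex <- lengths(ex)
  if (any(nex == 0L))
    return(sprintf("transcript '%s' has no exons", names(ex)[nex == 0L][1L]))
  strands <- unique(GenomicRanges::strand(ex))
  if (any(lengths(strands) != 1L))
    return(sprintf("transcript '%s' mixes strands",
                   names(ex)[lengths(strands) != 1L][1L]))
  wEx <- sum(GenomicRanges::width(ex))
  red <- GenomicRanges::reduce(ex)
  wRed <- sum(GenomicRanges::width(red))
  if (any(wEx != wRed))
    return(sprintf("exons of transcript '%s' overlap",
                   names(ex)[wEx != wRed][1L]))
  redCds <- GenomicRanges::reduce(cd)
  wCds <- sum(GenomicRanges::width(redCds))
  # per-transcript covered CDS width, computed on the unlisted ranges
  # (pairing CDS intervals with exons of the same transcript)
  uc <- unlist(redCds, use.names = FALSE)
  ue <- unlist(red, use.names = FALSE)
  txC <- rep(names(redCds), lengths(redCds))
  txE <- rep(names(red), lengths(red))
  hits <- GenomicRanges::findOverlaps(uc, ue)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  same <- txC[q] == txE[s]
  ovw <- pmin(GenomicRanges::end(uc)[q], GenomicRanges::end(ue)[s]) -
    pmax(GenomicRanges::start(uc)[q], GenomicRanges::start(ue)[s]) + 1L
  covered <- vapply(names(red), function(t) {
    sum(ovw[same & txC[q] == t])
  }, numeric(1))
  if (any(covered != wCds))
    return(sprintf("CDS of transcript '%s' extends outside its exons",
                   names(ex)[covered != wCds][1L]))
  TRUE
})

#' Standardized time-course profiles
#'
#' Per-transcript Z-score profiles over the timepoints of a design:
#' each retained row has mean 0 and (sample) standard deviation 1 across
#' timepoints. Transcripts whose replicate-averaged profile has zero
#' variance cannot be standardized and are set aside in `degenerateIds`.
#'
#' @slot values Numeric matrix, transcripts x timepoints, dimensionless.
#' @slot timepoints Numeric vector of timepoints in hours, ascending.
#' @slot degenerateIds Character vector of transcripts excluded for zero
#'   variance.
#'
#' @seealso [zscoreProfiles()]
#' @export
setClass("ZScoreMatrix",
  representation(
    values        = "matrix",
    timepoints    = "numeric",
    degenerateIds = "character"
  )
)

setValidity("ZScoreMatrix", function(object) {
  v <- object@values
  if (ncol(v) != length(object@timepoints))
    return("ncol(values) must equal length(timepoints)")
  if (is.unsorted(object@timepoints, strictly = TRUE))
    return("timepoints must be strictly ascending")
  if (nrow(v) > 0L) {
    if (is.null(rownames(v))) return("values must have transcript rownames")
    m <- rowMeans(v)
    s <- apply(v, 1L, stats::sd)
    # population-sd standardization is tolerated: sample sd then equals
    # sqrt(n/(n-1)) rather than 1
    pop <- s * sqrt((ncol(v) - 1) / ncol(v))
    if (any(abs(m) > 1e-8) ||
        any(abs(s - 1) > 1e-8 & abs(pop - 1) > 1e-8))
      return("every retained row must have mean 0 and sd 1")
  }
  if (any(object@degenerateIds %in% rownames(v)))
    return("degenerateIds must not appear among retained rows")
  TRUE
})

#' Co-expression module assignment
#'
#' The result of hybrid dynamic tree cutting: an integer module label per
#' transcript, where 0 marks the unassigned/outlier pool and labels
#' 1..K are ordered by decreasing module size.
#'
#' @slot labels Named integer vector (names are transcript ids); 0 means
#'   unassigned.
#' @slot dendrogram The `hclust` object the cut was applied to.
#' @slot params List of cut parameters (deepSplit, minClusterSize,
#'   maxCoreScatter, minGap, cutHeight).
#'
#' @seealso [cutModules()], [dropOutlierCluster()]
#' @export
setClass("SpliceModules",
  representation(
    labels     = "integer",
    dendrogram = "ANY",
    params     = "list"
  )
)

setValidity("SpliceModules", function(object) {
  lab <- object@labels
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    return("labels must be named by unique transcript ids")
  if (any(lab < 0L)) return("labels must be >= 0")
  pos <- lab[lab > 0L]
  if (length(pos)) {
    k <- max(pos)
    sizes <- tabulate(pos, nbins = k)
    if (any(sizes == 0L)) return("module labels must be consecutive 1..K")
    if (is.unsorted(rev(sizes))) return("module labels must be ordered by decreasing size")
  }
  TRUE
})

#' Bipartite cluster-regulator splicing network
#'
#' Edges connect DTU-transcript modules (by integer cluster id) to
#' regulator transcripts, weighted by the Pearson correlation between the
#' module centroid and the regulator's Z-score profile. Only edges with
#' `abs(r) >= threshold` are retained; the threshold is the top-percentile
#' order statistic of the candidate pool.
#'
#' @slot edges `data.frame` with columns `cluster_id` (integer),
#'   `regulator_id` (character) and `r` (numeric Pearson correlation).
#' @slot threshold Minimum absolute correlation tau retained.
#' @slot topFraction The fraction of the candidate pool retained (e.g.
#'   0.01 for the top 1 percent).
#' @slot temporalClass Named character vector per retained cluster id:
#'   `"early"`, `"late"` or `"unclassified"`.
#'
#' @seealso [buildNetwork()], [percentileThreshold()], [classifyTemporal()]
#' @export
setClass("SpliceNetwork",
  representation(
    edges         = "data.frame",
    threshold     = "numeric",
    topFraction   = "numeric",
    temporalClass = "character"
  )
)

setValidity("SpliceNetwork", function(object) {
  ed <- object@edges
  need <- c("cluster_id", "regulator_id", "r")
  if (!all(need %in% names(ed)))
    return("edges must have columns cluster_id, regulator_id, r")
  if (nrow(ed) && any(abs(ed$r) < object@threshold - 1e-12))
    return("every edge must satisfy abs(r) >= threshold")
  if (length(object@threshold) != 1L || length(object@topFraction) != 1L)
    return("threshold and topFraction must be scalars")
  bad <- setdiff(object@temporalClass, c("early", "late", "unclassified"))
  if (length(bad)) return("temporalClass values must be early/late/unclassified")
  TRUE
})
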