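#' @include AllClasses.R
NULL

#' Accessors for heatSpliceNet classes
#'
#' Small accessor generics for the package's S4 containers; prefer these
#' over direct slot access.
#'
#' @param x A [TranscriptModels-class], [ZScoreMatrix-class],
#'   [SpliceModules-class] or [SpliceNetwork-class] object.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))

#' @rdname accessors
#' @export
setGeneric("exonModels", function(x) standardGeneric("exonModels"))

#' @rdname accessors
#' @export
setGeneric("cdsModels", function(x) standardGeneric("cdsModels"))

#' @rdname accessors
#' @export
setGeneric("txGeneMap", function(x) standardGeneric("txGeneMap"))

#' @rdname accessors
#' @export
setGeneric("zscores", function(x) standardGeneric("zscores"))

#' @rdname accessors
#' @export
setGeneric("profileTimepoints", function(x) standardGeneric("profileTimepoints"))

#' @rdname accessors
#' @export
setGeneric("degenerateIds", function(x) standardGeneric("degenerateIds"))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname accessors
#' @export
setGeneric("temporalClass", function(x) standardGeneric("temporalClass"))

#' @rdname accessors
setMethod("transcriptIds", "TranscriptModels", function(x) names(x@exons))

#' @rdname accessors
setMethod("transcriptIds", "ZScoreMatrix", function(x) rownames(x@values))

#' @rdname accessors
setMethod("exonModels", "TranscriptModels", function(x) x@exons)

#' @rdname accessors
setMethod("cdsModels", "TranscriptModels", function(x) x@cds)

#' @rdname accessors
setMethod("txGeneMap", "TranscriptModels", function(x) x@txGene)

#' @rdname accessors
setMethod("zscores", "ZScoreMatrix", function(x) x@values)

#' @rdname accessors
setMethod("profileTimepoints", "ZScoreMatrix", function(x) x@timepoints)

#' @rdname accessors
setMethod("degenerateIds", "ZScoreMatrix", function(x) x@degenerateIds)

#' @rdname accessors
setMethod("moduleLabels", "SpliceModules", function(x) x@labels)

#' @rdname accessors
setMethod("moduleSizes", "SpliceModules", function(x) {
  pos <- x@labels[x@labels > 0L]
  if (!length(pos)) return(integer(0))
  tabulate(pos, nbins = max(pos))
})

#' @rdname accessors
setMethod("networkEdges", "SpliceNetwork", function(x) x@edges)

#' @rdname accessors
setMethod("networkThreshold", "SpliceNetwork", function(x) x@threshold)

#' @rdname accessors
setMethod("temporalClass", "SpliceNetwork", function(x) x@temporalClass)

setMethod("show", "TranscriptModels", function(object) {
  cat("TranscriptModels with", length(object@exons), "transcripts from",
      length(unique(object@txGene)), "genes\n")
  ncds <- sum(lengths(object@cds) > 0L)
  cat("  coding transcripts:", ncds, "\n")
})

setMethod("show", "ZScoreMatrix", function(object) {
  cat("ZScoreMatrix:", nrow(object@values), "transcripts x",
      length(object@timepoints), "timepoints (h):",
      paste(object@timepoints, collapse = ", "), "\n")
  if (length(object@degenerateIds))
    cat("  excluded zero-variance transcripts:",
        length(object@degenerateIds), "\n")
})

setMethod("show", "SpliceModules", function(object) {
  sizes <- moduleSizes(object)
  cat("SpliceModules:", length(object@labels), "transcripts in",
      length(sizes), "modules;", sum(object@labels == 0L),
      "unassigned (label 0)\n")
  if (length(sizes))
    cat("  module sizes:", paste(sizes, collapse = ", "), "\n")
})

setMethod("show", "SpliceNetwork", function(object) {
  ed <- object@edges
  cat("SpliceNetwork:", nrow(ed), "edges between",
      length(unique(ed$cluster_id)), "clusters and",
      length(unique(ed$regulator_id)), "regulator transcripts\n")
  cat(sprintf("  |r| >= %.6f (top fraction %.4g)\n",
              object@threshold, object@topFraction))
  if (length(object@temporalClass)) {
    tc <- table(factor(object@temporalClass,
                       levels = c("early", "late", "unclassified")))
    cat("  clusters:", tc[["early"]], "early,", tc[["late"]], "late,",
        tc[["unclassified"]], "unclassified\n")
  }
})
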