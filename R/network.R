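#' Filter the regulator candidate catalog
#'
#' A splicing-factor/RBP transcript is kept as a network regulator
#' candidate when it is heat-responsive (differentially expressed or
#' differentially alternatively spliced), codes for a functional protein,
#' and carries a nuclear localisation signal.
#'
#' @param catalog `data.frame` with columns `transcript_id`, `is_DE`,
#'   `is_DAS`, `is_protein_coding`, `has_NLS` (logical flags).
#' @return Character vector of retained regulator transcript ids.
#' @export
filterRegulators <- function(catalog) {
  need <- c("transcript_id", "is_DE", "is_DAS", "is_protein_coding", "has_NLS")
  if (!all(need %in% names(catalog)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  flags <- catalog[, setdiff(need, "transcript_id")]
  if (anyNA(flags)) stop("catalog flags must be defined for every transcript")
  keep <- (catalog$is_DE | catalog$is_DAS) &
    catalog$is_protein_coding & catalog$has_NLS
  as.character(catalog$transcript_id[keep])
}

#' Cluster centroids of Z-score profiles
#'
#' The centroid of a module is the per-timepoint arithmetic mean of its
#' member transcripts' Z-scores -- the module's consensus time profile.
#'
#' @param z A [ZScoreMatrix-class] over the clustered transcripts.
#' @param modules A [SpliceModules-class]; only positive labels are used.
#' @return Numeric matrix, one row per cluster (rownames are cluster
#'   ids), columns the timepoints.
#' @export
clusterCentroids <- function(z, modules) {
  lab <- moduleLabels(modules)
  lab <- lab[lab > 0L]
  if (!length(lab)) stop("no non-outlier clusters to summarise")
  zm <- zscores(z)
  missing <- setdiff(names(lab), rownames(zm))
  if (length(missing))
    stop("Z-scores missing for clustered transcript(s): ",
         paste(utils::head(missing, 3L), collapse = ", "))
  ks <- sort(unique(lab))
  cent <- t(vapply(ks, function(k) {
    colMeans(zm[names(lab)[lab == k], , drop = FALSE])
  }, numeric(ncol(zm))))
  rownames(cent) <- ks
  colnames(cent) <- colnames(zm)
  cent
}

#' Correlate cluster centroids with regulator profiles
#'
#' Forms the full candidate pool of the bipartite network: one Pearson
#' correlation per (cluster, regulator) pair over the shared time axis.
#' Regulators with a degenerate (zero-variance) profile are excluded
#' with a warning.
#'
#' @param centroids Matrix from [clusterCentroids()].
#' @param regulatorZ A [ZScoreMatrix-class] (or matrix) of regulator
#'   profiles over the same timepoints.
#' @return `data.frame` of candidate edges: `cluster_id`,
#'   `regulator_id`, `r`.
#' @export
correlateRegulators <- function(centroids, regulatorZ) {
  rz <- if (methods::is(regulatorZ, "ZScoreMatrix")) zscores(regulatorZ)
        else as.matrix(regulatorZ)
  if (ncol(rz) != ncol(centroids))
    stop("centroids and regulator profiles must share the time axis")
  sdv <- apply(rz, 1L, stats::sd)
  degen <- sdv == 0 | !is.finite(sdv)
  if (any(degen)) {
    warning(sprintf("excluding %d degenerate regulator profile(s): %s",
                    sum(degen),
                    paste(utils::head(rownames(rz)[degen], 3L), collapse = ", ")))
    rz <- rz[!degen, , drop = FALSE]
  }
  if (!nrow(rz)) stop("no non-degenerate regulator profiles")
  r <- stats::cor(t(centroids), t(rz))
  data.frame(
    cluster_id = rep(as.integer(rownames(centroids)), times = nrow(rz)),
    regulator_id = rep(rownames(rz), each = nrow(centroids)),
    r = as.vector(r),
    stringsAsFactors = FALSE)
}

#' Top-percentile threshold over candidate edges
#'
#' Nearest-rank percentile rule: with `N` candidates, the
#' `m = ceiling(topFraction * N)`-th largest absolute correlation is the
#' threshold tau, and every candidate with `|r| >= tau` is retained --
#' ties at tau are all kept, so the retained count can exceed `m`.
#'
#' @param candidates `data.frame` from [correlateRegulators()] (columns
#'   `cluster_id`, `regulator_id`, `r`).
#' @param topFraction Fraction of the pool to keep (default 0.01, the
#'   top 1 percent).
#' @return List with `threshold` (tau) and `edges` (the retained rows).
#' @export
percentileThreshold <- function(candidates, topFraction = 0.01) {
  if (!nrow(candidates)) stop("candidate edge list is empty")
  if (topFraction <= 0 || topFraction >= 1)
    stop("topFraction must be in (0, 1)")
  absr <- abs(candidates$r)
  m <- ceiling(topFraction * length(absr))
  tau <- sort(absr, decreasing = TRUE)[m]
  list(threshold = tau,
       edges = candidates[absr >= tau, , drop = FALSE])
}

#' Classify a cluster's temporal response
#'
#' Finds the timepoint `t*` of largest absolute departure from the 0-h
#' level. A cluster responds early if `t* <= 6` h (up- or
#' down-regulation within the first 6 h); late if `t* >= 12` h and the
#' departure is an up-regulation; otherwise it is unclassified. Flat
#' profiles are unclassified.
#'
#' @param profile Numeric centroid profile over `timepoints`.
#' @param timepoints Numeric time axis in hours (first entry is the
#'   unstressed 0-h reference).
#' @return `"early"`, `"late"` or `"unclassified"`.
#' @export
classifyTemporal <- function(profile, timepoints) {
  stopifnot(length(profile) == length(timepoints),
            !is.unsorted(timepoints, strictly = TRUE))
  delta <- profile - profile[1L]
  if (all(abs(delta) < 1e-12)) return("unclassified")
  idx <- which.max(abs(delta[-1L])) + 1L
  tstar <- timepoints[idx]
  if (tstar <= 6) return("early")
  if (tstar >= 12 && delta[idx] > 0) return("late")
  "unclassified"
}

#' Assemble the bipartite splicing network
#'
#' Nodes are the clusters and regulator transcripts with at least one
#' retained edge; each retained cluster is classified early/late from
#' its centroid. The correlation sign is kept on the edges even though
#' thresholding is on `|r|`.
#'
#' @param edges Retained edge `data.frame` (`cluster_id`, `regulator_id`,
#'   `r`), e.g. `percentileThreshold(...)$edges`.
#' @param threshold The tau the edges were filtered at.
#' @param topFraction The pool fraction used (recorded on the object).
#' @param centroids Centroid matrix from [clusterCentroids()] (used for
#'   temporal classification of the retained clusters).
#' @param timepoints Numeric time axis for the centroids.
#' @return A [SpliceNetwork-class] object.
#' @export
buildNetwork <- function(edges, threshold, topFraction, centroids = NULL,
                         timepoints = NULL) {
  edges <- as.data.frame(edges)[, c("cluster_id", "regulator_id", "r")]
  if (nrow(edges) && any(abs(edges$r) < threshold - 1e-12))
    stop("edges below the threshold supplied")
  tc <- character(0)
  if (!is.null(centroids) && nrow(edges)) {
    if (is.null(timepoints)) timepoints <- as.numeric(colnames(centroids))
    keep <- intersect(rownames(centroids),
                      as.character(sort(unique(edges$cluster_id))))
    tc <- vapply(keep, function(k) {
      classifyTemporal(centroids[k, ], timepoints)
    }, character(1))
  }
  methods::new("SpliceNetwork", edges = edges, threshold = threshold,
               topFraction = topFraction, temporalClass = tc)
}
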