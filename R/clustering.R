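#' Pairwise Pearson correlation of Z-score profiles
#'
#' @param z A [ZScoreMatrix-class] object (or a numeric matrix of
#'   profiles in rows) with at least 3 timepoints.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(z) {
  x <- if (methods::is(z, "ZScoreMatrix")) zscores(z) else as.matrix(z)
  if (ncol(x) < 3L) stop("at least 3 timepoints are required")
  sdv <- apply(x, 1L, stats::sd)
  if (any(sdv == 0 | !is.finite(sdv)))
    stop("degenerate (zero-variance) rows present; exclude them first")
  r <- stats::cor(t(x))
  diag(r) <- 1
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |r_ij|^power`. The diagonal is
#' zeroed so that node connectivity excludes self-similarity. With
#' `signed = TRUE` the signed variant `((1 + r)/2)^power` is used
#' instead, which sends strong negative correlations toward 0.
#'
#' @param corr Correlation matrix from [pairwiseCorrelation()].
#' @param power Soft-threshold exponent beta, >= 1.
#' @param signed Use the signed transformation (default `FALSE`).
#' @return Adjacency matrix with values in `[0, 1]`, zero diagonal.
#' @export
adjacencyMatrix <- function(corr, power, signed = FALSE) {
  if (!is.numeric(power) || length(power) != 1L || power < 1)
    stop("power must be a single number >= 1")
  a <- if (signed) ((1 + corr) / 2)^power else abs(corr)^power
  diag(a) <- 0
  a
}

#' Node connectivity of a weighted network
#'
#' @param adj Adjacency matrix (zero diagonal).
#' @return Named vector `k_i = sum_{j != i} a_ij`.
#' @export
connectivity <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  rowSums(a)
}

#' Scale-free topology fit
#'
#' Measures how well the connectivity distribution follows a power law:
#' connectivities are binned into `nBins` equal-width bins, and
#' `log10(frequency)` is regressed on `log10(mean connectivity)` over the
#' non-empty bins. The R-squared of that regression is the fit index
#' used to pick the soft-threshold power.
#'
#' @param k Connectivity vector from [connectivity()].
#' @param nBins Number of equal-width bins (default 10).
#' @return List with `r_squared`, `slope`, `mean_k`, `n_bins_used`.
#' @export
scaleFreeFit <- function(k, nBins = 10L) {
  k <- as.numeric(k)
  if (length(k) < 2L) stop("need at least 2 connectivity values")
  rng <- range(k)
  if (diff(rng) == 0) stop("fewer than 2 non-empty bins: all connectivities equal")
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  meank <- vapply(seq_len(nBins), function(b) mean(k[as.integer(bin) == b]),
                  numeric(1))
  use <- counts > 0 & meank > 0
  if (sum(use) < 2L) stop("fewer than 2 non-empty bins")
  freq <- counts[use] / length(k)
  lx <- log10(meank[use])
  ly <- log10(freq)
  fit <- stats::lm(ly ~ lx)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2L]),
       mean_k = mean(k),
       n_bins_used = sum(use))
}

#' Choose the soft-threshold power from a fit table
#'
#' Given candidate powers and their scale-free fit indices, returns the
#' smallest power whose fit index reaches `target`. When no candidate
#' reaches the target, the elbow is used: fit-index gains between
#' consecutive candidates are computed and the candidate after which the
#' gain drops the most is selected (the point of diminishing returns).
#'
#' @param powers Ascending candidate powers.
#' @param rSquared Fit index per candidate.
#' @param target Fit-index goal (default 0.7).
#' @return The selected power.
#' @seealso [selectPower()]
#' @export
pickPowerFromFits <- function(powers, rSquared, target = 0.7) {
  if (!length(powers)) stop("candidate powers must be non-empty")
  stopifnot(length(powers) == length(rSquared),
            !is.unsorted(powers, strictly = TRUE))
  hit <- which(rSquared >= target)
  if (length(hit)) return(powers[hit[1L]])
  if (length(powers) == 1L) return(powers)
  gains <- c(rSquared[1L], diff(rSquared))
  if (length(gains) < 2L) return(powers[length(powers)])
  drops <- gains[-length(gains)] - gains[-1L]
  powers[which.max(drops)]
}

#' Select the soft-threshold power for a Z-score matrix
#'
#' Computes the scale-free fit index for each candidate power (adjacency
#' -> connectivity -> [scaleFreeFit()]) and applies
#' [pickPowerFromFits()]. The full fit table is returned so the choice
#' can be inspected, mirroring the elbow-heuristic workflow.
#'
#' @param z A [ZScoreMatrix-class] object.
#' @param candidates Ascending candidate powers
#'   (default `c(1:10, 12, 14, 16, 17, 18, 20)`).
#' @param target Fit-index goal (default 0.7).
#' @param nBins Bins for [scaleFreeFit()] (default 10).
#' @param signed Passed to [adjacencyMatrix()].
#' @return List with `power` (the selection) and `fit_table`
#'   (`data.frame` of power, r_squared, slope, mean_k).
#' @export
selectPower <- function(z, candidates = c(1:10, 12, 14, 16, 17, 18, 20),
                        target = 0.7, nBins = 10L, signed = FALSE) {
  if (!length(candidates)) stop("candidate powers must be non-empty")
  candidates <- sort(unique(candidates))
  corr <- pairwiseCorrelation(z)
  rows <- lapply(candidates, function(p) {
    k <- connectivity(adjacencyMatrix(corr, p, signed = signed))
    fit <- tryCatch(scaleFreeFit(k, nBins = nBins),
                    error = function(e) list(r_squared = NA_real_,
                                             slope = NA_real_,
                                             mean_k = mean(k)))
    data.frame(power = p, r_squared = fit$r_squared,
               slope = fit$slope, mean_k = fit$mean_k)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$r_squared)
  if (!any(ok)) stop("scale-free fit undefined for every candidate power")
  list(power = pickPowerFromFits(tab$power[ok], tab$r_squared[ok],
                                 target = target),
       fit_table = tab)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj`; the diagonal is 1. Shared neighbourhoods
#' raise the similarity of weakly connected but topologically close
#' nodes, which stabilises module detection relative to raw correlation.
#'
#' @param adj Adjacency matrix (zero diagonal, values in `[0, 1]`).
#' @return TOM similarity matrix (unit diagonal).
#' @export
tomSimilarity <- function(adj) {
  a <- as.matrix(adj)
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Average-linkage hierarchical clustering of a dissimilarity matrix
#'
#' Thin wrapper over [stats::hclust()] (UPGMA) with input validation:
#' the matrix must be symmetric with a zero diagonal.
#'
#' @param d Symmetric dissimilarity matrix, zero diagonal (e.g. `1 - TOM`
#'   or `1 - |r|`).
#' @return An `hclust` object (`n - 1` merges, non-decreasing heights).
#' @export
hierarchicalCluster <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop("dissimilarity matrix must have zero diagonal")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Module dissimilarity from Z-score profiles
#'
#' Convenience composition: correlation -> soft-threshold adjacency ->
#' dissimilarity `1 - similarity`, where the similarity is the soft-
#' threshold adjacency itself (`"adj"`, the default), its topological
#' overlap (`"tom"`), or the raw absolute correlation (`"corr"`).
#'
#' The adjacency dissimilarity `1 - |r|^power` is the default because
#' the soft threshold is what creates the contrast between module-level
#' and chance correlation; with short time-course profiles the TOM
#' transform can pull sparsely connected transcripts toward dense
#' modules (its denominator is governed by the smaller connectivity),
#' blurring module boundaries.
#'
#' @param z A [ZScoreMatrix-class] object.
#' @param power Soft-threshold power.
#' @param dissimilarity `"adj"` (default) for `1 - |r|^power`, `"tom"`
#'   for `1 - TOM`, or `"corr"` for `1 - |r|`.
#' @param signed Passed to [adjacencyMatrix()].
#' @return Symmetric dissimilarity matrix.
#' @export
moduleDissimilarity <- function(z, power,
                                dissimilarity = c("adj", "tom", "corr"),
                                signed = FALSE) {
  dissimilarity <- match.arg(dissimilarity)
  corr <- pairwiseCorrelation(z)
  if (dissimilarity == "corr") {
    d <- 1 - abs(corr)
  } else if (dissimilarity == "adj") {
    d <- 1 - adjacencyMatrix(corr, power, signed = signed)
  } else {
    d <- 1 - tomSimilarity(adjacencyMatrix(corr, power, signed = signed))
  }
  diag(d) <- 0
  # numerical symmetrization: cor()/crossprod round-off can leave ~1e-16
  (d + t(d)) / 2
}
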