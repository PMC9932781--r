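#' Hybrid dynamic tree cut
#'
#' Detects co-expression modules by adaptively cutting an average-linkage
#' dendrogram, following the hybrid (tree + dissimilarity) strategy:
#'
#' 1. Merges above `cutHeight` (a fraction of the dendrogram height) are
#'    ignored, so distant joins never glue separated branches together.
#' 2. Merges below `cutHeight` are replayed bottom-up while candidate
#'    branches grow. When two branches meet and both satisfy the branch
#'    criteria -- size at least `minClusterSize`, core scatter at most
#'    `maxCoreScatter`, and a merge gap of at least `minGap` (all on
#'    heights normalised to `[0, 1]` between the lowest merge and
#'    `cutHeight`) -- each is frozen as a module. A branch's core is its
#'    `minClusterSize + floor(sqrt(size - minClusterSize))` earliest-
#'    joining objects; core scatter is the mean normalised joining height
#'    of the core, and the gap is the distance from the core top to the
#'    height at which the branch meets its sibling.
#' 3. Objects that joined a frozen branch above the scatter ceiling, and
#'    objects in branches that never qualified, are left unlabelled, then
#'    offered to the modules in a medoid-style assignment stage: an
#'    object joins the module with the smallest average dissimilarity,
#'    provided that distance lies within the module's merging radius (the
#'    largest average member-to-module dissimilarity). Whatever remains
#'    is the outlier pool, label 0.
#'
#' `deepSplit` trades module homogeneity against outlier count: 0 (few,
#' coarse, large outlier pool) to 4 (most homogeneous modules, least
#' objects in the outlier pool). It maps linearly onto
#' `maxCoreScatter = 0.64 + 0.08 * deepSplit` with
#' `minGap = (1 - maxCoreScatter) * 3/4`.
#'
#' Module labels are renumbered by decreasing size, 0 reserved for the
#' outlier pool.
#'
#' @param dendro An `hclust` object over the same objects as `d`.
#' @param d The dissimilarity matrix the dendrogram was built from.
#' @param deepSplit Integer 0-4 (default 4).
#' @param minClusterSize Smallest admissible module (default 20).
#' @param cutHeightFraction Fraction of the top merge height below which
#'   merges are honoured (default 0.99).
#' @param assignOutliers Run the medoid-style assignment stage
#'   (default `TRUE`).
#' @return A [SpliceModules-class] object.
#' @seealso [dropOutlierCluster()], [moduleDissimilarity()]
#' @export
cutModules <- function(dendro, d, deepSplit = 4L, minClusterSize = 20L,
                       cutHeightFraction = 0.99, assignOutliers = TRUE) {
  stopifnot(inherits(dendro, "hclust"))
  if (!deepSplit %in% 0:4) stop("deepSplit must be an integer in 0..4")
  if (minClusterSize < 1L) stop("minClusterSize must be >= 1")
  d <- as.matrix(d)
  n <- length(dendro$order)
  if (nrow(d) != n) stop("dendrogram and dissimilarity disagree in size")
  labelsVec <- dendro$labels
  if (is.null(labelsVec)) labelsVec <- as.character(seq_len(n))

  maxCoreScatter <- 0.64 + 0.08 * deepSplit
  minGap <- (1 - maxCoreScatter) * 3 / 4

  heights <- dendro$height
  merge <- dendro$merge
  hMin <- min(heights)
  cutHeight <- hMin + cutHeightFraction * (max(heights) - hMin)
  span <- cutHeight - hMin
  u <- function(h) {
    if (span <= 0) return(rep(0, length(h)))
    pmin(1, pmax(0, (h - hMin) / span))
  }

  coreSize <- function(sz) {
    if (sz <= minClusterSize) sz
    else min(sz, minClusterSize + floor(sqrt(sz - minClusterSize)))
  }

  # branch bookkeeping: per merge id, members (leaf indices) and the
  # normalised height at which each member joined the growing branch
  branches <- vector("list", n - 1L)
  clusters <- list()      # locked module member sets
  floaters <- integer(0)  # members shed at lock time

  qualifies <- function(br, attachU) {
    sz <- length(br$members)
    if (sz < minClusterSize) return(FALSE)
    nc <- coreSize(sz)
    ju <- sort(br$joinU)
    core <- ju[seq_len(nc)]
    if (mean(core) > maxCoreScatter) return(FALSE)
    (attachU - core[nc]) >= minGap
  }

  # freeze a branch as a module; membership is settled afterwards by the
  # core-based refinement stage
  lock <- function(br) {
    ord <- order(br$joinU)
    clusters[[length(clusters) + 1L]] <<- br$members[ord]
  }

  getEntity <- function(idx, h) {
    if (idx < 0L) {
      list(members = -idx, joinU = u(h), composite = FALSE)
    } else {
      branches[[idx]]
    }
  }

  tops <- list()
  active <- rep(TRUE, n - 1L)
  for (i in seq_len(n - 1L)) {
    h <- heights[i]
    if (h > cutHeight) {
      active[i] <- FALSE
      # children below stay top-level; singleton children are floaters
      for (child in merge[i, ]) {
        if (child > 0L && active[child]) {
          tops[[length(tops) + 1L]] <- branches[[child]]
          active[child] <- FALSE
        } else if (child < 0L) {
          floaters <- c(floaters, -child)
        }
      }
      next
    }
    L <- getEntity(merge[i, 1L], h)
    R <- getEntity(merge[i, 2L], h)
    for (child in merge[i, ]) if (child > 0L) active[child] <- FALSE
    hu <- u(h)
    if (L$composite || R$composite) {
      for (e in list(L, R)) {
        if (!e$composite && qualifies(e, hu)) lock(e)
        else if (!e$composite) floaters <- c(floaters, e$members)
      }
      branches[[i]] <- list(members = c(L$members, R$members),
                            joinU = c(L$joinU, R$joinU), composite = TRUE)
    } else if (qualifies(L, hu) && qualifies(R, hu)) {
      lock(L); lock(R)
      branches[[i]] <- list(members = c(L$members, R$members),
                            joinU = c(L$joinU, R$joinU), composite = TRUE)
    } else {
      branches[[i]] <- list(members = c(L$members, R$members),
                            joinU = c(L$joinU, R$joinU), composite = FALSE)
    }
    active[i] <- TRUE
  }
  for (i in which(active)) tops[[length(tops) + 1L]] <- branches[[i]]

  for (br in tops) {
    if (br$composite) next
    if (qualifies(br, 1)) lock(br) else floaters <- c(floaters, br$members)
  }

  labels <- integer(n)
  for (ci in seq_along(clusters)) labels[clusters[[ci]]] <- ci

  if (assignOutliers && length(clusters)) {
    # refinement: each module is represented by its core (the earliest-
    # joining objects, stored in joining order at lock time). Sorting
    # every object by its average dissimilarity to a core separates the
    # module (low, dense) from the rest (high): the module boundary is
    # placed at the largest gap in that sorted sequence, searched between
    # the core size and half the universe (a module is never most of the
    # data). Objects below the boundary of several modules go to the
    # nearest one; objects below none are outliers.
    cores <- lapply(clusters, function(mem) mem[seq_len(coreSize(length(mem)))])
    avg <- vapply(cores, function(core) rowMeans(d[, core, drop = FALSE]),
                  numeric(n))
    avg <- matrix(avg, nrow = n)
    inside <- matrix(FALSE, n, length(cores))
    for (ci in seq_along(cores)) {
      a <- avg[, ci]
      ord <- order(a)
      lo <- length(cores[[ci]])
      hi <- min(n - 1L, max(lo, floor(n / 2)))
      gaps <- a[ord[(lo + 1L):(hi + 1L)]] - a[ord[lo:hi]]
      # stragglers of a module can open sizable gaps before the true
      # boundary; take the last gap comparable to the largest
      big <- which(gaps >= 0.5 * max(gaps))
      boundary <- lo + big[length(big)] - 1L
      inside[ord[seq_len(boundary)], ci] <- TRUE
    }
    # two locked branches can be halves of one module (their boundary
    # sets then largely coincide): merge clusters whose boundary sets
    # overlap in more than half of the smaller set
    k <- length(cores)
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    if (k > 1L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        ov <- sum(inside[, i] & inside[, j])
        if (ov > 0.5 * min(sum(inside[, i]), sum(inside[, j])))
          parent[find(j)] <- find(i)
      }
    }
    groups <- split(seq_len(k), vapply(seq_len(k), find, integer(1)))
    cores <- lapply(groups, function(g) unlist(cores[g]))
    inside <- vapply(groups, function(g) {
      apply(inside[, g, drop = FALSE], 1L, any)
    }, logical(n))
    inside <- matrix(inside, nrow = n)
    avg <- vapply(cores, function(core) rowMeans(d[, core, drop = FALSE]),
                  numeric(n))
    avg <- matrix(avg, nrow = n)
    labels <- integer(n)
    for (i in seq_len(n)) {
      cand <- which(inside[i, ])
      if (length(cand) == 1L) labels[i] <- cand
      else if (length(cand) > 1L) labels[i] <- cand[which.min(avg[i, cand])]
    }
    # refinement can shrink a cluster below the size floor: dissolve it
    sizes <- tabulate(labels[labels > 0L], nbins = max(1L, max(labels)))
    small <- which(sizes > 0L & sizes < minClusterSize)
    labels[labels %in% small] <- 0L
  }

  labels <- .relabelBySize(labels)
  names(labels) <- labelsVec
  methods::new("SpliceModules", labels = labels, dendrogram = dendro,
               params = list(deepSplit = as.integer(deepSplit),
                             minClusterSize = as.integer(minClusterSize),
                             maxCoreScatter = maxCoreScatter,
                             minGap = minGap,
                             cutHeight = cutHeight))
}

.relabelBySize <- function(labels) {
  pos <- labels[labels > 0L]
  if (!length(pos)) return(as.integer(labels))
  sizes <- table(pos)
  # decreasing size; ties broken by old label for determinism
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- stats::setNames(seq_along(ord), names(sizes)[ord])
  out <- integer(length(labels))
  out[labels > 0L] <- remap[as.character(pos)]
  as.integer(out)
}

#' Drop the outlier cluster (label 0)
#'
#' The unassigned pool collects objects that fit no module; it is removed
#' before any downstream network stage.
#'
#' @param modules A [SpliceModules-class] object.
#' @return A [SpliceModules-class] containing only transcripts with a
#'   positive module label. Warns if nothing is retained.
#' @export
dropOutlierCluster <- function(modules) {
  lab <- moduleLabels(modules)
  keep <- lab > 0L
  if (!any(keep))
    warning("all transcripts are in the outlier cluster; nothing retained")
  methods::new("SpliceModules", labels = lab[keep],
               dendrogram = modules@dendrogram,
               params = c(modules@params,
                          list(outliersRemoved = sum(!keep))))
}
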