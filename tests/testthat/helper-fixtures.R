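# shared fixtures, built in code at test time

# block-structured dissimilarity: tight within-group, far between
blobDissimilarity <- function(sizes, within = 0.05, between = 0.9,
                              jitter = 0.01, seed = 42) {
  set.seed(seed)
  n <- sum(sizes)
  g <- rep(seq_along(sizes), sizes)
  d <- matrix(between, n, n)
  for (k in seq_along(sizes)) d[g == k, g == k] <- within
  d <- d + matrix(stats::runif(n * n, 0, jitter), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("o", seq_len(n)), paste0("o", seq_len(n)))
  attr(d, "groups") <- g
  d
}

writeQuantFile <- function(path, ids, tpm) {
  df <- data.frame(Name = ids, Length = 1000L, EffectiveLength = 800,
                   TPM = tpm, NumReads = round(tpm * 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# single transcript model with a prescribed distance between the last
# exon junction and the stop codon (negative: stop downstream of the
# junction); exon layout: nExons exons of 200 nt separated by 100-nt
# introns, total transcript length 200 * nExons
nmdToyModel <- function(distance, strandChar = "+", nExons = 2L,
                        tx = "tx1", cdsStartTx = 10L) {
  exonStarts <- (seq_len(nExons) - 1L) * 300L + 1L
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(exonStarts, width = 200L), strand = strandChar)
  lastJunction <- 200L * (nExons - 1L)
  stopTx <- lastJunction - distance
  stopifnot(stopTx > cdsStartTx)
  # map a transcript interval to genomic intervals given the exon chain
  ex53 <- if (strandChar == "-") rev(exons) else exons
  txToGenomic <- function(from, to) {
    offs <- c(0L, cumsum(GenomicRanges::width(ex53)))
    out <- NULL
    for (i in seq_along(ex53)) {
      lo <- max(from, offs[i] + 1L)
      hi <- min(to, offs[i + 1L])
      if (lo > hi) next
      if (strandChar == "-") {
        gHi <- GenomicRanges::end(ex53)[i] - (lo - offs[i] - 1L)
        gLo <- GenomicRanges::end(ex53)[i] - (hi - offs[i] - 1L)
      } else {
        gLo <- GenomicRanges::start(ex53)[i] + (lo - offs[i] - 1L)
        gHi <- GenomicRanges::start(ex53)[i] + (hi - offs[i] - 1L)
      }
      out <- rbind(out, c(gLo, gHi))
    }
    GenomicRanges::GRanges("chr1", IRanges::IRanges(out[, 1L], out[, 2L]),
                           strand = strandChar)
  }
  exl <- GenomicRanges::GRangesList(txToGenomic(1L, 200L * nExons))
  names(exl) <- tx
  cdl <- GenomicRanges::GRangesList(txToGenomic(cdsStartTx, stopTx))
  names(cdl) <- tx
  TranscriptModels(exl, cdl, stats::setNames("g1", tx))
}

# O(n^3) reference computation of the topological overlap matrix
bruteForceTom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

randomAdjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# full-sort reference for the nearest-rank top-percentile rule
bruteForceThreshold <- function(absR, topFraction) {
  m <- ceiling(topFraction * length(absR))
  tau <- sort(absR, decreasing = TRUE)[m]
  list(threshold = tau, retained = which(absR >= tau))
}

# map detected cluster ids to planted modules by majority vote
majorityMap <- function(labels, truth) {
  ks <- sort(unique(labels[labels > 0]))
  out <- vapply(ks, function(k) {
    tt <- truth[names(labels)[labels == k]]
    tt <- tt[tt > 0]
    if (!length(tt)) return(NA_integer_)
    as.integer(names(which.max(table(tt))))
  }, integer(1))
  stats::setNames(out, ks)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
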