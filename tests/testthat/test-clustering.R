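zFromRows <- function(mat) {
  rownames(mat) <- paste0("t", seq_len(nrow(mat)))
  colnames(mat) <- as.character(seq_len(ncol(mat)) - 1)
  zscoreProfiles(mat)
}

test_that("pairwise Pearson correlation matches the direct formula", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 3, 2, 4)
  r <- pairwiseCorrelation(rbind(a = x, b = y, c = -x))
  expect_equal(r["a", "a"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["a", "b"], 0.8)   # cov/sd product computed by hand
  expect_error(pairwiseCorrelation(rbind(a = x, b = rep(2, 4))), "degenerate")
})

test_that("soft-threshold adjacency is |r|^beta with zero diagonal", {
  r <- rbind(c(1, 0.9, 0), c(0.9, 1, -0.5), c(0, -0.5, 1))
  a <- adjacencyMatrix(r, 17)
  expect_equal(a[1, 2], 0.9^17, tolerance = 1e-12)
  expect_equal(a[1, 2], 0.16677, tolerance = 1e-4)
  expect_equal(a[1, 3], 0)
  expect_equal(diag(a), rep(0, 3))
  expect_error(adjacencyMatrix(r, 0.5), "power")

  # monotone in |r| for fixed beta
  rs <- seq(0, 1, by = 0.01)
  av <- rs^17
  expect_true(all(diff(av) >= 0))
  set.seed(3)
  r1 <- stats::runif(100); r2 <- stats::runif(100)
  expect_true(all((abs(r1) < abs(r2)) == (r1^6 < r2^6)))
})

test_that("connectivity equals brute-force row sums", {
  a1 <- matrix(1, 5, 5); diag(a1) <- 0
  expect_equal(unname(connectivity(a1)), rep(4, 5))
  expect_equal(unname(connectivity(matrix(0, 4, 4))), rep(0, 4))
  set.seed(4)
  a <- randomAdjacency(6)
  brute <- vapply(1:6, function(i) sum(a[i, -i]), numeric(1))
  expect_equal(unname(connectivity(a)), brute)
})

test_that("scale-free fit detects a constructed power law", {
  centers <- seq(5, 95, by = 10)
  counts <- round(1e5 / centers^2)
  k <- rep(centers, counts)
  fit <- scaleFreeFit(k, nBins = 10)
  expect_gte(fit$r_squared, 0.99)
  expect_lt(fit$slope, 0)

  expect_error(scaleFreeFit(rep(3, 50)), "non-empty bins")

  # uniform connectivity is a worse power-law fit than the construction
  set.seed(5)
  fitU <- scaleFreeFit(stats::runif(2000, 5, 95), nBins = 10)
  expect_lt(fitU$r_squared, fit$r_squared)
})

test_that("power selection honours target-first then elbow rules", {
  expect_equal(pickPowerFromFits(c(6, 12, 17), c(0.4, 0.69, 0.71), 0.7), 17)
  expect_equal(pickPowerFromFits(c(2, 4, 6), c(0.8, 0.9, 0.95), 0.7), 2)
  # gains (0.3, 0.25, 0.02, 0.01): elbow before the 0.02 gain
  r2 <- cumsum(c(0.3, 0.25, 0.02, 0.01))
  expect_equal(pickPowerFromFits(c(2, 4, 8, 12), r2, 0.99), 4)
  expect_error(pickPowerFromFits(numeric(0), numeric(0)), "non-empty")
})

test_that("selectPower reports a full fit table over the candidates", {
  sim <- simulateHeatStress(moduleSizes = c(25, 20), nBackground = 15,
                            regulatorLink = integer(0),
                            multiIsoformGenes = 0, seed = 6)
  z <- zscoreProfiles(averageReplicates(sim$se)[sim$dtuIds, ])
  sel <- selectPower(z, candidates = c(2, 6, 10, 17))
  expect_identical(sel$fit_table$power, c(2, 6, 10, 17))
  expect_true(sel$power %in% sel$fit_table$power)
  expect_true(all(sel$fit_table$r_squared >= 0 | is.na(sel$fit_table$r_squared)))
  expect_true(all(diff(sel$fit_table$mean_k) < 0))  # higher beta, sparser net
})

test_that("TOM matches its closed form and a brute-force oracle", {
  n <- 6
  a1 <- matrix(1, n, n); diag(a1) <- 0
  t1 <- tomSimilarity(a1)
  expect_equal(t1[1, 2], ((n - 2) + 1) / ((n - 1) + 1 - 1), tolerance = 1e-12)

  a0 <- matrix(0, 4, 4)
  t0 <- tomSimilarity(a0)
  expect_equal(t0[lower.tri(t0)], rep(0, 6))
  expect_equal(diag(t0), rep(1, 4))

  set.seed(7)
  for (i in 1:25) {
    a <- randomAdjacency(sample(5:8, 1))
    expect_equal(tomSimilarity(a), bruteForceTom(a), tolerance = 1e-12)
  }
})

test_that("average-linkage clustering behaves on small cases", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  hc <- hierarchicalCluster(d2)
  expect_equal(hc$height, 0.4)

  # two tight pairs merge internally before the pairs join
  d4 <- blobDissimilarity(c(2, 2), within = 0.1, between = 0.8, jitter = 0.01)
  hc4 <- hierarchicalCluster(d4)
  expect_true(all(hc4$merge[1, ] < 0) && all(hc4$merge[2, ] < 0))
  expect_equal(length(hc4$height), 3L)

  expect_error(hierarchicalCluster(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("dynamic tree cut recovers planted partitions", {
  d <- blobDissimilarity(c(15, 15), seed = 21)
  mod <- cutModules(hierarchicalCluster(d), d, deepSplit = 4,
                    minClusterSize = 5)
  lab <- moduleLabels(mod)
  expect_equal(sort(unique(lab)), 1:2)
  expect_equal(unname(moduleSizes(mod)), c(15L, 15L))
  expect_equal(adjustedRand(lab, attr(d, "groups")), 1)

  # below the size floor everything is an outlier
  dSmall <- blobDissimilarity(c(5, 5), seed = 22)
  modSmall <- cutModules(hierarchicalCluster(dSmall), dSmall,
                         minClusterSize = 20)
  expect_true(all(moduleLabels(modSmall) == 0L))

  # three blobs plus a genuine outlier object
  d3 <- blobDissimilarity(c(15, 12, 10), within = 0.05, between = 0.85,
                          seed = 23)
  n <- nrow(d3)
  d3 <- cbind(rbind(d3, 0.95), c(rep(0.95, n), 0))
  ids <- c(rownames(d3)[seq_len(n)], "outlier")
  dimnames(d3) <- list(ids, ids)
  mod3 <- cutModules(hierarchicalCluster(d3), d3, deepSplit = 4,
                     minClusterSize = 5)
  lab3 <- moduleLabels(mod3)
  expect_equal(max(lab3), 3L)
  expect_equal(unname(lab3["outlier"]), 0L)
  expect_equal(adjustedRand(lab3[ids != "outlier"],
                            attr(blobDissimilarity(c(15, 12, 10), seed = 23),
                                 "groups")), 1)

  expect_error(cutModules(hierarchicalCluster(d), d, minClusterSize = 0),
               "minClusterSize")
  expect_error(cutModules(hierarchicalCluster(d), d, deepSplit = 7),
               "deepSplit")
})

test_that("the detected partition is invariant to input row order", {
  sim <- simulateHeatStress(moduleSizes = c(20, 15), nBackground = 20,
                            regulatorLink = integer(0),
                            multiIsoformGenes = 0, seed = 9)
  z <- zscoreProfiles(averageReplicates(sim$se)[sim$dtuIds, ])
  runCut <- function(zm) {
    d <- moduleDissimilarity(zm, 17)
    moduleLabels(cutModules(hierarchicalCluster(d), d, 4, 10))
  }
  lab1 <- runCut(z)
  set.seed(1)
  perm <- sample(nrow(zscores(z)))
  zPerm <- methods::new("ZScoreMatrix",
                        values = zscores(z)[perm, ],
                        timepoints = profileTimepoints(z),
                        degenerateIds = character(0))
  lab2 <- runCut(zPerm)
  expect_equal(adjustedRand(lab1, lab2[names(lab1)]), 1)
})

test_that("dropping the outlier cluster removes label-0 transcripts", {
  labels <- stats::setNames(c(1L, 1L, 0L, 2L, 0L), paste0("t", 1:5))
  # sizes must be ordered: 1 has 2 members, 2 has 1
  mod <- methods::new("SpliceModules", labels = labels,
                      dendrogram = NULL, params = list())
  kept <- dropOutlierCluster(mod)
  expect_identical(names(moduleLabels(kept)), c("t1", "t2", "t4"))
  expect_identical(kept@params$outliersRemoved, 2L)
  expect_identical(moduleLabels(dropOutlierCluster(kept)),
                   moduleLabels(kept))
  allZero <- methods::new("SpliceModules",
                          labels = stats::setNames(c(0L, 0L), c("a", "b")),
                          dendrogram = NULL, params = list())
  expect_warning(dropOutlierCluster(allZero), "outlier")
})
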