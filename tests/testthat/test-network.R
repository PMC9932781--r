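test_that("regulator filter keeps heat-responsive coding NLS transcripts", {
  cat <- data.frame(
    transcript_id = c("r1", "r2", "r3", "r4"),
    is_DE = c(TRUE, TRUE, FALSE, FALSE),
    is_DAS = c(FALSE, FALSE, FALSE, TRUE),
    is_protein_coding = c(TRUE, TRUE, TRUE, TRUE),
    has_NLS = c(TRUE, FALSE, TRUE, TRUE))
  kept <- filterRegulators(cat)
  expect_identical(kept, c("r1", "r4"))  # r2 lacks NLS, r3 not responsive
  cat$has_NLS[1] <- NA
  expect_error(filterRegulators(cat), "defined")
  expect_error(filterRegulators(cat[, -2]), "columns")
})

test_that("centroids are per-timepoint means of member Z-scores", {
  z <- methods::new("ZScoreMatrix",
                    values = rbind(a = c(-1, 0, 1), b = c(1, 0, -1),
                                   c = c(-1, 0, 1)),
                    timepoints = c(0, 1, 3), degenerateIds = character(0))
  mod <- methods::new("SpliceModules",
                      labels = stats::setNames(c(1L, 1L, 2L), c("a", "b", "c")),
                      dendrogram = NULL, params = list())
  cent <- clusterCentroids(z, mod)
  expect_equal(unname(cent["1", ]), c(0, 0, 0))      # z and -z cancel
  expect_equal(unname(cent["2", ]), c(-1, 0, 1))     # singleton passthrough

  set.seed(12)
  vals <- matrix(stats::rnorm(40), nrow = 5,
                 dimnames = list(paste0("m", 1:5), NULL))
  vals <- t(apply(vals, 1, function(r) (r - mean(r)) / stats::sd(r)))
  z5 <- methods::new("ZScoreMatrix", values = vals,
                     timepoints = 1:8, degenerateIds = character(0))
  mod5 <- methods::new("SpliceModules",
                       labels = stats::setNames(rep(1L, 5), rownames(vals)),
                       dendrogram = NULL, params = list())
  expect_equal(unname(clusterCentroids(z5, mod5)["1", ]),
               unname(colMeans(vals)))
})

test_that("candidate pool is the cluster x regulator cross product", {
  cent <- matrix(stats::rnorm(19 * 8), nrow = 19,
                 dimnames = list(1:19, NULL))
  set.seed(13)
  regs <- matrix(stats::rnorm(186 * 8), nrow = 186,
                 dimnames = list(paste0("r", 1:186), NULL))
  cand <- correlateRegulators(cent, regs)
  expect_equal(nrow(cand), 3534)   # 19 clusters x 186 regulators
  expect_equal(anyDuplicated(cand[, c("cluster_id", "regulator_id")]), 0L)

  # exact tracking and mirroring
  cent1 <- matrix(c(0, -2, -1, 1), nrow = 1, dimnames = list("1", NULL))
  r2 <- rbind(same = cent1[1, ], anti = -cent1[1, ])
  cand2 <- correlateRegulators(cent1, r2)
  expect_equal(cand2$r[cand2$regulator_id == "same"], 1)
  expect_equal(cand2$r[cand2$regulator_id == "anti"], -1)

  # degenerate regulator profiles are excluded with a warning
  r3 <- rbind(ok = cent1[1, ], flat = rep(2, 4))
  expect_warning(c3 <- correlateRegulators(cent1, r3), "degenerate")
  expect_identical(c3$regulator_id, "ok")
})

test_that("percentile threshold follows the nearest-rank rule with ties", {
  set.seed(14)
  cand <- data.frame(cluster_id = 1L, regulator_id = paste0("r", 1:200),
                     r = stats::runif(200, -1, 1))
  thr <- percentileThreshold(cand, 0.01)
  expect_equal(thr$threshold, sort(abs(cand$r), decreasing = TRUE)[2])
  expect_equal(nrow(thr$edges), 2L)

  tied <- data.frame(cluster_id = 1L, regulator_id = paste0("r", 1:100),
                     r = rep(0.5, 100))
  thrT <- percentileThreshold(tied, 0.01)
  expect_equal(nrow(thrT$edges), 100L)   # all tied at tau stay

  expect_error(percentileThreshold(cand[0, ], 0.01), "empty")
  expect_error(percentileThreshold(cand, 0), "topFraction")
})

test_that("percentile threshold agrees with a full-sort oracle", {
  set.seed(15)
  for (n in c(10, 57, 1000, 10000)) {
    cand <- data.frame(cluster_id = 1L, regulator_id = paste0("r", seq_len(n)),
                       r = stats::runif(n, -1, 1))
    f <- stats::runif(1, 0.005, 0.2)
    thr <- percentileThreshold(cand, f)
    oracle <- bruteForceThreshold(abs(cand$r), f)
    expect_equal(thr$threshold, oracle$threshold)
    expect_identical(sort(thr$edges$regulator_id),
                     sort(cand$regulator_id[oracle$retained]))
  }
})

test_that("temporal classification separates early and late responses", {
  tps <- c(0, 1, 3, 6, 12, 24, 36, 48)
  downAt1 <- archetypeProfile("early_down", tps)
  expect_identical(classifyTemporal(downAt1, tps), "early")
  lateUp <- archetypeProfile("late_up", tps)
  expect_identical(classifyTemporal(lateUp, tps), "late")
  expect_identical(classifyTemporal(rep(0, 8), tps), "unclassified")
  # late-down is neither early nor a late up-regulation
  expect_identical(classifyTemporal(-lateUp, tps), "unclassified")
})

test_that("the assembled network respects its own invariants", {
  edges <- data.frame(cluster_id = c(2L, 2L, 5L),
                      regulator_id = c("a", "b", "a"),
                      r = c(0.99, 0.97, -0.98))
  tps <- c(0, 1, 3, 6, 12, 24, 36, 48)
  cent <- rbind(`2` = archetypeProfile("early_down", tps),
                `5` = archetypeProfile("late_up", tps))
  net <- buildNetwork(edges, 0.97, 0.01, centroids = cent, timepoints = tps)
  expect_true(all(abs(networkEdges(net)$r) >= networkThreshold(net)))
  expect_identical(unname(temporalClass(net)[c("2", "5")]),
                   c("early", "late"))
  expect_equal(length(unique(networkEdges(net)$cluster_id)), 2L)
  expect_error(buildNetwork(edges, 0.995, 0.01), "below the threshold")

  empty <- buildNetwork(edges[0, ], 0.9, 0.01)
  expect_equal(nrow(networkEdges(empty)), 0L)
})

test_that("planted regulator-module links are recovered as edges", {
  sim <- simulateHeatStress(seed = 1)
  tm <- averageReplicates(sim$se)
  z <- zscoreProfiles(tm[sim$dtuIds, ])
  d <- moduleDissimilarity(z, 17)
  mod <- dropOutlierCluster(cutModules(hierarchicalCluster(d), d, 4, 20))
  cent <- clusterCentroids(z, mod)
  regZ <- zscoreProfiles(tm[names(sim$truth$regulatorLink), , drop = FALSE])
  cand <- correlateRegulators(cent, regZ)
  link <- sim$truth$regulatorLink
  nPlanted <- sum(!is.na(link))
  thr <- percentileThreshold(cand, topFraction = nPlanted / nrow(cand))
  mapping <- majorityMap(moduleLabels(mod), sim$truth$moduleLabels)
  got <- paste(mapping[as.character(thr$edges$cluster_id)],
               thr$edges$regulator_id)
  planted <- paste(link[!is.na(link)], names(link)[!is.na(link)])
  precision <- mean(got %in% planted)
  recall <- mean(planted %in% got)
  expect_gte(precision, 0.8)
  expect_gte(recall, 0.8)
})
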