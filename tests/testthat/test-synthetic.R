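tps <- c(0, 1, 3, 6, 12, 24, 36, 48)

test_that("archetype profiles have the expected temporal shape", {
  ed <- archetypeProfile("early_down", tps)
  expect_equal(mean(ed), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ed), 1, tolerance = 1e-12)
  expect_equal(tps[which.min(ed)], 1)           # sharp drop right after onset
  expect_equal(tps[which.max(ed)], 0)

  tu <- archetypeProfile("early_transient_up", tps)
  expect_true(tps[which.max(tu)] %in% c(3, 6))
  # back near baseline by 24 h: departure is a small fraction of the peak
  expect_lt(abs(tu[tps == 24] - tu[tps == 48]), 0.15 * diff(range(tu)))

  lu <- archetypeProfile("late_up", tps)
  expect_true(all(diff(lu) >= 0))
  expect_equal(tps[which.max(lu)], 48)

  fl <- archetypeProfile("flat", tps)
  expect_true(all(fl == 0))
  expect_true(attr(fl, "degenerate"))
  expect_error(archetypeProfile("bogus", tps))
})

test_that("the generator is deterministic and honours its structure", {
  a <- simulateHeatStress(seed = 7)
  b <- simulateHeatStress(seed = 7)
  expect_identical(SummarizedExperiment::assay(a$se, "TPM"),
                   SummarizedExperiment::assay(b$se, "TPM"))
  expect_identical(a$truth, b$truth)
  c2 <- simulateHeatStress(seed = 8)
  expect_false(identical(SummarizedExperiment::assay(a$se, "TPM"),
                         SummarizedExperiment::assay(c2$se, "TPM")))

  # planted label counts match the configured sizes
  expect_length(a$dtuIds, 200L)
  expect_identical(unname(table(a$truth$moduleLabels)),
                   table(c(rep(0, 80), rep(1, 50), rep(2, 40), rep(3, 30))) |>
                     unname())

  mat <- SummarizedExperiment::assay(a$se, "TPM")
  expect_true(all(mat >= 0 & is.finite(mat)))
  expect_identical(dim(mat), c(218L, 24L))
})

test_that("zero-noise latent profiles equal the archetypes exactly", {
  sim <- simulateHeatStress(noiseSd = 0, replicateCv = 0, seed = 2)
  arch <- vapply(c("early_down", "early_transient_up", "late_up"),
                 archetypeProfile, numeric(8), timepoints = tps)
  lab <- sim$truth$moduleLabels
  lat <- sim$truth$latentZ
  for (m in 1:3) {
    members <- names(lab)[lab == m]
    expect_true(all(apply(lat[members, , drop = FALSE], 1,
                          function(p) isTRUE(all.equal(unname(p),
                                                       unname(arch[, m]))))))
  }
  # observed TPM Z-profiles track the archetype: the TPM mapping is
  # strictly monotone in the latent profile, so ranks are preserved
  tm <- averageReplicates(sim$se)
  z <- zscores(zscoreProfiles(tm[names(lab)[lab == 3], , drop = FALSE]))
  cors <- apply(z, 1, stats::cor, y = arch[, 3], method = "spearman")
  expect_true(all(cors == 1))
})

test_that("planted isoform proportions are coherent", {
  sim <- simulateHeatStress(seed = 5)
  sw <- sim$truth$switchIntervals
  expect_equal(nrow(sw), 4L)
  # switch interval endpoints are adjacent sampled timepoints
  expect_true(all(match(sw$t_b, tps) - match(sw$t_a, tps) == 1L))
  # latent proportions per gene sum to 1: gene TPM at a timepoint equals
  # the sum of its isoform latent TPMs, so proportions reconstruct
  tm <- averageReplicates(sim$se)
  iso <- rownames(tm)[startsWith(rownames(tm), "ISOG")]
  tracks <- isoformProportions(tm[iso, ], sim$txGene)
  for (tr in tracks) {
    sums <- colSums(tr$proportions)
    expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  }
})
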