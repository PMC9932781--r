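test_that("junction positions walk the transcript 5' to 3'", {
  one <- TranscriptModels(GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500), strand = "+")))
  expect_identical(transcriptJunctions(one)$t1, integer(0))

  two <- TranscriptModels(GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1, 201), c(100, 400)), strand = "+")))
  expect_identical(transcriptJunctions(two)$t1, 100L)  # 100 then 200 nt

  # minus strand: junctions from cumulative exon lengths walked 5'->3'
  widths <- c(70L, 120L, 50L)
  starts <- c(1L, 201L, 501L)
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, width = widths), strand = "-")
  m <- TranscriptModels(GenomicRanges::GRangesList(t1 = ex))
  w53 <- rev(widths)   # 5'->3' on minus strand is descending start
  expect_identical(transcriptJunctions(m)$t1,
                   as.integer(cumsum(w53)[-3]))
})

test_that("the 50-nt NMD rule is strict on both strands and exon counts", {
  for (strandChar in c("+", "-")) {
    for (nEx in c(2L, 3L)) {
      for (dist in c(0L, 49L, 50L, 51L, 200L)) {
        if (dist == 200L && nEx == 2L) next  # stop would leave the CDS start
        m <- nmdToyModel(dist, strandChar, nEx)
        f <- nmdFlags(m)
        expect_identical(f$distance, dist,
                         info = sprintf("%s strand, %d exons, d=%d",
                                        strandChar, nEx, dist))
        expect_identical(f$flagged, dist > 50L,
                         info = sprintf("%s strand, %d exons, d=%d",
                                        strandChar, nEx, dist))
      }
    }
  }
  # non-coding transcript: never flagged
  nc <- TranscriptModels(GenomicRanges::GRangesList(
    t1 = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(1, 301), c(200, 500)), strand = "+")))
  f <- nmdFlags(nc)
  expect_false(f$flagged)
  expect_true(is.na(f$stop_codon_pos))
})

test_that("isoform proportions divide gene TPM per timepoint", {
  tm <- rbind(gA.1 = c(41, 70, 0), gA.2 = c(59, 30, 0), gB.1 = c(5, 10, 2))
  colnames(tm) <- c("0", "1", "3")
  txg <- stats::setNames(c("gA", "gA", "gB"), rownames(tm))
  tracks <- isoformProportions(tm, txg)
  # the two-isoform split observed pre-stress
  expect_equal(unname(tracks$gA$proportions["gA.1", "0"]), 0.41)
  expect_equal(unname(tracks$gA$proportions["gA.2", "0"]), 0.59)
  # unexpressed timepoint: proportions undefined
  expect_true(all(is.na(tracks$gA$proportions[, "3"])))
  # single-isoform gene: proportion 1 wherever expressed
  expect_equal(unname(tracks$gB$proportions["gB.1", ]), c(1, 1, 1))
  expect_error(isoformProportions(tm, txg[-1]), "without gene mapping")
})

test_that("switch detection finds dominance changes between adjacent timepoints", {
  tm <- rbind(g.1 = c(41, 70, 80), g.2 = c(59, 30, 20))
  colnames(tm) <- c("0", "1", "3")
  tr <- isoformProportions(tm, stats::setNames(c("g", "g"), rownames(tm)))
  sw <- detectSwitches(tr, minGeneTpm = 0)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$t_a, 0)
  expect_equal(sw$t_b, 1)
  expect_identical(sw$isoform_from, "g.2")
  expect_identical(sw$isoform_to, "g.1")
  expect_equal(sw$prop_to_before, 0.41)
  expect_equal(sw$prop_to_after, 0.7)

  # monotone dominance: no events
  tm2 <- rbind(g.1 = c(70, 80, 90), g.2 = c(30, 20, 10))
  colnames(tm2) <- colnames(tm)
  tr2 <- isoformProportions(tm2, stats::setNames(c("g", "g"), rownames(tm2)))
  expect_equal(nrow(detectSwitches(tr2, minGeneTpm = 0)), 0L)

  # exact tie: dominance goes to the lexicographically first isoform
  tm3 <- rbind(g.1 = c(50, 20), g.2 = c(50, 80))
  colnames(tm3) <- c("0", "1")
  tr3 <- isoformProportions(tm3, stats::setNames(c("g", "g"), rownames(tm3)))
  sw3 <- detectSwitches(tr3, minGeneTpm = 0)
  expect_identical(sw3$isoform_from, "g.1")

  # low-expression intervals are skipped by the TPM floor
  tm4 <- rbind(g.1 = c(0.4, 0.1), g.2 = c(0.2, 0.5))
  colnames(tm4) <- c("0", "1")
  tr4 <- isoformProportions(tm4, stats::setNames(c("g", "g"), rownames(tm4)))
  expect_equal(nrow(detectSwitches(tr4, minGeneTpm = 1)), 0L)
})

test_that("planted switch intervals are recovered exactly at zero noise", {
  sim <- simulateHeatStress(noiseSd = 0, replicateCv = 0, seed = 5)
  tm <- averageReplicates(sim$se)
  iso <- rownames(tm)[startsWith(rownames(tm), "ISOG")]
  tracks <- isoformProportions(tm[iso, ], sim$txGene)
  sw <- detectSwitches(tracks, minGeneTpm = 0)
  truth <- sim$truth$switchIntervals
  sw <- sw[order(sw$gene_id), ]
  truth <- truth[order(truth$gene_id), ]
  expect_identical(sw$gene_id, truth$gene_id)
  expect_equal(sw$t_a, truth$t_a)
  expect_equal(sw$t_b, truth$t_b)
})

test_that("CDS coverage of a domain region is classified per isoform", {
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), strand = "+")
  mk <- function(cdsRanges) GenomicRanges::GRanges("chr1", cdsRanges, strand = "+")
  models <- TranscriptModels(
    GenomicRanges::GRangesList(full = ex, same = ex, half = ex,
                               none = ex, comp = ex),
    GenomicRanges::GRangesList(
      full = mk(IRanges::IRanges(100, 500)),
      same = mk(IRanges::IRanges(100, 500)),
      half = mk(IRanges::IRanges(100, 300)),
      none = mk(IRanges::IRanges(600, 700)),
      comp = mk(IRanges::IRanges(301, 500))),
    stats::setNames(rep("g", 5), c("full", "same", "half", "none", "comp")))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 500))
  expect_identical(compareCdsRegion(models, "full", "same", region), "identical")
  expect_identical(compareCdsRegion(models, "full", "half", region), "truncated_in_b")
  expect_identical(compareCdsRegion(models, "full", "none", region), "absent_in_b")
  expect_identical(compareCdsRegion(models, "half", "comp", region),
                   "identical_complement")
  modelsX <- TranscriptModels(
    GenomicRanges::GRangesList(a = ex, b = ex),
    txGene = stats::setNames(c("g1", "g2"), c("a", "b")))
  expect_error(compareCdsRegion(modelsX, "a", "b", region), "same gene")
})
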