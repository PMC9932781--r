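#' Archetype time profiles of the heat-stress response
#'
#' Standardized (mean 0, sample sd 1) template profiles over a set of
#' timepoints, emulating the temporal patterns of heat-responsive
#' transcript modules:
#'
#' * `early_down`: sharp down-regulation right after stress onset,
#'   minimum at the first stressed timepoint, then stably low with a
#'   slight drift.
#' * `early_transient_up`: transient up-regulation peaking at 3-6 h,
#'   back near baseline by 24 h.
#' * `late_up`: non-decreasing rise, maximal at the last timepoint
#'   (up-regulation only from about 24 h).
#' * `flat`: no response. Returned as all zeros with attribute
#'   `degenerate = TRUE` (a constant profile cannot be standardized).
#'
#' @param name Archetype name.
#' @param timepoints Numeric timepoints in hours, ascending
#'   (default `c(0, 1, 3, 6, 12, 24, 36, 48)`).
#' @return Numeric profile over `timepoints`; zero-mean and unit
#'   (sample) sd unless degenerate.
#' @export
archetypeProfile <- function(name = c("early_down", "early_transient_up",
                                      "late_up", "flat"),
                             timepoints = c(0, 1, 3, 6, 12, 24, 36, 48)) {
  name <- match.arg(name)
  t <- as.numeric(timepoints)
  stopifnot(!is.unsorted(t, strictly = TRUE))
  raw <- switch(name,
    early_down = ifelse(t == 0, 1, -1 + 0.01 * (t - 1)),
    early_transient_up = (t / 4) * exp(1 - t / 4),
    late_up = 1 / (1 + exp(-(t - 30) / 6)),
    flat = rep(0, length(t)))
  if (name == "flat") {
    attr(raw, "degenerate") <- TRUE
    return(raw)
  }
  z <- (raw - mean(raw)) / stats::sd(raw)
  attr(z, "degenerate") <- FALSE
  z
}

# independent profile kept only if not spuriously collinear with any
# planted archetype: with few timepoints a random profile can mimic an
# archetype by chance, which would make the planted labels
# unidentifiable. Collinearity is checked on the expression scale the
# pipeline sees (after the exponential TPM mapping), because that
# mapping concentrates a profile's weight on its maxima and can turn a
# moderate latent correlation into a near-perfect observed one.
.backgroundProfile <- function(archMat, amplitude, maxAbsCor = 0.8) {
  archTpm <- 2^(amplitude * archMat)
  repeat {
    p <- stats::rnorm(nrow(archMat), 0, 1)
    if (all(abs(stats::cor(2^(amplitude * p), archTpm)) < maxAbsCor))
      return(p)
  }
}

.lognormalNoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.toyGeneModel <- function(gene, isoforms, offset, strandChar) {
  # two exons of 300 nt separated by a 100-nt intron; CDS variants place
  # the last junction 0, >50 or just-over-50 nt downstream of the stop
  ex <- GenomicRanges::GRanges("chrS",
    IRanges::IRanges(c(offset + 1L, offset + 401L),
                     c(offset + 300L, offset + 700L)),
    strand = strandChar)
  minus <- identical(strandChar, "-")
  cdsPlus <- list(  # in transcript terms: stop at 450 / 240 / 249
    IRanges::IRanges(c(offset + 51L, offset + 401L),
                     c(offset + 300L, offset + 550L)),
    IRanges::IRanges(offset + 51L, offset + 240L),
    IRanges::IRanges(offset + 51L, offset + 249L))
  cdsMinus <- list(
    IRanges::IRanges(c(offset + 151L, offset + 401L),
                     c(offset + 300L, offset + 650L)),
    IRanges::IRanges(offset + 461L, offset + 650L),
    IRanges::IRanges(offset + 452L, offset + 650L))
  cdsSets <- if (minus) cdsMinus else cdsPlus
  exons <- list(); cds <- list()
  for (i in seq_along(isoforms)) {
    exons[[isoforms[i]]] <- ex
    cds[[isoforms[i]]] <- GenomicRanges::GRanges("chrS", cdsSets[[i]],
                                                 strand = strandChar)
  }
  list(exons = exons, cds = cds)
}

#' Simulate a heat-stress time-course with planted structure
#'
#' Generates a fully self-contained synthetic dataset with the
#' statistical structure the network analysis assumes: co-expressed
#' transcript modules following archetype time profiles, background
#' transcripts with independent noise profiles, regulator transcripts
#' tracking a linked module's archetype (or nothing, for decoys),
#' multi-isoform genes with a planted isoform switch, and toy transcript
#' models exercising the 50-nt NMD junction rule on both strands.
#'
#' Each module member's latent profile is its archetype plus Gaussian
#' noise (`noiseSd`, Z units), mapped to TPM as
#' `baseline * 2^(amplitude * profile)` with a log-uniform baseline in
#' `[1, 100]`; replicate observations multiply the latent TPM by
#' lognormal noise with coefficient of variation `replicateCv` (unit
#' mean). In the noise-free limit the latent profiles equal the
#' archetypes exactly and module recovery is exact.
#'
#' @param moduleSizes Integer sizes of the planted modules
#'   (default `c(50, 40, 30)`).
#' @param archetypes Archetype per module, recycled over
#'   `c("early_down", "early_transient_up", "late_up")`.
#' @param nBackground Background transcripts with independent profiles
#'   (default 80).
#' @param regulatorLink Integer vector, one entry per regulator: the
#'   planted module it tracks, or `NA` for a decoy (default: one
#'   regulator per module plus 5 decoys).
#' @param noiseSd Gaussian sd added to latent Z profiles (default 0.2).
#' @param replicateCv Replicate-level lognormal coefficient of
#'   variation (default 0.1).
#' @param nReplicates Replicates per timepoint (default 3).
#' @param timepoints Time axis in hours
#'   (default `c(0, 1, 3, 6, 12, 24, 36, 48)`).
#' @param multiIsoformGenes Number of multi-isoform genes with a planted
#'   switch (default 4).
#' @param amplitude log2 fold-change amplitude of the TPM mapping
#'   (default 2).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `se` (TPM `SummarizedExperiment` over all
#'   transcripts), `design`, `dtuIds` (module + background transcripts,
#'   the clustering universe), `truth` (planted `moduleLabels`,
#'   `regulatorLink`, `switchIntervals`, `latentZ`), `catalog` (the
#'   regulator flag table), `txGene`, and `models`
#'   ([TranscriptModels-class] toy gene structures).
#' @export
simulateHeatStress <- function(moduleSizes = c(50, 40, 30),
                               archetypes = c("early_down",
                                              "early_transient_up",
                                              "late_up"),
                               nBackground = 80,
                               regulatorLink = c(seq_along(moduleSizes),
                                                 rep(NA, 5)),
                               noiseSd = 0.2,
                               replicateCv = 0.1,
                               nReplicates = 3,
                               timepoints = c(0, 1, 3, 6, 12, 24, 36, 48),
                               multiIsoformGenes = 4,
                               amplitude = 2,
                               seed = 1) {
  stopifnot(all(moduleSizes > 0), noiseSd >= 0, replicateCv >= 0,
            nReplicates >= 1, length(timepoints) >= 2)
  nm <- length(moduleSizes)
  archetypes <- rep_len(archetypes, nm)
  tps <- as.numeric(timepoints)
  nt <- length(tps)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  archMat <- vapply(archetypes, archetypeProfile, numeric(nt),
                    timepoints = tps)

  ids <- character(0); genes <- character(0)
  latent <- NULL; labels <- integer(0)
  for (m in seq_len(nm)) {
    for (i in seq_len(moduleSizes[m])) {
      ids <- c(ids, sprintf("MOD%d_G%03d.1", m, i))
      genes <- c(genes, sprintf("MOD%d_G%03d", m, i))
      latent <- rbind(latent, archMat[, m] + stats::rnorm(nt, 0, noiseSd))
      labels <- c(labels, m)
    }
  }
  for (i in seq_len(nBackground)) {
    ids <- c(ids, sprintf("BG_G%03d.1", i))
    genes <- c(genes, sprintf("BG_G%03d", i))
    latent <- rbind(latent, .backgroundProfile(archMat, amplitude))
    labels <- c(labels, 0L)
  }

  regIds <- sprintf("REG%02d.1", seq_along(regulatorLink))
  regGenes <- sprintf("REG%02d", seq_along(regulatorLink))
  for (j in seq_along(regulatorLink)) {
    prof <- if (is.na(regulatorLink[j])) .backgroundProfile(archMat, amplitude)
            else archMat[, regulatorLink[j]] + stats::rnorm(nt, 0, noiseSd)
    latent <- rbind(latent, prof)
  }
  ids <- c(ids, regIds)
  genes <- c(genes, regGenes)

  rownames(latent) <- ids
  baseline <- 10^stats::runif(length(ids), 0, 2)
  tpmLatent <- baseline * 2^(amplitude * latent)

  # multi-isoform genes: fixed latent proportions flipping once at a
  # planted inter-timepoint interval; gene-level TPM is flat
  isoRows <- NULL; isoIds <- character(0); isoGenes <- character(0)
  switchIntervals <- NULL
  isoModels <- list(exons = list(), cds = list())
  if (multiIsoformGenes > 0) {
    for (gidx in seq_len(multiIsoformGenes)) {
      g <- sprintf("ISOG%02d", gidx)
      nIso <- 2L + gidx %% 2L
      isos <- sprintf("%s.%d", g, seq_len(nIso))
      s <- 1L + (gidx - 1L) %% (nt - 1L)
      before <- if (nIso == 2L) c(0.7, 0.3) else c(0.55, 0.25, 0.2)
      after <- if (nIso == 2L) c(0.3, 0.7) else c(0.2, 0.6, 0.2)
      props <- vapply(seq_len(nt), function(i) if (i <= s) before else after,
                      numeric(nIso))
      gTpm <- 10^stats::runif(1, 1, 2)
      isoRows <- rbind(isoRows, gTpm * props)
      isoIds <- c(isoIds, isos)
      isoGenes <- c(isoGenes, rep(g, nIso))
      switchIntervals <- rbind(switchIntervals, data.frame(
        gene_id = g, isoform_from = isos[1L], isoform_to = isos[2L],
        t_a = tps[s], t_b = tps[s + 1L], stringsAsFactors = FALSE))
      mdl <- .toyGeneModel(g, isos, offset = 1000L * gidx,
                           strandChar = if (gidx %% 2L) "+" else "-")
      isoModels$exons <- c(isoModels$exons, mdl$exons)
      isoModels$cds <- c(isoModels$cds, mdl$cds)
    }
    rownames(isoRows) <- isoIds
  }

  tpmAll <- rbind(tpmLatent, isoRows)
  allIds <- c(ids, isoIds)
  allGenes <- c(genes, isoGenes)

  design <- sampleDesign(
    sample_id = sprintf("T%g_R%d", rep(tps, each = nReplicates),
                        rep(seq_len(nReplicates), nt)),
    timepoint_h = rep(tps, each = nReplicates),
    replicate = rep(seq_len(nReplicates), nt))
  mat <- matrix(0, nrow = nrow(tpmAll), ncol = nrow(design),
                dimnames = list(allIds, design$sample_id))
  for (ci in seq_len(nrow(design))) {
    tpIdx <- match(design$timepoint_h[ci], tps)
    mat[, ci] <- tpmAll[, tpIdx] * .lognormalNoise(nrow(tpmAll), replicateCv)
  }
  se <- .tpm_se(mat, design)

  nReg <- length(regIds)
  catalog <- data.frame(
    transcript_id = regIds,
    is_DE = rep(TRUE, nReg),
    is_DAS = rep(FALSE, nReg),
    is_protein_coding = rep(TRUE, nReg),
    has_NLS = !is.na(regulatorLink),
    stringsAsFactors = FALSE)

  txGene <- stats::setNames(allGenes, allIds)

  # toy models: realistic two-exon structures for the isoform genes,
  # single-exon models for the rest (built in bulk: element-wise GRanges
  # construction is costly)
  single <- GenomicRanges::GRanges("chrB",
    IRanges::IRanges(10000L + 2000L * seq_along(ids), width = 1000L),
    strand = "+")
  names(single) <- ids
  exonsSingle <- methods::as(single, "GRangesList")
  emptyCds <- GenomicRanges::GRangesList(rep(list(GenomicRanges::GRanges()),
                                             length(ids)))
  names(emptyCds) <- ids
  exons <- suppressWarnings(
    c(GenomicRanges::GRangesList(isoModels$exons), exonsSingle))
  cds <- suppressWarnings(
    c(GenomicRanges::GRangesList(isoModels$cds), emptyCds))
  ord <- c(isoIds, ids)
  models <- TranscriptModels(exons[ord], cds[ord], txGene[ord])

  list(se = se,
       design = design,
       dtuIds = ids[seq_along(labels)],
       truth = list(
         moduleLabels = stats::setNames(labels, ids[seq_along(labels)]),
         regulatorLink = stats::setNames(regulatorLink, regIds),
         switchIntervals = switchIntervals,
         latentZ = latent),
       catalog = catalog,
       txGene = txGene,
       models = models)
}
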