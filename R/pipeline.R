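.defaultConfig <- function() {
  list(
    simulate = NULL,          # list of simulateHeatStress() args, or NULL
    inputs = NULL,            # list(expression, design, dtu_list, tx2gene,
                              #      catalog, gtf) of file paths
    power = 17,               # soft threshold; "auto" for elbow selection
    power_candidates = c(1:10, 12, 14, 16, 17, 18, 20),
    scale_free_target = 0.7,
    n_bins = 10,
    dissimilarity = "adj",    # or "tom" / "corr"
    signed = FALSE,
    deep_split = 4,
    min_cluster_size = 20,
    cut_height_fraction = 0.99,
    top_fraction = 0.01,
    min_gene_tpm = 1,
    per_sample_z = FALSE,
    sd_type = "sample",
    log2_offset = NULL,
    seed = 1)
}

.mergeConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .defaultConfig()
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  cfg
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.matrixDf <- function(mat, idCol = "transcript_id") {
  out <- data.frame(rownames(mat), as.data.frame(mat, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1L] <- idCol
  out
}

.readMatrixTsv <- function(path, idCol = "transcript_id") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- as.character(tab[[1L]])
  mat
}

.need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("%s not found: %s", what,
                 if (is.null(path)) "(not configured)" else path),
         call. = FALSE)
  path
}

.stage_inputs <- function(cfg, dir) {
  inp <- file.path(dir, "inputs")
  dir.create(inp, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    if (isTRUE(args)) args <- list()
    if (is.null(args$seed)) args$seed <- cfg$seed
    sim <- do.call(simulateHeatStress, args)
    writeExpressionMatrix(sim$se, file.path(inp, "expression.tsv"))
    .writeTsv(sim$design, file.path(inp, "design.tsv"))
    writeLines(sim$dtuIds, file.path(inp, "dtu_transcripts.txt"))
    .writeTsv(data.frame(transcript_id = names(sim$txGene),
                         gene_id = unname(sim$txGene),
                         stringsAsFactors = FALSE),
              file.path(inp, "tx2gene.tsv"))
    .writeTsv(sim$catalog, file.path(inp, "regulator_catalog.tsv"))
    writeGtf(sim$models, file.path(inp, "models.gtf"))
  } else {
    src <- cfg$inputs
    file.copy(.need_file(src$expression, "expression matrix"),
              file.path(inp, "expression.tsv"), overwrite = TRUE)
    file.copy(.need_file(src$design, "sample design table"),
              file.path(inp, "design.tsv"), overwrite = TRUE)
    file.copy(.need_file(src$dtu_list, "DTU transcript list"),
              file.path(inp, "dtu_transcripts.txt"), overwrite = TRUE)
    file.copy(.need_file(src$tx2gene, "transcript-to-gene map"),
              file.path(inp, "tx2gene.tsv"), overwrite = TRUE)
    file.copy(.need_file(src$catalog, "regulator catalog"),
              file.path(inp, "regulator_catalog.tsv"), overwrite = TRUE)
    if (!is.null(src$gtf))
      file.copy(.need_file(src$gtf, "transcript annotation"),
                file.path(inp, "models.gtf"), overwrite = TRUE)
  }
  invisible(inp)
}

.readRunInputs <- function(dir) {
  inp <- file.path(dir, "inputs")
  destab <- utils::read.delim(file.path(inp, "design.tsv"),
                              stringsAsFactors = FALSE)
  design <- sampleDesign(destab$sample_id, destab$timepoint_h,
                         destab$replicate)
  se <- readQuantTables(file.path(inp, "expression.tsv"), design)
  t2g <- utils::read.delim(file.path(inp, "tx2gene.tsv"),
                           stringsAsFactors = FALSE)
  list(se = se, design = design,
       dtu = readLines(file.path(inp, "dtu_transcripts.txt")),
       txGene = stats::setNames(t2g$gene_id, t2g$transcript_id),
       catalog = utils::read.delim(file.path(inp, "regulator_catalog.tsv"),
                                   stringsAsFactors = FALSE),
       gtf = file.path(inp, "models.gtf"))
}

.stage_normalize <- function(cfg, dir) {
  run <- .readRunInputs(dir)
  tm <- averageReplicates(run$se)
  .writeTsv(.matrixDf(tm), file.path(dir, "timepoint_tpm.tsv"))
  dtu <- intersect(run$dtu, rownames(tm))
  if (!length(dtu)) stop("no DTU transcripts present in the expression matrix")
  if (isTRUE(cfg$per_sample_z)) {
    # standardize over all samples first, then average replicates and
    # re-standardize (Pearson correlation downstream is unaffected by
    # the final affine step; it only restores the unit-variance
    # invariant of the container)
    mat <- SummarizedExperiment::assay(run$se, "TPM")[dtu, , drop = FALSE]
    zs <- zscoreProfiles(mat, timepoints = seq_len(ncol(mat)),
                         sdType = cfg$sd_type, log2Offset = cfg$log2_offset)
    zmat <- zscores(zs) - min(zscores(zs))
    colnames(zmat) <- colnames(mat)
    seZ <- SummarizedExperiment::SummarizedExperiment(
      assays = list(TPM = zmat),
      colData = SummarizedExperiment::colData(run$se))
    tmz <- averageReplicates(seZ)
    z <- zscoreProfiles(tmz, timepoints = attr(tmz, "timepoints_h"),
                        sdType = cfg$sd_type)
  } else {
    z <- zscoreProfiles(tm[dtu, , drop = FALSE],
                        timepoints = attr(tm, "timepoints_h"),
                        sdType = cfg$sd_type, log2Offset = cfg$log2_offset)
  }
  .writeTsv(.matrixDf(zscores(z)), file.path(dir, "zscores.tsv"))
  writeLines(degenerateIds(z), file.path(dir, "zscore_degenerate.txt"))
  invisible(z)
}

.readZ <- function(dir) {
  zm <- .readMatrixTsv(file.path(dir, "zscores.tsv"))
  methods::new("ZScoreMatrix", values = zm,
               timepoints = as.numeric(colnames(zm)),
               degenerateIds = readLines(file.path(dir,
                                                   "zscore_degenerate.txt")))
}

.stage_cluster <- function(cfg, dir) {
  z <- .readZ(dir)
  sel <- selectPower(z, candidates = cfg$power_candidates,
                     target = cfg$scale_free_target, nBins = cfg$n_bins,
                     signed = cfg$signed)
  .writeTsv(sel$fit_table, file.path(dir, "fit_table.tsv"))
  power <- if (identical(cfg$power, "auto")) sel$power else cfg$power
  d <- moduleDissimilarity(z, power, dissimilarity = cfg$dissimilarity,
                           signed = cfg$signed)
  dendro <- hierarchicalCluster(d)
  modules <- cutModules(dendro, d, deepSplit = cfg$deep_split,
                        minClusterSize = cfg$min_cluster_size,
                        cutHeightFraction = cfg$cut_height_fraction)
  ape::write.tree(ape::as.phylo(dendro), file.path(dir, "dendrogram.nwk"))
  .writeTsv(data.frame(transcript_id = names(moduleLabels(modules)),
                       cluster = unname(moduleLabels(modules)),
                       stringsAsFactors = FALSE),
            file.path(dir, "clusters.tsv"))
  writeLines(sprintf("%.15g", power), file.path(dir, "power_used.txt"))
  invisible(modules)
}

.readClusters <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "clusters.tsv"),
                           stringsAsFactors = FALSE)
  stats::setNames(as.integer(tab$cluster), tab$transcript_id)
}

.stage_network <- function(cfg, dir) {
  run <- .readRunInputs(dir)
  z <- .readZ(dir)
  labels <- .readClusters(dir)
  labels <- labels[labels > 0L]
  if (!length(labels)) stop("no non-outlier clusters; network stage aborted")
  modules <- methods::new("SpliceModules", labels = labels,
                          dendrogram = NULL, params = list())
  cent <- clusterCentroids(z, modules)
  .writeTsv(.matrixDf(cent, idCol = "cluster_id"),
            file.path(dir, "centroids.tsv"))
  kept <- filterRegulators(run$catalog)
  tm <- .readMatrixTsv(file.path(dir, "timepoint_tpm.tsv"))
  kept <- intersect(kept, rownames(tm))
  if (!length(kept)) stop("no regulator transcripts pass the catalog filter")
  regZ <- zscoreProfiles(tm[kept, , drop = FALSE],
                         timepoints = as.numeric(colnames(tm)),
                         sdType = cfg$sd_type, log2Offset = cfg$log2_offset)
  cand <- correlateRegulators(cent, regZ)
  .writeTsv(cand, file.path(dir, "candidate_edges.tsv"))
  thr <- percentileThreshold(cand, topFraction = cfg$top_fraction)
  net <- buildNetwork(thr$edges, thr$threshold, cfg$top_fraction,
                      centroids = cent,
                      timepoints = profileTimepoints(z))
  writeNetwork(net, file.path(dir, "network.tsv"), format = "tsv")
  writeNetwork(net, file.path(dir, "network.sif"), format = "sif")
  writeNetwork(net, file.path(dir, "network.graphml"), format = "graphml")
  invisible(net)
}

.stage_isoforms <- function(cfg, dir) {
  run <- .readRunInputs(dir)
  tm <- .readMatrixTsv(file.path(dir, "timepoint_tpm.tsv"))
  nIso <- table(run$txGene[rownames(tm)])
  multi <- names(nIso)[nIso >= 2L]
  keep <- rownames(tm)[run$txGene[rownames(tm)] %in% multi]
  sw <- if (length(keep)) {
    tracks <- isoformProportions(tm[keep, , drop = FALSE], run$txGene)
    detectSwitches(tracks, minGeneTpm = cfg$min_gene_tpm)
  } else detectSwitches(list(), minGeneTpm = cfg$min_gene_tpm)
  .writeTsv(sw, file.path(dir, "switches.tsv"))
  if (file.exists(run$gtf)) {
    flags <- nmdFlags(readGtf(run$gtf))
    .writeTsv(flags, file.path(dir, "nmd_flags.tsv"))
  }
  invisible(sw)
}

#' Run the full splicing-network analysis
#'
#' Orchestrates the pipeline end to end: input assembly (from files, or
#' from the synthetic generator), replicate averaging and Z-scoring of
#' the DTU transcripts, soft-threshold selection and module detection,
#' the bipartite cluster-regulator network, and the isoform-level
#' analyses (proportions, switches, NMD flags). Every stage reads its
#' inputs from and writes its outputs to `outDir` as plain TSV, so any
#' stage can be re-run on its own against the cached intermediates, and
#' a `manifest.json` records the configuration, all parameters and the
#' MD5 of every input and output file. Runs with identical configuration
#' and seed produce byte-identical manifests.
#'
#' @param config A configuration list, or the path to a YAML file with
#'   the same fields. Unset fields take the package defaults (power 17,
#'   scale-free target 0.7, deepSplit 4, minClusterSize 20, TOM
#'   dissimilarity, top fraction 0.01, min gene TPM 1, seed 1). Provide
#'   either `simulate` (arguments for [simulateHeatStress()], or `TRUE`
#'   for its defaults) or `inputs` (paths: `expression`, `design`,
#'   `dtu_list`, `tx2gene`, `catalog`, and optionally `gtf`).
#' @param outDir Run directory (created if needed).
#' @param stages Stages to execute, in order; default all. Re-running a
#'   later stage alone requires the earlier stages' files in `outDir`.
#' @return The manifest, invisibly.
#' @export
runAll <- function(config = list(simulate = TRUE), outDir,
                   stages = c("inputs", "normalize", "cluster",
                              "network", "isoforms")) {
  cfg <- .mergeConfig(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (st in stages) {
    res <- tryCatch(switch(st,
      inputs = .stage_inputs(cfg, outDir),
      normalize = .stage_normalize(cfg, outDir),
      cluster = .stage_cluster(cfg, outDir),
      network = .stage_network(cfg, outDir),
      isoforms = .stage_isoforms(cfg, outDir)),
      error = function(e) stop(sprintf("stage '%s' failed: %s", st,
                                       conditionMessage(e)), call. = FALSE))
  }
  manifest <- .writeManifest(cfg, outDir)
  invisible(manifest)
}

.writeManifest <- function(cfg, dir) {
  hashDir <- function(paths) {
    paths <- paths[file.exists(paths)]
    h <- as.vector(tools::md5sum(paths))
    stats::setNames(h, basename(paths))
  }
  inputFiles <- sort(list.files(file.path(dir, "inputs"), full.names = TRUE))
  outFiles <- sort(setdiff(list.files(dir, full.names = TRUE),
                           c(file.path(dir, "inputs"),
                             file.path(dir, "manifest.json"))))
  summary <- list()
  cl <- file.path(dir, "clusters.tsv")
  if (file.exists(cl)) {
    lab <- .readClusters(dir)
    sizes <- if (any(lab > 0)) as.integer(table(lab[lab > 0])) else integer(0)
    summary$n_clusters <- length(sizes)
    summary$cluster_sizes <- sort(sizes, decreasing = TRUE)
    summary$n_outlier <- sum(lab == 0L)
  }
  nt <- file.path(dir, "network.tsv")
  if (file.exists(nt)) {
    net <- readNetworkTsv(nt)
    cand <- utils::read.delim(file.path(dir, "candidate_edges.tsv"))
    perCluster <- !duplicated(net$cluster_id)
    summary$n_candidate_edges <- nrow(cand)
    summary$n_retained_edges <- nrow(net)
    summary$threshold <- min(abs(net$pearson_r))
    summary$n_early_clusters <- sum(net$temporal_class[perCluster] == "early")
    summary$n_late_clusters <- sum(net$temporal_class[perCluster] == "late")
  }
  sw <- file.path(dir, "switches.tsv")
  if (file.exists(sw))
    summary$n_switch_events <- nrow(utils::read.delim(sw))
  nf <- file.path(dir, "nmd_flags.tsv")
  if (file.exists(nf))
    summary$n_nmd_flagged <- sum(utils::read.delim(nf)$flagged)
  pw <- file.path(dir, "power_used.txt")
  manifest <- list(
    tool = "heatSpliceNet",
    config = cfg[order(names(cfg))],
    parameters = list(
      power = if (file.exists(pw)) as.numeric(readLines(pw)) else cfg$power,
      deep_split = cfg$deep_split,
      min_cluster_size = cfg$min_cluster_size,
      dissimilarity = cfg$dissimilarity,
      top_fraction = cfg$top_fraction,
      scale_free_target = cfg$scale_free_target,
      min_gene_tpm = cfg$min_gene_tpm,
      seed = cfg$seed),
    inputs = as.list(hashDir(inputFiles)),
    outputs = as.list(hashDir(outFiles)),
    summary = summary)
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(dir, "manifest.json"))
  manifest
}
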