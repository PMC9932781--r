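#' Exon-exon junction positions in transcript coordinates
#'
#' Walks each transcript 5' to 3' and reports the 1-based transcript
#' coordinate of the last nucleotide of each upstream exon -- the
#' positions where exon junction complexes are deposited. Single-exon
#' transcripts have no junctions.
#'
#' @param models A [TranscriptModels-class] object.
#' @return Named list, one integer vector of junction positions per
#'   transcript.
#' @export
transcriptJunctions <- function(models) {
  stopifnot(methods::is(models, "TranscriptModels"))
  lapply(stats::setNames(transcriptIds(models), transcriptIds(models)),
         function(tx) {
           w <- GenomicRanges::width(exonModels(models)[[tx]])
           if (length(w) < 2L) return(integer(0))
           as.integer(cumsum(w)[-length(w)])
         })
}

# genomic position -> 1-based transcript coordinate (exons already in
# 5'->3' order; strand taken from the exons)
.g2t <- function(exons, gpos) {
  st <- as.character(GenomicRanges::strand(exons))[1L]
  offsets <- c(0L, cumsum(GenomicRanges::width(exons)))
  for (i in seq_along(exons)) {
    s <- GenomicRanges::start(exons)[i]
    e <- GenomicRanges::end(exons)[i]
    if (gpos >= s && gpos <= e) {
      within <- if (st == "-") e - gpos + 1L else gpos - s + 1L
      return(offsets[i] + within)
    }
  }
  stop(sprintf("genomic position %d falls outside the exons", gpos))
}

#' Flag transcripts with NMD-targeting exon junctions
#'
#' Applies the 50-nt rule of nonsense-mediated decay targeting: a
#' transcript is flagged when an exon-exon junction lies strictly more
#' than 50 nt downstream of its stop codon, i.e. the junction's exon
#' junction complex is not displaced by the terminating ribosome. The
#' stop-codon position is the transcript coordinate of the last base of
#' the last CDS interval (dedicated stop-codon features are merged into
#' the CDS by [readGtf()]). Non-coding transcripts are never flagged.
#'
#' A junction exactly 50 nt downstream does not flag: the rule is a
#' strict `> 50`.
#'
#' @param models A [TranscriptModels-class] object.
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `stop_codon_pos`, `last_junction_pos` (both 1-based transcript
#'   coordinates, `NA` when absent), `distance`
#'   (`last_junction_pos - stop_codon_pos`) and logical `flagged`.
#' @export
nmdFlags <- function(models) {
  stopifnot(methods::is(models, "TranscriptModels"))
  juncs <- transcriptJunctions(models)
  rows <- lapply(transcriptIds(models), function(tx) {
    j <- juncs[[tx]]
    lastj <- if (length(j)) max(j) else NA_integer_
    cds <- cdsModels(models)[[tx]]
    if (length(cds) == 0L) {
      return(data.frame(transcript_id = tx, stop_codon_pos = NA_integer_,
                        last_junction_pos = lastj, distance = NA_integer_,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    exons <- exonModels(models)[[tx]]
    st <- as.character(GenomicRanges::strand(exons))[1L]
    stopG <- if (st == "-") min(GenomicRanges::start(cds))
             else max(GenomicRanges::end(cds))
    stopT <- .g2t(exons, stopG)
    txlen <- sum(GenomicRanges::width(exons))
    if (stopT > txlen) stop(sprintf("CDS of '%s' extends past transcript end", tx))
    dist <- if (is.na(lastj)) NA_integer_ else lastj - stopT
    flagged <- any(j > stopT + 50L)
    data.frame(transcript_id = tx, stop_codon_pos = stopT,
               last_junction_pos = lastj, distance = dist,
               flagged = flagged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Isoform proportions of gene expression over time
#'
#' For every gene, total gene expression at a timepoint is the sum of
#' its transcripts' TPM, and each isoform's proportion is its share of
#' that total. Timepoints where the gene is not expressed (gene TPM 0)
#' have undefined proportions, marked `NA`.
#'
#' @param tm Timepoint TPM matrix from [averageReplicates()].
#' @param txGene Named character vector transcript id -> gene id
#'   covering every row of `tm`.
#' @return Named list of per-gene tracks; each track is a list with
#'   `gene_id`, `isoforms`, `timepoints`, `gene_tpm` (vector) and
#'   `proportions` (isoforms x timepoints matrix, `NA` where undefined).
#' @export
isoformProportions <- function(tm, txGene) {
  missing <- setdiff(rownames(tm), names(txGene))
  if (length(missing))
    stop("transcript(s) without gene mapping: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  tps <- attr(tm, "timepoints_h")
  if (is.null(tps)) tps <- as.numeric(colnames(tm))
  genes <- unique(unname(txGene[rownames(tm)]))
  tracks <- lapply(genes, function(g) {
    iso <- sort(rownames(tm)[txGene[rownames(tm)] == g])
    sub <- tm[iso, , drop = FALSE]
    tot <- colSums(sub)
    prop <- sweep(sub, 2L, tot, "/")
    prop[, tot == 0] <- NA_real_
    list(gene_id = g, isoforms = iso, timepoints = tps,
         gene_tpm = unname(tot), proportions = prop)
  })
  stats::setNames(tracks, genes)
}

.dominantIsoform <- function(props) {
  # ties broken by lexicographic isoform id (rows are sorted by id)
  names(props)[which.max(props)]
}

#' Detect isoform switches between adjacent timepoints
#'
#' An isoform switch is a change, between two consecutive sampled
#' timepoints, of which isoform holds the largest share of the gene's
#' expression. Intervals where the gene is expressed below `minGeneTpm`
#' at either end are skipped (unexpressed timepoints produce noise-driven
#' dominance flips). Exact proportion ties are broken by lexicographic
#' isoform id, so results are deterministic.
#'
#' @param tracks A single track or list of tracks from
#'   [isoformProportions()].
#' @param minGeneTpm Minimum gene TPM at both interval ends (default 1).
#' @return `data.frame` of switch events: `gene_id`, `isoform_from`,
#'   `isoform_to`, `t_a`, `t_b` (the flanking timepoints),
#'   `prop_to_before`, `prop_to_after` (the incoming isoform's share on
#'   each side). Zero rows when no switch occurs.
#' @export
detectSwitches <- function(tracks, minGeneTpm = 1) {
  if (!is.null(tracks$gene_id)) tracks <- list(tracks)
  empty <- data.frame(gene_id = character(0), isoform_from = character(0),
                      isoform_to = character(0), t_a = numeric(0),
                      t_b = numeric(0), prop_to_before = numeric(0),
                      prop_to_after = numeric(0), stringsAsFactors = FALSE)
  rows <- lapply(tracks, function(tr) {
    p <- tr$proportions
    tps <- tr$timepoints
    out <- NULL
    for (i in seq_len(length(tps) - 1L)) {
      if (tr$gene_tpm[i] < minGeneTpm || tr$gene_tpm[i + 1L] < minGeneTpm) next
      if (anyNA(p[, i]) || anyNA(p[, i + 1L])) next
      da <- .dominantIsoform(stats::setNames(p[, i], rownames(p)))
      db <- .dominantIsoform(stats::setNames(p[, i + 1L], rownames(p)))
      if (da != db) {
        out <- rbind(out, data.frame(
          gene_id = tr$gene_id, isoform_from = da, isoform_to = db,
          t_a = tps[i], t_b = tps[i + 1L],
          prop_to_before = p[db, i], prop_to_after = p[db, i + 1L],
          stringsAsFactors = FALSE))
      }
    }
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the CDS coverage of a genomic region between two isoforms
#'
#' Classifies how isoform `txB`'s coding sequence covers a region
#' (typically a protein-domain-encoding interval) relative to isoform
#' `txA` of the same gene: `"identical"` (same covered bases),
#' `"truncated_in_b"` (a proper non-empty subset of A's covered bases),
#' `"absent_in_b"` (no overlap with the region),
#' `"identical_complement"` (B covers exactly the region bases A does
#' not), or `"other"` for coverage patterns outside these classes.
#'
#' @param models A [TranscriptModels-class] object.
#' @param txA,txB Transcript ids of two isoforms of the same gene.
#' @param region A `GRanges` of length 1 within the gene span.
#' @return A classification string.
#' @export
compareCdsRegion <- function(models, txA, txB, region) {
  tg <- txGeneMap(models)
  if (!identical(unname(tg[txA]), unname(tg[txB])))
    stop("isoforms must come from the same gene")
  stopifnot(length(region) == 1L)
  region <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(region),
    IRanges::IRanges(GenomicRanges::start(region), GenomicRanges::end(region)))
  cov <- function(tx) {
    cds <- cdsModels(models)[[tx]]
    if (length(cds) == 0L) return(GenomicRanges::GRanges())
    GenomicRanges::intersect(
      GenomicRanges::reduce(.unstrand(cds)), region)
  }
  a <- cov(txA)
  b <- cov(txB)
  wa <- sum(GenomicRanges::width(a))
  wb <- sum(GenomicRanges::width(b))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b)))
  if (wb == 0L) return("absent_in_b")
  if (wa == wb && inter == wa) return("identical")
  if (inter == wb && wb < wa) return("truncated_in_b")
  comp <- GenomicRanges::setdiff(region, a)
  wcomp <- sum(GenomicRanges::width(comp))
  interComp <- sum(GenomicRanges::width(GenomicRanges::intersect(b, comp)))
  if (wb == wcomp && interComp == wb) return("identical_complement")
  "other"
}

.unstrand <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  gr
}
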