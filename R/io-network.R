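.network_table <- function(network) {
  ed <- networkEdges(network)
  tc <- temporalClass(network)
  cls <- as.character(ed$cluster_id)
  data.frame(
    cluster_id = ed$cluster_id,
    regulator_transcript_id = ed$regulator_id,
    pearson_r = ed$r,
    temporal_class = ifelse(cls %in% names(tc), unname(tc[cls]), "unclassified"),
    stringsAsFactors = FALSE)
}

#' Export a bipartite splicing network
#'
#' Writes the cluster-regulator network for downstream visualisation
#' (e.g. Cytoscape). Three formats are supported: a TSV edge table with
#' columns `cluster_id`, `regulator_transcript_id`, `pearson_r`,
#' `temporal_class`; GraphML with a `type` node attribute distinguishing
#' cluster from regulator nodes; and SIF with the interaction token
#' `correlates`. Cluster node names are prefixed `cluster_` so the two
#' node sets cannot collide.
#'
#' @param network A [SpliceNetwork-class] object.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"graphml"`, `"sif"`.
#' @return `path`, invisibly.
#' @seealso [readNetworkTsv()]
#' @export
writeNetwork <- function(network, path, format = c("tsv", "graphml", "sif")) {
  stopifnot(methods::is(network, "SpliceNetwork"))
  format <- match.arg(format)
  tab <- .network_table(network)
  if (format == "tsv") {
    out <- tab
    out$pearson_r <- sprintf("%.15g", out$pearson_r)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("cluster_%d\tcorrelates\t%s",
                       tab$cluster_id, tab$regulator_transcript_id), path)
  } else {
    g <- .network_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.network_igraph <- function(network) {
  tab <- .network_table(network)
  cl_nodes <- sort(unique(tab$cluster_id))
  reg_nodes <- sort(unique(tab$regulator_transcript_id))
  verts <- data.frame(
    name = c(sprintf("cluster_%d", cl_nodes), reg_nodes),
    type = c(rep("cluster", length(cl_nodes)), rep("regulator", length(reg_nodes))),
    stringsAsFactors = FALSE)
  tc <- temporalClass(network)
  verts$temporal_class <- c(
    ifelse(as.character(cl_nodes) %in% names(tc),
           unname(tc[as.character(cl_nodes)]), "unclassified"),
    rep(NA_character_, length(reg_nodes)))
  edges <- data.frame(from = sprintf("cluster_%d", tab$cluster_id),
                      to = tab$regulator_transcript_id,
                      pearson_r = tab$pearson_r,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Read a network edge TSV written by [writeNetwork()]
#'
#' @param path Path to a network TSV.
#' @return A `data.frame` with columns `cluster_id`,
#'   `regulator_transcript_id`, `pearson_r`, `temporal_class`.
#' @export
readNetworkTsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("cluster_id", "regulator_transcript_id", "pearson_r", "temporal_class")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s is not a network TSV (missing columns)", path))
  tab$cluster_id <- as.integer(tab$cluster_id)
  tab$pearson_r <- as.numeric(tab$pearson_r)
  tab
}
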