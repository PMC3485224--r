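#' Export the cluster-relationship network for visualization
#'
#' Writes the final population network — the network edges that fall
#' within optimal clusters, weighted by similarity — in Cytoscape-ready
#' formats. Node attributes carry the sample ID, cluster label, degree
#' centrality (the visual node size) and an optional external population
#' label; the edge weight (similarity) is the edge-thickness proxy. A
#' \code{styleHint} graph attribute ("circular" or "organic") is written
#' instead of layout coordinates, which are a viewer concern.
#'
#' @param W weighted cluster-relationship matrix (from an
#'   [SpcResult-class]).
#' @param graph the [KnnGraph-class] the analysis ran on.
#' @param partition named integer vector of cluster labels.
#' @param degree named integer vector of degree centralities (default:
#'   recomputed from \code{graph}).
#' @param labels optional named vector of external population labels
#'   (annotation only).
#' @param format any of \code{"graphml"}, \code{"sif"} (default both).
#' @param prefix output path prefix.
#' @param styleHint preferred Cytoscape layout style.
#' @return invisibly, the paths written.
#' @export
exportNetwork <- function(W, graph, partition, degree = degreeCentrality(graph),
                          labels = NULL, format = c("graphml", "sif"),
                          prefix, styleHint = c("organic", "circular")) {
  styleHint <- match.arg(styleHint)
  bad <- setdiff(format, c("graphml", "sif"))
  if (length(bad))
    stop("unknown format(s) ", paste(bad, collapse = ", "),
         "; supported: graphml, sif")
  ids <- graph@sampleIDs
  e <- graph@edges
  w <- W[cbind(e$from, e$to)]
  keep <- w > 0
  edgeTab <- data.frame(from = e$from[keep], to = e$to[keep],
                        weight = w[keep], stringsAsFactors = FALSE)
  nodeTab <- data.frame(name = ids,
                        cluster = as.integer(partition[ids]),
                        degree = as.integer(degree[ids]),
                        stringsAsFactors = FALSE)
  if (!is.null(labels)) nodeTab$population <- as.character(labels[ids])
  g <- igraph::graph_from_data_frame(edgeTab, directed = FALSE,
                                     vertices = nodeTab)
  g <- igraph::set_graph_attr(g, "styleHint", styleHint)
  paths <- character()
  if ("graphml" %in% format) {
    p <- paste0(prefix, ".graphml")
    igraph::write_graph(g, p, format = "graphml")
    paths <- c(paths, p)
  }
  if ("sif" %in% format) {
    p <- paste0(prefix, ".sif")
    lines <- paste(edgeTab$from, "related", edgeTab$to)
    isolated <- setdiff(ids, unique(c(edgeTab$from, edgeTab$to)))
    writeLines(c(lines, isolated), p)
    paths <- c(paths, p)
  }
  pNode <- paste0(prefix, "_nodes.tsv")
  write.table(nodeTab, pNode, sep = "\t", quote = FALSE, row.names = FALSE)
  pEdge <- paste0(prefix, "_edges.tsv")
  write.table(edgeTab, pEdge, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pNode, pEdge))
}

#' Export the cluster hierarchy
#'
#' Newick output uses the cluster-stability span (death - birth
#' temperature) as branch lengths; JSON output additionally records birth
#' and death temperatures and memberships per cluster.
#'
#' @param tree a [ClusterTree-class].
#' @param prefix output path prefix.
#' @param format \code{"newick"}, \code{"json"} or \code{"both"}.
#' @return invisibly, the paths written.
#' @export
exportTree <- function(tree, prefix, format = c("newick", "json", "both")) {
  format <- match.arg(format)
  paths <- character()
  if (format %in% c("newick", "both")) {
    p <- paste0(prefix, ".nwk")
    writeLines(paste0(treeToNewick(tree), ";"), p)
    paths <- c(paths, p)
  }
  if (format %in% c("json", "both")) {
    p <- paste0(prefix, ".json")
    jsonlite::write_json(lapply(tree@nodes, function(nd) {
      list(id = nd$id, parent = nd$parent, children = nd$children,
           size = length(nd$members), members = nd$members,
           birth = nd$birth, death = nd$death, cs = nd$death - nd$birth)
    }), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

treeToNewick <- function(tree) {
  recurse <- function(nodeId) {
    nd <- tree@nodes[[nodeId]]
    label <- sprintf("cluster%d_n%d", nd$id, length(nd$members))
    cs <- nd$death - nd$birth
    if (!length(nd$children))
      return(sprintf("%s:%.8g", label, cs))
    kids <- nd$children
    sizes <- vapply(tree@nodes[kids], function(n) length(n$members), integer(1))
    firsts <- vapply(tree@nodes[kids], function(n) min(n$members), character(1))
    kids <- kids[order(-sizes, firsts)]
    sprintf("(%s)%s:%.8g",
            paste(vapply(kids, recurse, character(1)), collapse = ","),
            label, cs)
  }
  recurse(1L)
}
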