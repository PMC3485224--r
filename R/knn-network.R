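#' Build the k-nearest-neighbour population network
#'
#' Connects individuals that are mutual k nearest neighbours by genetic
#' distance: the edge (i, j) exists iff j is among i's k nearest AND i is
#' among j's k nearest (set \code{mutual = FALSE} for the union rule, where
#' one direction suffices). Afterwards every individual left without a
#' neighbour is connected to the individual with the smallest genetic
#' distance to it, applied iteratively until no isolated node remains. Tied
#' distances are broken by sample ID, so the network is invariant to the
#' input sample order.
#'
#' @param D a [DistanceMatrix-class].
#' @param k number of nearest neighbours (default 10); must satisfy
#'   1 <= k < number of samples.
#' @param mutual logical; mutual-k-NN rule (default) or union rule.
#' @return a [KnnGraph-class].
#' @export
buildKnnGraph <- function(D, k = 10L, mutual = TRUE) {
  v <- D@.Data
  ids <- rownames(v)
  n <- length(ids)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (k >= n) stop(sprintf("k = %d must be smaller than the number of samples (%d)", k, n))

  # neighbour lists ordered by (distance, ID); ID order makes ties deterministic
  idOrd <- order(ids)
  nbr <- vector("list", n)
  names(nbr) <- ids
  nbrSet <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- v[i, ]
    ord <- order(d[-i], rank(ids[-i]))
    cand <- ids[-i][ord]
    nbr[[i]] <- cand[seq_len(k)]
    nbrSet[i, nbr[[i]]] <- TRUE
  }
  inK <- if (mutual) nbrSet & t(nbrSet) else nbrSet | t(nbrSet)
  idx <- which(inK & upper.tri(inK), arr.ind = TRUE)
  edges <- data.frame(from = pmin(ids[idx[, 1]], ids[idx[, 2]]),
                      to = pmax(ids[idx[, 1]], ids[idx[, 2]]),
                      distance = v[idx], stringsAsFactors = FALSE)

  # orphan completion: isolated nodes get one edge to the nearest neighbour
  repeat {
    deg <- table(factor(c(edges$from, edges$to), levels = ids))
    orphans <- ids[deg == 0L]
    if (!length(orphans)) break
    add <- lapply(orphans, function(id) {
      d <- v[id, ]
      others <- setdiff(ids, id)
      nn <- others[order(d[others], rank(others))][1L]
      data.frame(from = min(id, nn), to = max(id, nn),
                 distance = v[id, nn], stringsAsFactors = FALSE)
    })
    add <- unique(do.call(rbind, add))
    key <- paste(edges$from, edges$to)
    add <- add[!(paste(add$from, add$to) %in% key), , drop = FALSE]
    edges <- rbind(edges, add)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("KnnGraph", sampleIDs = ids[idOrd], edges = edges, k = k,
      mutual = mutual, neighbours = nbr[idOrd])
}

#' Degree centrality of every node
#'
#' The number of direct connections of each individual in the network; in
#' the final visualization it drives the node size and highlights key,
#' highly connected individuals.
#'
#' @param graph a [KnnGraph-class].
#' @return named integer vector over all samples.
#' @export
degreeCentrality <- function(graph) {
  tab <- table(factor(c(graph@edges$from, graph@edges$to),
                      levels = graph@sampleIDs))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Convert a KnnGraph to an igraph object
#'
#' @param graph a [KnnGraph-class].
#' @return an undirected \pkg{igraph} graph with a \code{distance} edge
#'   attribute.
#' @export
asIgraph <- function(graph) {
  g <- igraph::graph_from_data_frame(graph@edges, directed = FALSE,
                                     vertices = data.frame(name = graph@sampleIDs))
  g
}

#' Write the network edge list as TSV
#'
#' @param graph a [KnnGraph-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(graph, path) {
  write.table(graph@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
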