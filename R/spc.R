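#' Configure a super-paramagnetic clustering run
#'
#' @param q number of Potts states (default 20, the standard choice: large
#'   enough that distinct clusters rarely share a spin by chance, small
#'   enough to keep the transition sharp).
#' @param temperatures explicit increasing temperature grid; \code{NULL}
#'   (default) selects the automatic grid of 50 evenly spaced points from
#'   0.01 T* to 2 T*, T* = mean(J) / (4 log(1 + sqrt(q))), extended until
#'   both the one-cluster and the all-singleton regimes are seen.
#' @param burnInSweeps,measureSweeps discarded / measured Swendsen-Wang
#'   sweeps per temperature (defaults 200 and 800).
#' @param theta spin-spin correlation threshold linking edges into
#'   clusters (default 0.5).
#' @param minClusterSize smallest reported cluster; smaller components are
#'   kept as unclustered singletons (default 2).
#' @param captureRule also link each node to its highest-correlation
#'   neighbour when that correlation exceeds theta/2 (default TRUE); this
#'   attaches stragglers to the cluster they correlate with most.
#' @param seed RNG seed.
#' @return an [SpcConfig-class].
#' @export
spcConfig <- function(q = 20L, temperatures = NULL, burnInSweeps = 200L,
                      measureSweeps = 800L, theta = 0.5,
                      minClusterSize = 2L, captureRule = TRUE, seed = 1L) {
  new("SpcConfig", q = as.integer(q),
      temperatures = if (is.null(temperatures)) numeric() else as.numeric(temperatures),
      burnInSweeps = as.integer(burnInSweeps),
      measureSweeps = as.integer(measureSweeps), theta = theta,
      minClusterSize = as.integer(minClusterSize),
      captureRule = isTRUE(captureRule), seed = as.integer(seed))
}

#' Potts couplings on the population network
#'
#' Assigns every edge a ferromagnetic interaction strength
#' J_ij = (1/K) exp(-d_ij^2 / (2 a^2)), where a is the mean edge distance
#' (the local distance scale) and K the mean node degree. J decreases
#' strictly with distance, so genetically close neighbours are coupled
#' more strongly.
#'
#' @param graph a [KnnGraph-class] with at least one edge.
#' @return a [Couplings-class] aligned with \code{edges(graph)}.
#' @export
computeCouplings <- function(graph) {
  e <- graph@edges
  if (!nrow(e)) stop("graph has no edges")
  a <- mean(e$distance)
  if (a == 0)
    stop("all edge distances are zero; remove duplicate samples or jitter distances")
  kHat <- 2 * nrow(e) / length(graph@sampleIDs)
  J <- exp(-e$distance^2 / (2 * a^2)) / kHat
  new("Couplings", J = J, a = a, meanDegree = kHat)
}

# edge endpoints as 0-based indices into sampleIDs, for the C++ engine
edgeIndices <- function(graph) {
  ids <- graph@sampleIDs
  list(from = match(graph@edges$from, ids) - 1L,
       to = match(graph@edges$to, ids) - 1L)
}

#' One Swendsen-Wang cluster update
#'
#' For every edge whose endpoints share a spin the bond freezes with
#' probability 1 - exp(-J_ij / T); each connected component of frozen
#' bonds then receives an independent uniform spin from \{1..q\}. At high
#' temperature no bond freezes and spins are redrawn independently; at low
#' temperature aligned regions flip as one block.
#'
#' @param state integer vector of current spins in \{1..q\}, one per
#'   sample (named or in \code{sampleIDs(graph)} order).
#' @param graph a [KnnGraph-class].
#' @param couplings a [Couplings-class] for the graph.
#' @param temperature positive temperature.
#' @param q number of Potts states.
#' @return integer vector of updated spins.
#' @export
swendsenWangSweep <- function(state, graph, couplings, temperature, q = 20L) {
  stopifnot(temperature > 0, all(state >= 1L), all(state <= q))
  idx <- edgeIndices(graph)
  out <- .swSweepOnce(as.integer(state) - 1L, idx$from, idx$to,
                      couplings@J, temperature, as.integer(q)) + 1L
  names(out) <- graph@sampleIDs
  out
}

#' Equilibrium measurements at one temperature
#'
#' Runs burn-in followed by measurement sweeps and records, per edge, the
#' spin-coincidence frequency <delta_{s_i, s_j}> and its unbiased
#' correlation estimate G_ij = (q <delta> - 1) / (q - 1) (clipped to
#' [0, 1]); the mean magnetization m = (q N_max / N - 1) / (q - 1) with
#' N_max the largest spin population; and the susceptibility
#' chi = (N / T) (<m^2> - <m>^2). The partition is extracted from G via
#' [extractClusters()].
#'
#' @param graph a [KnnGraph-class].
#' @param couplings a [Couplings-class].
#' @param temperature positive temperature.
#' @param config an [SpcConfig-class]; the RNG is seeded from
#'   \code{config@seed}.
#' @return list with elements \code{temperature}, \code{delta} (per-edge
#'   coincidence frequency), \code{G} (per-edge correlation),
#'   \code{magnetization}, \code{susceptibility}, \code{partition}.
#' @export
measureAtTemperature <- function(graph, couplings, temperature, config) {
  set.seed(config@seed)
  recs <- runEngine(graph, couplings, temperature, config)
  recs[[1L]]
}

# Run the C++ engine over a temperature grid; RNG state is taken as-is so
# the caller controls seeding.
runEngine <- function(graph, couplings, temps, config) {
  idx <- edgeIndices(graph)
  n <- length(graph@sampleIDs)
  q <- config@q
  eng <- .spcEngine(n, idx$from, idx$to, couplings@J, as.numeric(temps),
                    q, config@burnInSweeps, config@measureSweeps)
  lapply(seq_along(temps), function(t) {
    delta <- eng$deltaFreq[t, ]
    G <- pmin(pmax((q * delta - 1) / (q - 1), 0), 1)
    mm <- eng$mMean[t]
    chi <- n / temps[t] * max(eng$m2Mean[t] - mm^2, 0)
    rec <- list(temperature = temps[t], delta = delta, G = G,
                magnetization = mm, susceptibility = chi)
    rec$partition <- extractClusters(rec, graph, theta = config@theta,
                                     minClusterSize = config@minClusterSize,
                                     captureRule = config@captureRule)
    rec
  })
}

#' Extract the cluster partition from spin-spin correlations
#'
#' Links every edge whose correlation exceeds \code{theta}; when
#' \code{captureRule} is on, each node is additionally linked to its
#' neighbour of maximal correlation provided that correlation exceeds
#' \code{theta / 2}. Clusters are the connected components of the linked
#' graph; components smaller than \code{minClusterSize} are reported as
#' unclustered singletons. Labels are ordered by decreasing cluster size
#' (ties by smallest member ID), and the logical attribute
#' \code{"clustered"} marks members of genuine clusters.
#'
#' @param record a per-temperature record with element \code{G} aligned
#'   with the graph's edges (see [measureAtTemperature()]).
#' @param graph a [KnnGraph-class].
#' @param theta correlation threshold (default 0.5).
#' @param minClusterSize minimum cluster size (default 2).
#' @param captureRule logical (default TRUE).
#' @return named integer vector of cluster labels per sample.
#' @export
extractClusters <- function(record, graph, theta = 0.5, minClusterSize = 2L,
                            captureRule = TRUE) {
  ids <- graph@sampleIDs
  e <- graph@edges
  G <- record$G
  keep <- G > theta
  if (captureRule && nrow(e)) {
    # per node, its incident edge of maximal correlation
    einc <- c(seq_len(nrow(e)), seq_len(nrow(e)))
    node <- c(e$from, e$to)
    gv <- c(G, G)
    ord <- order(node, -gv, einc)
    first <- !duplicated(node[ord])
    best <- einc[ord][first]
    bestG <- gv[ord][first]
    keep[best[bestG > theta / 2]] <- TRUE
  }
  sub <- igraph::graph_from_data_frame(e[keep, c("from", "to"), drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = ids))
  comp <- igraph::components(sub)
  member <- split(ids, comp$membership[ids])
  small <- lengths(member) < minClusterSize
  # break undersized components into unclustered singletons
  member <- c(member[!small],
              lapply(unlist(member[small], use.names = FALSE), identity))
  clustered <- c(rep(TRUE, sum(!small)),
                 rep(FALSE, length(member) - sum(!small)))
  sizes <- lengths(member)
  minId <- vapply(member, min, character(1))
  ord <- order(-sizes, minId)
  member <- member[ord]
  clustered <- clustered[ord]
  part <- integer(length(ids))
  names(part) <- ids
  for (i in seq_along(member)) part[member[[i]]] <- i
  attr(part, "clustered") <- clustered[part]
  part
}

partitionSignature <- function(part) {
  sizes <- sort(tabulate(part), decreasing = TRUE)
  paste0(length(sizes), "|", paste(sizes, collapse = ","))
}

#' Run super-paramagnetic clustering over a temperature gradient
#'
#' The full clustering stage: Potts couplings on the network, Swendsen-
#' Wang Monte Carlo at every temperature of the grid, per-temperature
#' partitions from the spin-spin correlations, the cluster-stability
#' hierarchy, and the optimal partition. The optimal partition is the
#' cluster configuration (number of clusters and multiset of sizes) that
#' persists over the longest contiguous span of the temperature gradient
#' (the all-singleton paramagnetic configuration is not a candidate; ties
#' go to the lower temperature). The binary cluster-relationship matrix B
#' marks network edges within optimal clusters, and W = B * S weights them
#' by the similarity matrix.
#'
#' @param D a [DistanceMatrix-class] (used for the similarity weighting
#'   and the re-ordered output matrix).
#' @param graph the [KnnGraph-class] built from \code{D}.
#' @param config an [SpcConfig-class].
#' @param similarity optional [SimilarityMatrix-class]; defaults to
#'   \code{1 - D} when distances lie in [0, 1].
#' @return an [SpcResult-class].
#' @export
runSpc <- function(D, graph, config = spcConfig(), similarity = NULL) {
  stopifnot(is(D, "DistanceMatrix"), is(graph, "KnnGraph"))
  couplings <- computeCouplings(graph)
  ids <- graph@sampleIDs
  n <- length(ids)
  if (is.null(similarity)) {
    similarity <- if (all(D@.Data >= 0 & D@.Data <= 1)) toSimilarity(D)
                  else stop("supply 'similarity' when distances are not in [0, 1]")
  }
  set.seed(config@seed)

  if (length(config@temperatures)) {
    temps <- config@temperatures
    records <- runEngine(graph, couplings, temps, config)
  } else {
    tStar <- mean(couplings@J) / (4 * log(1 + sqrt(config@q)))
    temps <- seq(0.01 * tStar, 2 * tStar, length.out = 50L)
    records <- runEngine(graph, couplings, temps, config)
    nComp <- igraph::count_components(asIgraph(graph))
    oneCluster <- function(r) max(r$partition) <= nComp
    allSingle <- function(r) max(tabulate(r$partition)) == 1L
    ext <- 0L
    while (!any(vapply(records, allSingle, logical(1))) && ext < 3L) {
      hi <- max(temps)
      newT <- seq(hi + diff(temps)[1], 2 * hi, length.out = 25L)
      records <- c(records, runEngine(graph, couplings, newT, config))
      temps <- c(temps, newT)
      ext <- ext + 1L
    }
    while (!any(vapply(records, oneCluster, logical(1))) && ext < 6L) {
      lo <- min(temps)
      newT <- seq(lo / 10, lo * 0.9, length.out = 10L)
      records <- c(records[0], runEngine(graph, couplings, newT, config), records)
      temps <- c(newT, temps)
      ext <- ext + 1L
    }
    ord <- order(temps)
    temps <- temps[ord]
    records <- records[ord]
    if (!any(vapply(records, allSingle, logical(1))) ||
        !any(vapply(records, oneCluster, logical(1))))
      warning("temperature grid did not reach both the one-cluster and ",
              "all-singleton regimes; trace: ",
              paste(vapply(records, function(r) max(r$partition), integer(1)),
                    collapse = " "))
  }

  # optimal configuration: longest contiguous persistence of
  # (cluster count, size multiset); the fully unclustered state is excluded
  sig <- vapply(records, function(r) partitionSignature(r$partition), character(1))
  singletonSig <- paste0(n, "|", paste(rep(1L, n), collapse = ","))
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values != singletonSig)
  if (!length(cand)) cand <- seq_along(runs$values)
  best <- cand[which.max(runs$lengths[cand])]   # ties: first = lower T
  optIdx <- as.integer(floor((starts[best] + ends[best]) / 2))

  tree <- buildClusterTree(records, temps, ids, config@minClusterSize)
  part <- records[[optIdx]]$partition

  S <- similarity@.Data[ids, ids]
  B <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- graph@edges
  co <- part[e$from] == part[e$to]
  for (r in which(co)) {
    B[e$from[r], e$to[r]] <- 1
    B[e$to[r], e$from[r]] <- 1
  }
  W <- B * S

  ro <- reorderDistanceMatrix(D, tree)

  new("SpcResult", records = records, temperatures = temps,
      optimalIndex = optIdx, partition = part, tree = tree,
      binaryMatrix = B, weightMatrix = W,
      reorderedDistance = ro$matrix, permutation = ro$permutation,
      config = config)
}

# Assemble the cluster hierarchy by majority linkage between consecutive
# temperatures. A frontier of leaf nodes partitions the samples; at each
# temperature every cluster is assigned to the frontier node holding the
# plurality of its members. A frontier node whose membership is intact
# extends its lifetime (death temperature); otherwise it is replaced by
# child nodes, one per piece of at least minClusterSize members, so
# children are disjoint subsets of their parent by construction.
buildClusterTree <- function(records, temps, ids, minClusterSize = 2L) {
  nodes <- list(list(id = 1L, parent = 0L, children = integer(),
                     members = ids, birth = temps[1L], death = temps[1L]))
  frontier <- setNames(rep(1L, length(ids)), ids)  # sample -> leaf node id
  for (t in seq_along(records)) {
    part <- records[[t]]$partition
    labs <- sort(unique(part))
    # plurality frontier node per cluster (ties: larger overlap, lower id)
    assign <- vapply(labs, function(lab) {
      ov <- table(frontier[names(part)[part == lab]])
      cand <- as.integer(names(ov))
      cand[order(-as.integer(ov), cand)][1L]
    }, integer(1))
    for (f in unique(frontier)) {
      fmem <- names(frontier)[frontier == f]
      clab <- labs[assign == f]
      pieces <- lapply(clab, function(lab)
        intersect(names(part)[part == lab], fmem))
      pieces <- pieces[lengths(pieces) > 0L]
      if (length(pieces) == 1L && length(pieces[[1L]]) == length(fmem)) {
        nodes[[f]]$death <- temps[t]          # intact: extend lifetime
        next
      }
      pieces <- pieces[lengths(pieces) >= minClusterSize]
      if (length(pieces) > 1L ||
          (length(pieces) == 1L && length(pieces[[1L]]) < length(fmem))) {
        firsts <- vapply(pieces, min, character(1))
        pieces <- pieces[order(-lengths(pieces), firsts)]
        for (mem in pieces) {
          nodeId <- length(nodes) + 1L
          nodes[[nodeId]] <- list(id = nodeId, parent = f,
                                  children = integer(), members = mem,
                                  birth = temps[t], death = temps[t])
          nodes[[f]]$children <- c(nodes[[f]]$children, nodeId)
          frontier[mem] <- nodeId
        }
      }
      # members in no surviving piece leave the frontier (melted)
      melted <- setdiff(fmem, unlist(pieces, use.names = FALSE))
      frontier <- frontier[setdiff(names(frontier), melted)]
      if (!length(pieces)) next
    }
  }
  new("ClusterTree", nodes = nodes, sampleIDs = ids)
}

#' Cluster stability of every tree node
#'
#' CS is the persistence span of a cluster along the temperature
#' (genetic-distance threshold) gradient: death minus birth temperature.
#'
#' @param tree a [ClusterTree-class].
#' @return data.frame with node id, parent, size, birth, death and CS.
#' @export
clusterStability <- function(tree) {
  data.frame(
    id = vapply(tree@nodes, `[[`, integer(1), "id"),
    parent = vapply(tree@nodes, `[[`, integer(1), "parent"),
    size = vapply(tree@nodes, function(n) length(n$members), integer(1)),
    birth = vapply(tree@nodes, `[[`, numeric(1), "birth"),
    death = vapply(tree@nodes, `[[`, numeric(1), "death"),
    cs = vapply(tree@nodes, function(n) n$death - n$birth, numeric(1))
  )
}

#' Re-order a distance matrix by the cluster hierarchy
#'
#' Samples are permuted into depth-first traversal order of the cluster
#' tree so that clusters appear as contiguous blocks along the diagonal.
#'
#' @param D a [DistanceMatrix-class].
#' @param tree a [ClusterTree-class] over the same samples.
#' @return list with \code{matrix} (the permuted distances) and
#'   \code{permutation} (integer indices into the original order).
#' @export
reorderDistanceMatrix <- function(D, tree) {
  ids <- rownames(D@.Data)
  dfs <- function(nodeId) {
    nd <- tree@nodes[[nodeId]]
    if (!length(nd$children)) return(sort(nd$members))
    kids <- nd$children
    # deterministic child order: larger clusters first, then smallest ID
    sizes <- vapply(tree@nodes[kids], function(n) length(n$members), integer(1))
    firsts <- vapply(tree@nodes[kids], function(n) min(n$members), character(1))
    kids <- kids[order(-sizes, firsts)]
    covered <- unlist(lapply(kids, dfs), use.names = FALSE)
    c(covered, sort(setdiff(nd$members, covered)))
  }
  ordIds <- dfs(1L)
  perm <- match(ordIds, ids)
  list(matrix = D@.Data[perm, perm, drop = FALSE], permutation = perm)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 means identical partitions, 0 the expectation under independence.
#'
#' @param a,b label vectors (named vectors are matched by name).
#' @return the adjusted Rand index.
#' @export
ariScore <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  expected <- sumi * sumj / choose(n, 2)
  maxidx <- (sumi + sumj) / 2
  if (maxidx == expected) return(1)
  (sumij - expected) / (maxidx - expected)
}

#' Write SPC results as plain-text tables
#'
#' Writes the per-temperature partitions, the susceptibility trace, the
#' cluster tree (Newick with CS branch lengths plus JSON with birth/death
#' temperatures) and the relationship matrices.
#'
#' @param result an [SpcResult-class].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeSpcResult <- function(result, prefix) {
  paths <- character()
  parts <- do.call(rbind, lapply(result@records, function(r) {
    data.frame(sample = names(r$partition), cluster = as.integer(r$partition),
               temperature = r$temperature)
  }))
  p <- paste0(prefix, "_partitions.tsv")
  write.table(parts, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_susceptibility.tsv")
  write.table(susceptibilityTrace(result), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_optimal_partition.tsv")
  write.table(data.frame(sample = names(result@partition),
                         cluster = as.integer(result@partition),
                         clustered = attr(result@partition, "clustered")),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  paths <- c(paths, exportTree(result@tree, paste0(prefix, "_tree"),
                               format = "both"))
  mats <- c(binaryMatrix = "binary_matrix", weightMatrix = "weight_matrix",
            reorderedDistance = "reordered_distance")
  for (nm in names(mats)) {
    p <- paste0(prefix, "_", mats[[nm]], ".tsv")
    m <- slot(result, nm)
    write.table(data.frame(id = rownames(m), m, check.names = FALSE), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
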