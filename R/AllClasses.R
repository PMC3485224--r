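#' @import methods
#' @importFrom stats runif rbeta rbinom rbeta kmeans quantile
#' @importFrom utils read.table write.table
#' @useDynLib popnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' GenotypeDataset: diploid SNP genotype calls with marker metadata
#'
#' Samples-by-SNPs matrix of diploid genotype codes counting copies of the
#' counted allele (the lexicographically later of the two observed alleles),
#' so codes are 0, 1, 2 or \code{NA} for missing. Marker metadata
#' (chromosome, position, the two alleles) is carried alongside.
#'
#' @slot genotypes integer matrix, samples in rows (rownames = sample IDs),
#'   SNPs in columns (colnames = SNP IDs); entries in \{0, 1, 2, NA\}.
#' @slot snpInfo data.frame with one row per SNP: \code{chrom} (character),
#'   \code{pos} (integer, 1-based; \code{NA} if unknown), \code{allele1},
#'   \code{allele2} (counted allele; may be \code{NA} when unobserved).
#'
#' @seealso [readPlinkText()], [qcFilter()], [asdMatrix()]
#' @export
setClass("GenotypeDataset",
  representation(genotypes = "matrix", snpInfo = "data.frame"),
  validity = function(object) {
    g <- object@genotypes
    msg <- character()
    if (is.null(rownames(g)) || is.null(colnames(g)))
      msg <- c(msg, "genotype matrix must have sample IDs as rownames and SNP IDs as colnames")
    else {
      if (anyDuplicated(rownames(g))) msg <- c(msg, "duplicate sample IDs")
      if (anyDuplicated(colnames(g))) msg <- c(msg, "duplicate SNP IDs")
    }
    vals <- g[!is.na(g)]
    if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
    if (nrow(object@snpInfo) != ncol(g))
      msg <- c(msg, "snpInfo rows must match genotype columns")
    if (!all(c("chrom", "pos") %in% colnames(object@snpInfo)))
      msg <- c(msg, "snpInfo must have columns 'chrom' and 'pos'")
    if (length(msg)) msg else TRUE
  }
)

#' QcReport: record of genotype quality-control filtering
#'
#' @slot removedSnps data.frame with columns \code{id} and \code{reason}
#'   (one of \code{no_position}, \code{low_call_rate}, \code{low_maf},
#'   \code{hwe_fail}).
#' @slot removedSamples data.frame with columns \code{id} and \code{reason}
#'   (one of \code{low_call_rate}, \code{duplicate}).
#' @slot thresholds named list of the thresholds applied.
#' @slot dims integer vector: samples/SNPs before and after filtering.
#'
#' @export
setClass("QcReport",
  representation(removedSnps = "data.frame", removedSamples = "data.frame",
                 thresholds = "list", dims = "integer"))

#' DistanceMatrix: pairwise genetic distances
#'
#' A symmetric square matrix of pairwise genetic distances with a zero
#' diagonal; sample IDs are the dimnames. Allele-sharing distances live in
#' [0, 1]; externally supplied model-based distances may use any
#' non-negative scale.
#'
#' @export
setClass("DistanceMatrix", contains = "matrix",
  validity = function(object) {
    m <- object@.Data
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
    if (is.null(rownames(m))) msg <- c(msg, "must carry sample IDs as dimnames")
    if (any(!is.finite(m))) msg <- c(msg, "entries must be finite")
    else {
      if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "must be symmetric")
      if (any(abs(diag(m)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    }
    if (length(msg)) msg else TRUE
  }
)

#' SimilarityMatrix: pairwise genetic similarity / relationship
#'
#' Symmetric square matrix of similarities (1 - distance for allele-sharing
#' input, or an externally supplied relationship such as a co-ancestry
#' matrix). The diagonal holds the maximal similarity of each row.
#'
#' @export
setClass("SimilarityMatrix", contains = "matrix",
  validity = function(object) {
    m <- object@.Data
    msg <- character()
    if (nrow(m) != ncol(m)) msg <- c(msg, "must be square")
    if (is.null(rownames(m))) msg <- c(msg, "must carry sample IDs as dimnames")
    if (any(!is.finite(m))) msg <- c(msg, "entries must be finite")
    else if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, "must be symmetric")
    if (length(msg)) msg else TRUE
  }
)

#' KnnGraph: mutual k-nearest-neighbour population network
#'
#' Sparse undirected network over samples. An edge joins two individuals
#' when each is among the other's k nearest neighbours by genetic distance
#' (mutual rule; a union rule is available), after which every isolated
#' individual receives one edge to its globally nearest neighbour.
#'
#' @slot sampleIDs character vector of node IDs.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{distance}; each unordered pair appears once with
#'   \code{from < to} lexicographically.
#' @slot k the k-NN parameter used.
#' @slot mutual logical; TRUE for the mutual-k-NN rule.
#' @slot neighbours named list: per sample, its ordered k nearest
#'   neighbour IDs.
#'
#' @export
setClass("KnnGraph",
  representation(sampleIDs = "character", edges = "data.frame",
                 k = "integer", mutual = "logical", neighbours = "list"),
  validity = function(object) {
    e <- object@edges
    msg <- character()
    if (!all(c("from", "to", "distance") %in% colnames(e)))
      msg <- c(msg, "edges need columns from, to, distance")
    else {
      if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
      if (!all(c(e$from, e$to) %in% object@sampleIDs))
        msg <- c(msg, "edge endpoints must be sample IDs")
      if (anyDuplicated(paste(pmin(e$from, e$to), pmax(e$from, e$to))))
        msg <- c(msg, "duplicate edges")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Couplings: Potts interaction strengths on the network
#'
#' Per-edge ferromagnetic couplings J_ij = (1/K) * exp(-d_ij^2 / (2 a^2)),
#' where a is the mean neighbour (edge) distance and K the mean node degree.
#' J is symmetric and strictly decreasing in d.
#'
#' @slot J numeric vector of couplings, aligned with the graph's edge table.
#' @slot a local distance scale (mean edge distance).
#' @slot meanDegree mean node degree of the graph.
#'
#' @export
setClass("Couplings",
  representation(J = "numeric", a = "numeric", meanDegree = "numeric"),
  validity = function(object) {
    if (any(object@J <= 0)) "couplings must be strictly positive" else TRUE
  })

#' SpcConfig: parameters of the super-paramagnetic clustering run
#'
#' @slot q number of Potts states (default 20).
#' @slot temperatures increasing grid of positive temperatures; empty for
#'   the automatic grid.
#' @slot burnInSweeps,measureSweeps Swendsen-Wang sweeps discarded /
#'   measured at each temperature.
#' @slot theta spin-spin correlation threshold for linking edges into
#'   clusters (default 0.5).
#' @slot minClusterSize components smaller than this are reported as
#'   unclustered singletons (default 2).
#' @slot captureRule logical; additionally link each node to its
#'   highest-correlation neighbour (when that correlation exceeds theta/2).
#' @slot seed RNG seed for the Monte-Carlo run.
#'
#' @export
setClass("SpcConfig",
  representation(q = "integer", temperatures = "numeric",
                 burnInSweeps = "integer", measureSweeps = "integer",
                 theta = "numeric", minClusterSize = "integer",
                 captureRule = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@q < 2L) msg <- c(msg, "q must be >= 2")
    if (object@theta <= 0 || object@theta >= 1) msg <- c(msg, "theta must be in (0,1)")
    if (length(object@temperatures)) {
      if (any(object@temperatures <= 0)) msg <- c(msg, "temperatures must be positive")
      if (is.unsorted(object@temperatures, strictly = TRUE))
        msg <- c(msg, "temperatures must be strictly increasing")
    }
    if (object@burnInSweeps < 1L || object@measureSweeps < 1L)
      msg <- c(msg, "sweep counts must be positive")
    if (length(msg)) msg else TRUE
  })

#' ClusterTree: hierarchy of clusters over the temperature gradient
#'
#' Each node records the member samples of a cluster, the temperature at
#' which it first appears (birth), the temperature at which its membership
#' changes or it melts (death), and its cluster stability CS = death -
#' birth, i.e. its persistence span along the temperature (genetic-distance
#' threshold) gradient.
#'
#' @slot nodes list; each element has \code{id}, \code{parent} (0 for the
#'   root), \code{children} (integer ids), \code{members} (character),
#'   \code{birth}, \code{death} (numeric temperatures).
#' @slot sampleIDs all samples (members of the root).
#'
#' @export
setClass("ClusterTree",
  representation(nodes = "list", sampleIDs = "character"),
  validity = function(object) {
    if (!length(object@nodes)) return("tree must have at least a root node")
    root <- object@nodes[[1L]]
    msg <- character()
    if (!setequal(root$members, object@sampleIDs))
      msg <- c(msg, "root must contain all samples")
    for (nd in object@nodes) {
      if (length(nd$children)) {
        kids <- lapply(object@nodes[nd$children], `[[`, "members")
        all_kids <- unlist(kids)
        if (anyDuplicated(all_kids))
          msg <- c(msg, "children of a node must be disjoint")
        if (!all(all_kids %in% nd$members))
          msg <- c(msg, "children must be subsets of their parent")
      }
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' SpcResult: full output of a super-paramagnetic clustering run
#'
#' @slot records list of per-temperature records (see
#'   [measureAtTemperature()]): temperature, magnetization, susceptibility,
#'   per-edge spin-spin correlations, and the extracted partition.
#' @slot temperatures the temperature grid actually used.
#' @slot optimalIndex index into \code{records} of the selected partition.
#' @slot partition named integer vector: optimal cluster label per sample
#'   (labels ordered by decreasing cluster size); attribute
#'   \code{"clustered"} flags members of clusters of at least the minimum
#'   size.
#' @slot tree [ClusterTree-class] of cluster relationships.
#' @slot binaryMatrix 0/1 matrix: network edge within an optimal cluster.
#' @slot weightMatrix binaryMatrix weighted by the similarity matrix.
#' @slot reorderedDistance input distances permuted to the tree order.
#' @slot permutation sample order used for \code{reorderedDistance}.
#' @slot config the [SpcConfig-class] used.
#'
#' @export
setClass("SpcResult",
  representation(records = "list", temperatures = "numeric",
                 optimalIndex = "integer", partition = "integer",
                 tree = "ClusterTree", binaryMatrix = "matrix",
                 weightMatrix = "matrix", reorderedDistance = "matrix",
                 permutation = "integer", config = "SpcConfig"))

#' PopTreeSpec: hierarchical population scenario for the simulator
#'
#' Rooted population tree with one drift coefficient per branch,
#' F = 1 - exp(-t / (2 Ne)) for a branch lasting t generations at effective
#' size Ne. Leaves carry sample counts.
#'
#' @slot branches data.frame with columns \code{node}, \code{parent}
#'   (\code{"ROOT"} for top-level branches) and \code{f} (drift in [0, 1)).
#' @slot samplesPerLeaf named integer vector over leaf populations.
#' @slot nSnps number of SNPs to simulate.
#' @slot ancestralRange length-2 numeric: range of ancestral allele
#'   frequencies drawn per SNP.
#'
#' @export
setClass("PopTreeSpec",
  representation(branches = "data.frame", samplesPerLeaf = "integer",
                 nSnps = "integer", ancestralRange = "numeric"),
  validity = function(object) {
    b <- object@branches
    msg <- character()
    if (!all(c("node", "parent", "f") %in% colnames(b)))
      msg <- c(msg, "branches need columns node, parent, f")
    else {
      if (anyDuplicated(b$node)) msg <- c(msg, "branch nodes must be unique")
      if (any(b$f < 0 | b$f >= 1)) msg <- c(msg, "drift F must be in [0, 1)")
      leaves <- setdiff(b$node, b$parent)
      if (!setequal(names(object@samplesPerLeaf), leaves))
        msg <- c(msg, "samplesPerLeaf must name exactly the leaf populations")
    }
    if (object@nSnps < 1L) msg <- c(msg, "nSnps must be positive")
    if (length(object@ancestralRange) != 2L ||
        any(object@ancestralRange <= 0) || any(object@ancestralRange >= 1))
      msg <- c(msg, "ancestralRange must be two frequencies in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' PcaResult: principal components of a similarity matrix
#'
#' @slot scores samples x components score matrix.
#' @slot eigenvalues non-increasing eigenvalues of the centred matrix.
#' @slot varianceFraction per-component fraction of total variance.
#' @slot loadings component loading matrix (columns are components).
#'
#' @export
setClass("PcaResult",
  representation(scores = "matrix", eigenvalues = "numeric",
                 varianceFraction = "numeric", loadings = "matrix"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(rev(object@eigenvalues)))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (any(object@varianceFraction < -1e-12 | object@varianceFraction > 1 + 1e-12))
      msg <- c(msg, "variance fractions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })
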