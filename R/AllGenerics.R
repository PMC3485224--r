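#' Sample identifiers of an object
#'
#' @param x a popnet object carrying samples.
#' @return character vector of sample IDs.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @describeIn sampleIDs sample IDs of a genotype dataset
#' @export
setMethod("sampleIDs", "GenotypeDataset", function(x) rownames(x@genotypes))

#' @describeIn sampleIDs sample IDs of a distance matrix
#' @export
setMethod("sampleIDs", "DistanceMatrix", function(x) rownames(x@.Data))

#' @describeIn sampleIDs sample IDs of a similarity matrix
#' @export
setMethod("sampleIDs", "SimilarityMatrix", function(x) rownames(x@.Data))

#' @describeIn sampleIDs node IDs of a k-NN network
#' @export
setMethod("sampleIDs", "KnnGraph", function(x) x@sampleIDs)

#' @describeIn sampleIDs all samples under the root of a cluster tree
#' @export
setMethod("sampleIDs", "ClusterTree", function(x) x@sampleIDs)

#' SNP identifiers of a genotype dataset
#'
#' @param x a [GenotypeDataset-class].
#' @return character vector of SNP IDs.
#' @export
setGeneric("snpIDs", function(x) standardGeneric("snpIDs"))

#' @describeIn snpIDs SNP IDs of a genotype dataset
#' @export
setMethod("snpIDs", "GenotypeDataset", function(x) colnames(x@genotypes))

#' Genotype code matrix
#'
#' @param x a [GenotypeDataset-class].
#' @return integer matrix (samples x SNPs) of codes 0/1/2/NA.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @describeIn genotypes the code matrix
#' @export
setMethod("genotypes", "GenotypeDataset", function(x) x@genotypes)

#' SNP metadata of a genotype dataset
#'
#' @param x a [GenotypeDataset-class].
#' @return data.frame with chrom, pos and allele columns.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' @describeIn snpInfo the metadata table
#' @export
setMethod("snpInfo", "GenotypeDataset", function(x) x@snpInfo)

#' Edge table of a network
#'
#' @param x a [KnnGraph-class].
#' @return data.frame with columns from, to, distance.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @describeIn edges edge table of the k-NN network
#' @export
setMethod("edges", "KnnGraph", function(x) x@edges)

#' Optimal partition of an SPC run
#'
#' @param x an [SpcResult-class].
#' @return named integer vector of cluster labels with attribute
#'   \code{"clustered"}.
#' @export
setGeneric("partition", function(x) standardGeneric("partition"))

#' @describeIn partition the selected optimal partition
#' @export
setMethod("partition", "SpcResult", function(x) x@partition)

#' Cluster-stability tree of an SPC run
#'
#' @param x an [SpcResult-class].
#' @return a [ClusterTree-class].
#' @export
setGeneric("clusterTree", function(x) standardGeneric("clusterTree"))

#' @describeIn clusterTree the hierarchy of clusters
#' @export
setMethod("clusterTree", "SpcResult", function(x) x@tree)

#' Susceptibility trace of an SPC run
#'
#' @param x an [SpcResult-class].
#' @return data.frame with temperature, magnetization, susceptibility and
#'   number of clusters per recorded temperature.
#' @export
setGeneric("susceptibilityTrace", function(x) standardGeneric("susceptibilityTrace"))

#' @describeIn susceptibilityTrace per-temperature summaries
#' @export
setMethod("susceptibilityTrace", "SpcResult", function(x) {
  data.frame(
    temperature = vapply(x@records, `[[`, numeric(1), "temperature"),
    magnetization = vapply(x@records, `[[`, numeric(1), "magnetization"),
    susceptibility = vapply(x@records, `[[`, numeric(1), "susceptibility"),
    nClusters = vapply(x@records, function(r) max(r$partition), integer(1))
  )
})

setMethod("show", "GenotypeDataset", function(object) {
  g <- object@genotypes
  miss <- if (length(g)) mean(is.na(g)) else 0
  cat(sprintf("GenotypeDataset: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(g), ncol(g), 100 * miss))
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport\n")
  cat(sprintf("  samples: %d -> %d (removed %d)\n", object@dims[1], object@dims[3],
              nrow(object@removedSamples)))
  cat(sprintf("  SNPs:    %d -> %d (removed %d)\n", object@dims[2], object@dims[4],
              nrow(object@removedSnps)))
  if (nrow(object@removedSnps))
    print(table(object@removedSnps$reason))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix: %d samples, range [%.4g, %.4g]\n",
              nrow(object@.Data), min(object@.Data), max(object@.Data)))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d samples, range [%.4g, %.4g]\n",
              nrow(object@.Data), min(object@.Data), max(object@.Data)))
})

setMethod("show", "KnnGraph", function(object) {
  cat(sprintf("KnnGraph: %d nodes, %d edges (k = %d, %s rule)\n",
              length(object@sampleIDs), nrow(object@edges), object@k,
              if (object@mutual) "mutual" else "union"))
})

setMethod("show", "SpcConfig", function(object) {
  cat(sprintf(
    "SpcConfig: q = %d, theta = %.2f, %d + %d sweeps, %s, seed = %d\n",
    object@q, object@theta, object@burnInSweeps, object@measureSweeps,
    if (length(object@temperatures))
      sprintf("%d temperatures", length(object@temperatures))
    else "automatic temperature grid",
    object@seed))
})

setMethod("show", "ClusterTree", function(object) {
  leaves <- sum(vapply(object@nodes, function(n) length(n$children) == 0L, logical(1)))
  cat(sprintf("ClusterTree: %d nodes (%d leaves) over %d samples\n",
              length(object@nodes), leaves, length(object@sampleIDs)))
})

setMethod("show", "SpcResult", function(object) {
  p <- object@partition
  sizes <- sort(tabulate(p), decreasing = TRUE)
  cat(sprintf(
    "SpcResult: %d samples, %d temperatures; optimal partition at T = %.4g\n",
    length(p), length(object@temperatures),
    object@records[[object@optimalIndex]]$temperature))
  cat(sprintf("  %d clusters, sizes: %s\n", length(sizes),
              paste(utils::head(sizes, 10), collapse = ", ")))
})

setMethod("show", "PopTreeSpec", function(object) {
  cat(sprintf("PopTreeSpec: %d branches, leaves: %s; %d SNPs\n",
              nrow(object@branches),
              paste(sprintf("%s(n=%d)", names(object@samplesPerLeaf),
                            object@samplesPerLeaf), collapse = ", "),
              object@nSnps))
})

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult: %d samples, %d components; top variance fractions: %s\n",
              nrow(object@scores), ncol(object@scores),
              paste(sprintf("%.3f", utils::head(object@varianceFraction, 4)),
                    collapse = ", ")))
})
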