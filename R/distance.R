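#' Allele-sharing distance matrix
#'
#' Computes the classical allele-sharing distance between all pairs of
#' individuals: one minus the average proportion of alleles shared
#' identical-by-state per SNP. With genotype codes g in \{0, 1, 2\}, a pair
#' shares 2 - |g_i - g_j| alleles at a SNP, so
#' d_ij = mean(|g_i - g_j| / 2) over pairwise-complete SNPs.
#'
#' @param ds a [GenotypeDataset-class] with at least two samples and one
#'   SNP.
#' @return a [DistanceMatrix-class] with entries in [0, 1].
#' @examples
#' g <- rbind(s1 = c(2L, 1L), s2 = c(1L, 1L))
#' colnames(g) <- c("a", "b")
#' asdMatrix(genotypeDataset(g))   # d(s1, s2) = 0.25
#' @export
asdMatrix <- function(ds) {
  g <- ds@genotypes
  if (nrow(g) < 2L) stop("need at least two samples")
  if (ncol(g) < 1L) stop("need at least one SNP")
  pw <- pairwiseAbsDiff(g)
  if (any(pw$overlap == 0 & upper.tri(pw$overlap))) {
    bad <- which(pw$overlap == 0 & upper.tri(pw$overlap), arr.ind = TRUE)
    stop("distance undefined for sample pairs with no overlapping SNPs: ",
         paste(rownames(g)[bad[, 1]], rownames(g)[bad[, 2]],
               sep = "/", collapse = ", "))
  }
  d <- pw$sumAbsDiff / (2 * pw$overlap)
  diag(d) <- 0
  d <- (d + t(d)) / 2   # exact symmetry against floating-point noise
  dimnames(d) <- list(rownames(g), rownames(g))
  new("DistanceMatrix", d)
}

#' Read a square distance or similarity matrix
#'
#' Reads either a square TSV with sample IDs as header row (and optionally
#' a leading ID column), or a headerless PLINK \code{.mdist}-style matrix
#' accompanied by an ID file (\code{.mdist.id}, family and individual ID
#' per row). Asymmetry up to 1e-8 is tolerated; larger asymmetry is
#' symmetrized by averaging with a warning.
#'
#' @param path path to the matrix file.
#' @param idsPath optional path to the PLINK-style ID file.
#' @param type \code{"distance"} or \code{"similarity"}.
#' @return a [DistanceMatrix-class] or [SimilarityMatrix-class].
#' @export
readMatrix <- function(path, idsPath = NULL, type = c("distance", "similarity")) {
  type <- match.arg(type)
  if (!is.null(idsPath)) {
    ids <- read.table(idsPath, header = FALSE, colClasses = "character")
    ids <- if (ncol(ids) >= 2L && anyDuplicated(ids[[2]]) == 0L) ids[[2]]
           else apply(ids, 1, paste, collapse = "_")
    m <- as.matrix(read.table(path, header = FALSE))
    dimnames(m) <- list(ids, ids)
  } else {
    tab <- read.table(path, header = TRUE, check.names = FALSE)
    # a leading non-numeric column carries row IDs
    if (is.character(tab[[1]]) || is.factor(tab[[1]])) {
      rn <- as.character(tab[[1]])
      tab <- tab[, -1, drop = FALSE]
      rownames(tab) <- rn
    } else rownames(tab) <- colnames(tab)
    m <- as.matrix(tab)
  }
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix is not square: %d x %d", nrow(m), ncol(m)))
  if (!is.numeric(m)) stop("matrix is not numeric")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at row %s, column %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    warning(sprintf(
      "matrix asymmetric (max |M - t(M)| = %.3g); symmetrized by averaging",
      asym))
  }
  m <- (m + t(m)) / 2
  if (type == "distance") {
    diag(m) <- 0
    new("DistanceMatrix", m)
  } else {
    new("SimilarityMatrix", m)
  }
}

#' Write a distance/similarity matrix
#'
#' @param m a [DistanceMatrix-class] or [SimilarityMatrix-class].
#' @param path output path. With \code{format = "tsv"}, a square TSV with
#'   header IDs; with \code{format = "mdist"}, a headerless PLINK-style
#'   matrix plus \code{<path>.id}.
#' @param format \code{"tsv"} or \code{"mdist"}.
#' @return invisibly, the paths written.
#' @export
writeMatrix <- function(m, path, format = c("tsv", "mdist")) {
  format <- match.arg(format)
  vals <- m@.Data
  if (format == "tsv") {
    df <- data.frame(id = rownames(vals), vals, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  } else {
    write.table(vals, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    idPath <- paste0(path, ".id")
    write.table(data.frame(fid = rownames(vals), iid = rownames(vals)),
                idPath, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(c(path, idPath))
  }
}

#' Convert distances to similarities and back
#'
#' For allele-sharing distances in [0, 1], similarity is S = 1 - D
#' elementwise (and conversely D = 1 - S), so the two conversions are
#' mutual inverses.
#'
#' @param D a [DistanceMatrix-class] with entries in [0, 1].
#' @return a [SimilarityMatrix-class].
#' @export
toSimilarity <- function(D) {
  stopifnot(is(D, "DistanceMatrix"))
  v <- D@.Data
  if (any(v < 0 | v > 1))
    stop("distances outside [0, 1]; rescale (e.g. min-max) before converting")
  new("SimilarityMatrix", 1 - v)
}

#' @rdname toSimilarity
#' @param S a [SimilarityMatrix-class] with entries in [0, 1].
#' @export
toDistance <- function(S) {
  stopifnot(is(S, "SimilarityMatrix"))
  v <- S@.Data
  if (any(v < 0 | v > 1))
    stop("similarities outside [0, 1]; rescale (e.g. min-max) before converting")
  d <- 1 - v
  diag(d) <- 0
  new("DistanceMatrix", d)
}
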