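#' Principal component analysis of a similarity matrix
#'
#' Eigen-decomposition of the column-centred similarity (allele-sharing)
#' matrix: components are ordered by decreasing eigenvalue and signed so
#' that the largest-magnitude loading of each component is positive.
#'
#' @param S a [SimilarityMatrix-class] (symmetric).
#' @param nComponents number of components to keep (default all).
#' @return a [PcaResult-class].
#' @export
pcaOnSimilarity <- function(S, nComponents = NULL) {
  if (!is(S, "SimilarityMatrix")) {
    if (is.matrix(S) && nrow(S) == ncol(S) && max(abs(S - t(S))) <= 1e-8)
      S <- new("SimilarityMatrix", (S + t(S)) / 2)
    else stop("input must be a symmetric similarity matrix")
  }
  X <- S@.Data
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ev <- sv$d^2 / (n - 1)
  keep <- if (is.null(nComponents)) seq_len(min(n - 1L, length(ev)))
          else seq_len(min(nComponents, length(ev)))
  loadings <- sv$v[, keep, drop = FALSE]
  scores <- Xc %*% loadings
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", keep)
  new("PcaResult", scores = scores, eigenvalues = ev[keep],
      varianceFraction = (ev / sum(ev))[keep], loadings = loadings)
}

#' Horn's parallel analysis for the number of significant components
#'
#' Monte-Carlo component retention in the Glorfeld variant: each observed
#' eigenvalue is compared against the (1 - alpha) percentile of the
#' corresponding eigenvalue of null matrices obtained by permuting every
#' column of the input independently. Components are counted from the
#' first while the observed eigenvalue exceeds its null percentile and
#' counting stops at the first failure.
#'
#' @param S a [SimilarityMatrix-class] or symmetric matrix.
#' @param alpha significance level (default 0.01).
#' @param iterations number of Monte-Carlo permutations (default 10000).
#' @param seed RNG seed.
#' @return integer: number of significant components.
#' @export
hornParallel <- function(S, alpha = 0.01, iterations = 10000L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  X <- if (is(S, "SimilarityMatrix")) S@.Data else as.matrix(S)
  n <- nrow(X)
  eig <- function(M) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(Mc), symmetric = TRUE, only.values = TRUE)$values
    pmax(ev, 0) / (n - 1)
  }
  obs <- eig(X)
  set.seed(as.integer(seed))
  nullEv <- matrix(0, iterations, length(obs))
  perm <- X
  for (it in seq_len(iterations)) {
    for (j in seq_len(ncol(X))) perm[, j] <- X[sample.int(n), j]
    nullEv[it, ] <- eig(perm)
  }
  thresh <- apply(nullEv, 2, quantile, probs = 1 - alpha, names = FALSE)
  nSig <- 0L
  for (k in seq_along(obs)) {
    if (obs[k] > thresh[k]) nSig <- nSig + 1L else break
  }
  nSig
}

#' K selection by k-means and the Calinski-Harabasz criterion
#'
#' Runs k-means with multiple random restarts for every K in the range and
#' scores each clustering with the Calinski-Harabasz criterion
#' [B/(K-1)] / [W/(N-K)], the ratio of between- to within-cluster
#' dispersion; the best K maximizes the criterion.
#'
#' @param scores samples x components matrix (typically the significant
#'   PC scores).
#' @param kMin,kMax range of K (defaults 2 and 7).
#' @param restarts random restarts per K (default 10).
#' @param seed RNG seed.
#' @return list with \code{bestK}, \code{criterion} (named numeric per K)
#'   and \code{labels} (list of cluster assignments per K).
#' @export
kmeansCalinski <- function(scores, kMin = 2L, kMax = 7L, restarts = 10L,
                           seed = 1L) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  set.seed(as.integer(seed))
  ks <- seq(as.integer(kMin), as.integer(kMax))
  crit <- setNames(rep(NA_real_, length(ks)), ks)
  labels <- setNames(vector("list", length(ks)), ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    if (k >= n) {
      warning(sprintf("K = %d skipped: not below the number of samples (%d)", k, n))
      next
    }
    fit <- kmeans(scores, centers = k, nstart = restarts, iter.max = 100L)
    crit[i] <- calinskiHarabasz(fit$betweenss, fit$tot.withinss, n, k)
    lab <- fit$cluster
    names(lab) <- rownames(scores)
    labels[[i]] <- lab
  }
  bestK <- if (all(is.na(crit))) NA_integer_ else ks[which.max(crit)]
  list(bestK = bestK, criterion = crit, labels = labels)
}

#' Calinski-Harabasz criterion from sums of squares
#'
#' @param betweenSS between-cluster sum of squares.
#' @param withinSS total within-cluster sum of squares.
#' @param n number of samples.
#' @param k number of clusters.
#' @return the criterion value.
#' @export
calinskiHarabasz <- function(betweenSS, withinSS, n, k) {
  (betweenSS / (k - 1)) / (withinSS / (n - k))
}

#' Write PCA scores and cluster criteria as TSV
#'
#' @param pca a [PcaResult-class].
#' @param km result of [kmeansCalinski()] (optional).
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeBenchmark <- function(pca, km = NULL, prefix) {
  pScores <- paste0(prefix, "_pc_scores.tsv")
  write.table(data.frame(sample = rownames(pca@scores), pca@scores,
                         check.names = FALSE),
              pScores, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- pScores
  if (!is.null(km)) {
    pCrit <- paste0(prefix, "_calinski.tsv")
    write.table(data.frame(k = as.integer(names(km$criterion)),
                           calinski = unname(km$criterion)),
                pCrit, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, pCrit)
  }
  invisible(paths)
}
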