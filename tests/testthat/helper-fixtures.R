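# Shared fixtures and independent oracles, all generated in code.

# Tiny PED/MAP files on disk; returns the two paths.
writeTinyPlink <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(c(
    "F1 s1 0 0 0 -9 A A C C G T",
    "F1 s2 0 0 0 -9 A G C C T T",
    "F1 s3 0 0 0 -9 G G 0 0 G G",
    "F1 s4 0 0 0 -9 A G C C G T"), ped)
  writeLines(c(
    "1 snp1 0 100",
    "1 snp2 0 200",
    "2 snp3 0 300"), map)
  c(ped = ped, map = map)
}

# GenotypeDataset straight from a code matrix.
gd <- function(m, ids = sprintf("s%d", seq_len(nrow(m))),
               snps = sprintf("snp%d", seq_len(ncol(m))), pos = NULL) {
  dimnames(m) <- list(ids, snps)
  info <- data.frame(chrom = "1",
                     pos = if (is.null(pos)) seq_len(ncol(m)) * 100L else pos,
                     stringsAsFactors = FALSE)
  genotypeDataset(m, snpInfo = info)
}

# DistanceMatrix from a plain symmetric matrix.
dm <- function(m, ids = sprintf("s%d", seq_len(nrow(m)))) {
  dimnames(m) <- list(ids, ids)
  new("DistanceMatrix", m)
}

# KnnGraph built directly from an edge table (for engine-level tests).
toyGraph <- function(edges, ids = sort(unique(c(edges$from, edges$to))),
                     k = 1L) {
  edges$from2 <- pmin(edges$from, edges$to)
  edges$to2 <- pmax(edges$from, edges$to)
  e <- data.frame(from = edges$from2, to = edges$to2,
                  distance = edges$distance, stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), ]
  rownames(e) <- NULL
  new("KnnGraph", sampleIDs = ids, edges = e, k = as.integer(k),
      mutual = TRUE, neighbours = list())
}

toyCouplings <- function(J) new("Couplings", J = J, a = 1, meanDegree = 2)

# Exact Boltzmann enumeration for a q-state Potts model on a small graph:
# returns the exact expectation of the edge spin-coincidence indicators and
# of the magnetization m = (q N_max / N - 1)/(q - 1).
enumPotts <- function(n, edgeFrom, edgeTo, J, q, temperature) {
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), n)))
  H <- rep(0, nrow(states))
  for (e in seq_along(edgeFrom))
    H <- H + J[e] * (states[, edgeFrom[e]] != states[, edgeTo[e]])
  w <- exp(-H / temperature)
  w <- w / sum(w)
  delta <- vapply(seq_along(edgeFrom), function(e)
    sum(w * (states[, edgeFrom[e]] == states[, edgeTo[e]])), numeric(1))
  nMax <- apply(states, 1, function(s) max(tabulate(s, nbins = q)))
  m <- sum(w * (q * nMax / n - 1) / (q - 1))
  list(delta = delta, m = m)
}

# Replicated Monte-Carlo measurement: mean and standard error over
# independent seeds, for comparison against enumPotts.
replicateMeasure <- function(graph, couplings, temperature, q, nRep = 12L,
                             sweeps = 1500L, seed0 = 500L) {
  reps <- lapply(seq_len(nRep), function(r) {
    cfg <- spcConfig(q = q, burnInSweeps = 100L, measureSweeps = sweeps,
                     seed = seed0 + r)
    measureAtTemperature(graph, couplings, temperature, cfg)
  })
  deltas <- do.call(rbind, lapply(reps, `[[`, "delta"))
  ms <- vapply(reps, `[[`, numeric(1), "magnetization")
  list(delta = colMeans(deltas),
       deltaSE = apply(deltas, 2, stats::sd) / sqrt(nRep),
       m = mean(ms), mSE = stats::sd(ms) / sqrt(nRep))
}

# Hudson's pairwise F_ST (ratio of averages, sample-size corrected) from two
# genotype code matrices; independent of any package code path.
hudsonFst <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colMeans(g1, na.rm = TRUE) / 2
  p2 <- colMeans(g2, na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (2 * n1 - 1) - p2 * (1 - p2) / (2 * n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Genotype matrix with exact Hardy-Weinberg proportions at every SNP.
hweExactDataset <- function(nPerGeno = 25L, nSnps = 4L) {
  col <- rep(c(0L, 1L, 1L, 2L), each = nPerGeno)   # p = 0.5, exact 1:2:1
  gd(matrix(rep(col, nSnps), ncol = nSnps))
}
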