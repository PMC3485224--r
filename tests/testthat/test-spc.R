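test_that("couplings follow the Gaussian kernel of edge distances", {
  # two edges, distances 0 and 0.5: a = 0.25, mean degree = 2*2/3
  g <- toyGraph(data.frame(from = c("a", "b"), to = c("b", "c"),
                           distance = c(0, 0.5)))
  cp <- computeCouplings(g)
  kHat <- 2 * 2 / 3
  expect_equal(cp@a, 0.25)
  expect_equal(cp@J[1], 1 / kHat)                       # zero distance
  expect_equal(cp@J[2], exp(-0.5^2 / (2 * 0.25^2)) / kHat)
  # single edge with d = a gives J = exp(-1/2)/kHat
  g1 <- toyGraph(data.frame(from = "a", to = "b", distance = 0.4))
  cp1 <- computeCouplings(g1)
  expect_equal(cp1@J, exp(-0.5) / 1)

  # strictly decreasing in distance
  set.seed(61)
  d <- sort(runif(6, 0.1, 0.9))
  gm <- toyGraph(data.frame(from = sprintf("n%d", 1:6),
                            to = sprintf("n%d", c(2:6, 1)), distance = d))
  expect_true(all(diff(computeCouplings(gm)@J[order(gm@edges$distance)]) < 0))

  expect_error(computeCouplings(toyGraph(
    data.frame(from = "a", to = "b", distance = 0))), "zero")
})

test_that("Swendsen-Wang sweeps behave correctly in both temperature limits", {
  g <- toyGraph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                           distance = 0.2))
  cp <- computeCouplings(g)
  # T -> 0 from an aligned state: the whole graph is one frozen component
  set.seed(62)
  s <- swendsenWangSweep(rep(3L, 4), g, cp, temperature = 1e-9, q = 5)
  expect_identical(length(unique(s)), 1L)
  expect_true(all(s >= 1 & s <= 5))
  # T -> infinity: bonds never freeze, spins are redrawn independently
  set.seed(63)
  draws <- replicate(300, swendsenWangSweep(rep(1L, 4), g, cp,
                                            temperature = 1e12, q = 4))
  expect_true(all(draws >= 1 & draws <= 4))
  # each node's spin is approximately uniform
  freq <- table(factor(draws[1, ], levels = 1:4)) / 300
  expect_lt(max(abs(freq - 0.25)), 0.12)
  # and the four nodes are not locked together
  expect_gt(mean(apply(draws, 2, function(x) length(unique(x)))), 2)
})

test_that("Monte-Carlo equilibrium matches exact Boltzmann enumeration", {
  # 4-node path, q = 3, moderate couplings near the interesting regime
  ef <- c(1L, 2L, 3L); et <- c(2L, 3L, 4L)
  J <- c(1, 0.6, 1)
  g <- toyGraph(data.frame(from = c("n1", "n2", "n3"),
                           to = c("n2", "n3", "n4"), distance = 0.3))
  cp <- toyCouplings(J)
  for (Temp in c(0.5, 1.0)) {
    exact <- enumPotts(4, ef, et, J, q = 3, temperature = Temp)
    mc <- replicateMeasure(g, cp, Temp, q = 3, nRep = 12L, sweeps = 1500L,
                           seed0 = 700L + round(100 * Temp))
    expect_true(all(abs(mc$delta - exact$delta) <= 3 * mc$deltaSE + 1e-9),
                info = sprintf("delta at T=%.2f", Temp))
    expect_lt(abs(mc$m - exact$m), 3 * mc$mSE + 1e-9)
  }
})

test_that("two cliques joined by a weak edge correlate within, not across", {
  # two 4-cliques joined by one weak bond; exact enumeration cross-check
  cl1 <- t(combn(1:4, 2)); cl2 <- t(combn(5:8, 2))
  ef <- c(cl1[, 1], cl2[, 1], 4L); et <- c(cl1[, 2], cl2[, 2], 5L)
  J <- c(rep(1, 12), 0.15)
  ids <- sprintf("n%d", 1:8)
  g <- toyGraph(data.frame(from = ids[ef], to = ids[et], distance = 0.3))
  # toyGraph sorts edges; realign J to the sorted edge table
  key <- paste(pmin(ids[ef], ids[et]), pmax(ids[ef], ids[et]))
  J <- J[match(paste(g@edges$from, g@edges$to), key)]
  ef2 <- match(g@edges$from, ids); et2 <- match(g@edges$to, ids)
  Temp <- 0.8
  exact <- enumPotts(8, ef2, et2, J, q = 3, temperature = Temp)
  cross <- which(J < 0.5)
  expect_gt(min(exact$delta[-cross]), exact$delta[cross])
  mc <- replicateMeasure(g, toyCouplings(J), Temp, q = 3, nRep = 8L,
                         sweeps = 1200L, seed0 = 900L)
  expect_true(all(abs(mc$delta - exact$delta) <= 3 * mc$deltaSE + 1e-9))
  G <- (3 * mc$delta - 1) / 2
  expect_gt(min(G[-cross]), G[cross])
})

test_that("cluster extraction follows thresholded correlations plus capture", {
  ids <- sprintf("s%d", 1:5)
  g <- toyGraph(data.frame(from = ids[1:4], to = ids[2:5], distance = 0.3))
  rec <- list(G = c(.9, .9, .2, .9))   # edges sorted: (1,2),(2,3),(3,4),(4,5)
  part <- extractClusters(rec, g, theta = 0.5, minClusterSize = 2L)
  expect_identical(max(part), 2L)
  expect_identical(unname(part[c("s1", "s2", "s3")]), rep(1L, 3))
  expect_identical(unname(part[c("s4", "s5")]), rep(2L, 2))

  partAll <- extractClusters(list(G = rep(1, 4)), g)
  expect_identical(max(partAll), 1L)
  partNone <- extractClusters(list(G = rep(0, 4)), g)
  expect_identical(max(partNone), 5L)
  expect_false(any(attr(partNone, "clustered")))
})

test_that("high-temperature limit: vanishing correlations, singleton partition", {
  g <- toyGraph(data.frame(from = c("a", "b", "c", "a"),
                           to = c("b", "c", "d", "d"), distance = 0.25))
  cp <- computeCouplings(g)
  cfg <- spcConfig(q = 10L, burnInSweeps = 100L, measureSweeps = 2000L, seed = 71L)
  rec <- measureAtTemperature(g, cp, temperature = 1e6, config = cfg)
  expect_lt(max(rec$G), 0.15)
  expect_identical(max(rec$partition), 4L)
  expect_gte(rec$susceptibility, 0)

  recLow <- measureAtTemperature(g, cp, temperature = 1e-6, config = cfg)
  expect_equal(min(recLow$G), 1)
  expect_identical(max(recLow$partition), 1L)
  expect_gt(recLow$magnetization, 0.99)
})

test_that("paramagnetic susceptibility matches the independent-spins value", {
  g <- toyGraph(data.frame(from = c("a", "b", "c", "d"),
                           to = c("b", "c", "d", "e"), distance = 0.3))
  cp <- computeCouplings(g)
  q <- 6L; n <- 5L
  cfg <- spcConfig(q = q, burnInSweeps = 100L, measureSweeps = 8000L,
                   seed = 91L)
  Temp <- 1e4   # far above the transition: spins effectively independent
  rec <- measureAtTemperature(g, cp, Temp, cfg)
  # oracle: variance of m for iid uniform spins, by direct simulation
  set.seed(92)
  mIid <- replicate(20000, {
    nMax <- max(tabulate(sample.int(q, n, replace = TRUE), nbins = q))
    (q * nMax / n - 1) / (q - 1)
  })
  chiIid <- n / Temp * var(mIid)
  expect_equal(rec$susceptibility, chiIid, tolerance = 0.15)
  expect_equal(rec$magnetization, mean(mIid), tolerance = 0.02)
})

test_that("five strongly drifted populations are recovered across seeds", {
  hits <- 0L
  for (s in 1:10) {
    spec <- popTreeSpec(
      data.frame(node = paste0("P", 1:5), parent = "ROOT", f = 0.25),
      samplesPerLeaf = setNames(rep(12L, 5), paste0("P", 1:5)), nSnps = 400L)
    sim <- simulateGenotypes(spec, seed = 300 + s)
    D <- asdMatrix(sim$dataset)
    g <- buildKnnGraph(D, k = 5)
    res <- runSpc(D, g, spcConfig(seed = 400 + s, burnInSweeps = 100L,
                                  measureSweeps = 400L))
    p <- partition(res)
    if (max(p) == 5L && isTRUE(all.equal(ariScore(sim$labels, p), 1)))
      hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("SPC recovers two well-separated simulated populations", {
  spec <- popTreeSpec(
    data.frame(node = c("P1", "P2"), parent = "ROOT", f = 0.3),
    samplesPerLeaf = c(P1 = 14L, P2 = 14L), nSnps = 400L)
  sim <- simulateGenotypes(spec, seed = 81)
  D <- asdMatrix(sim$dataset)
  g <- buildKnnGraph(D, k = 5)
  res <- runSpc(D, g, spcConfig(seed = 82L, burnInSweeps = 100L,
                                measureSweeps = 400L))
  p <- partition(res)
  expect_identical(max(p), 2L)
  expect_equal(ariScore(sim$labels, p), 1)
  # susceptibility non-negative across the whole gradient
  expect_true(all(susceptibilityTrace(res)$susceptibility >= 0))
  # tree is a valid nested hierarchy with the root covering all samples
  expect_true(validObject(clusterTree(res)))
  cs <- clusterStability(clusterTree(res))
  expect_true(all(cs$cs >= 0))
  # the two populations appear as child clusters of the root
  kids <- cs[cs$parent == 1L, ]
  expect_gte(nrow(kids), 2L)
})

test_that("a single panmictic population stays one stable cluster", {
  spec <- popTreeSpec(data.frame(node = "P1", parent = "ROOT", f = 0),
                      samplesPerLeaf = c(P1 = 20L), nSnps = 300L)
  sim <- simulateGenotypes(spec, seed = 83)
  D <- asdMatrix(sim$dataset)
  g <- buildKnnGraph(D, k = 5)
  res <- runSpc(D, g, spcConfig(seed = 84L, burnInSweeps = 100L,
                                measureSweeps = 400L))
  expect_identical(max(partition(res)), 1L)
})

test_that("identical seed and config give bit-identical results", {
  spec <- popTreeSpec(
    data.frame(node = c("P1", "P2"), parent = "ROOT", f = 0.25),
    samplesPerLeaf = c(P1 = 10L, P2 = 10L), nSnps = 250L)
  sim <- simulateGenotypes(spec, seed = 85)
  D <- asdMatrix(sim$dataset)
  g <- buildKnnGraph(D, k = 4)
  cfg <- spcConfig(seed = 86L, burnInSweeps = 80L, measureSweeps = 300L)
  r1 <- runSpc(D, g, cfg)
  r2 <- runSpc(D, g, cfg)
  expect_identical(r1@partition, r2@partition)
  expect_identical(r1@temperatures, r2@temperatures)
  expect_identical(lapply(r1@records, `[[`, "G"),
                   lapply(r2@records, `[[`, "G"))
  expect_identical(clusterStability(r1@tree), clusterStability(r2@tree))
})

test_that("reordered distance matrix is a permutation with block structure", {
  spec <- popTreeSpec(
    data.frame(node = c("P1", "P2"), parent = "ROOT", f = 0.3),
    samplesPerLeaf = c(P1 = 12L, P2 = 12L), nSnps = 300L)
  sim <- simulateGenotypes(spec, seed = 87)
  D <- asdMatrix(sim$dataset)
  g <- buildKnnGraph(D, k = 5)
  res <- runSpc(D, g, spcConfig(seed = 88L, burnInSweeps = 80L,
                                measureSweeps = 300L))
  perm <- res@permutation
  expect_identical(sort(perm), seq_len(24L))
  ro <- res@reorderedDistance
  expect_equal(sort(as.vector(ro)), sort(as.vector(D@.Data)))
  # blocks of the optimal partition are contiguous and tighter than between
  p <- partition(res)[rownames(ro)]
  expect_identical(unname(rle(as.integer(p))$lengths),
                   unname(sort(tabulate(p), decreasing = TRUE)))
  b1 <- rownames(ro)[p == 1]; b2 <- rownames(ro)[p == 2]
  expect_lt(mean(ro[b1, b1]), mean(ro[b1, b2]))
})

test_that("temperature records nest into a tree (no cluster maps to two parents)", {
  spec <- popTreeSpec(
    data.frame(node = c("P1", "P2", "P3"), parent = "ROOT", f = c(0.3, 0.3, 0.35)),
    samplesPerLeaf = c(P1 = 8L, P2 = 8L, P3 = 8L), nSnps = 300L)
  sim <- simulateGenotypes(spec, seed = 89)
  D <- asdMatrix(sim$dataset)
  g <- buildKnnGraph(D, k = 4)
  res <- runSpc(D, g, spcConfig(seed = 90L, burnInSweeps = 80L,
                                measureSweeps = 300L))
  tree <- clusterTree(res)
  expect_true(validObject(tree))
  # every non-root node has exactly one parent and is a subset of it
  for (nd in tree@nodes[-1]) {
    expect_identical(length(nd$parent), 1L)
    expect_true(all(nd$members %in% tree@nodes[[nd$parent]]$members))
    expect_gte(nd$death, nd$birth)
  }
})
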