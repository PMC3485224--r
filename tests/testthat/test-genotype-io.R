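test_that("PLINK text parsing codes the lexicographically later allele", {
  p <- writeTinyPlink()
  ds <- readPlinkText(p["ped"], p["map"])
  expect_s4_class(ds, "GenotypeDataset")
  expect_identical(sampleIDs(ds), c("s1", "s2", "s3", "s4"))
  expect_identical(snpIDs(ds), c("snp1", "snp2", "snp3"))
  g <- genotypes(ds)
  # snp1 alleles {A, G}: counted allele G
  expect_identical(unname(g[, "snp1"]), c(0L, 1L, 2L, 1L))
  # snp2 is monomorphic C except the missing call in s3
  expect_identical(unname(g[, "snp2"]), c(2L, 2L, NA, 2L))
  expect_identical(unname(g[, "snp3"]), c(1L, 2L, 0L, 1L))
  expect_identical(snpInfo(ds)$allele2, c("G", "C", "T"))
  expect_identical(snpInfo(ds)$pos, c(100L, 200L, 300L))
})

test_that("single-record file and missing genotype conventions", {
  dir <- withr::local_tempdir()
  writeLines("F1 only 0 0 0 -9 A A", file.path(dir, "one.ped"))
  writeLines("1 s 0 5", file.path(dir, "one.map"))
  ds <- readPlinkText(file.path(dir, "one.ped"), file.path(dir, "one.map"))
  expect_identical(unname(genotypes(ds)[1, 1]), 2L)
  expect_false(anyNA(genotypes(ds)))

  writeLines("F1 only 0 0 0 -9 0 0", file.path(dir, "one.ped"))
  ds <- readPlinkText(file.path(dir, "one.ped"), file.path(dir, "one.map"))
  expect_true(is.na(genotypes(ds)[1, 1]))
})

test_that("malformed PED input fails with informative errors", {
  dir <- withr::local_tempdir()
  writeLines(c("F1 s1 0 0 0 -9 A A C C",
               "F1 s2 0 0 0 -9 A A"), file.path(dir, "bad.ped"))
  writeLines(c("1 snp1 0 1", "1 snp2 0 2"), file.path(dir, "bad.map"))
  expect_error(readPlinkText(file.path(dir, "bad.ped"), file.path(dir, "bad.map")),
               "line 2")
  writeLines(c("F1 s1 0 0 0 -9 A A",
               "F1 s2 0 0 0 -9 C C",
               "F1 s3 0 0 0 -9 G G"), file.path(dir, "tri.ped"))
  writeLines("1 snpX 0 1", file.path(dir, "tri.map"))
  expect_error(readPlinkText(file.path(dir, "tri.ped"), file.path(dir, "tri.map")),
               "snpX")
})

test_that("PED/MAP round-trip preserves the genotype matrix", {
  # every column carries both alleles, so the deterministic coding
  # (count of the lexicographically later observed allele) round-trips
  m <- rbind(c(0L, 1L, 2L),
             c(1L, NA, 0L),
             c(2L, 2L, 1L),
             c(0L, 1L, NA))
  ds <- gd(m)
  dir <- withr::local_tempdir()
  writePlinkText(ds, file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  ds2 <- readPlinkText(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  # coding is deterministic (count of lexicographically later allele), but a
  # column written from codes k may read back as 2-k when the written allele
  # labels reverse the order; writePlinkText uses A(first)/B(counted), so
  # codes are preserved exactly.
  expect_identical(unname(genotypes(ds2)), unname(genotypes(ds)))
  expect_identical(sampleIDs(ds2), sampleIDs(ds))
})

test_that("exact HWE test matches enumeration and is symmetric", {
  expect_equal(hweExactP(7, 0, 0), 1)
  expect_equal(hweExactP(0, 2, 0), 1)   # both feasible het counts are <= observed prob
  # full enumeration over feasible heterozygote counts for (5, 0, 5):
  # P(h) for h = 0,2,...,10 gives two-sided p = P(h = 0) = 0.00136396
  expect_equal(hweExactP(5, 0, 5), 0.001363961, tolerance = 1e-6)

  # Monte-Carlo allele-shuffling oracle: draw genotype tables conditional on
  # the allele counts by random pairing and compare tail probabilities.
  mcHwe <- function(nAA, nAa, naa, reps = 40000L) {
    n <- nAA + nAa + naa
    alleles <- rep(c(1L, 0L), c(2 * nAA + nAa, 2 * naa + nAa))
    hets <- replicate(reps, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    pObs <- mean(hets == nAa)
    tab <- table(hets) / reps
    sum(tab[tab <= pObs * (1 + 1e-9)])
  }
  set.seed(21)
  expect_equal(hweExactP(3, 4, 3), mcHwe(3, 4, 3), tolerance = 0.02)
  expect_equal(hweExactP(6, 2, 2), mcHwe(6, 2, 2), tolerance = 0.05)

  # invariance to swapping the homozygote classes
  for (cc in list(c(5, 3, 2), c(1, 8, 1), c(0, 3, 7), c(4, 0, 4))) {
    expect_equal(hweExactP(cc[1], cc[2], cc[3]), hweExactP(cc[3], cc[2], cc[1]))
  }
})

test_that("QC removes low-MAF and HWE-failing SNPs with tagged reasons", {
  base <- hweExactDataset(nPerGeno = 25L, nSnps = 2L)   # 100 samples, clean
  g <- genotypes(base)
  # one SNP at MAF 0.005 (1 copy in 200 alleles), one extreme HWE failure
  g <- cbind(g, lowmaf = c(1L, rep(0L, 99L)),
             hwebad = rep(c(0L, 2L), 50L))
  ds <- gd(g, snps = colnames(g))
  res <- qcFilter(ds, removeDuplicates = FALSE)
  expect_setequal(res$report@removedSnps$id, c("lowmaf", "hwebad"))
  expect_identical(
    res$report@removedSnps$reason[res$report@removedSnps$id == "lowmaf"],
    "low_maf")
  expect_identical(
    res$report@removedSnps$reason[res$report@removedSnps$id == "hwebad"],
    "hwe_fail")
  expect_identical(snpIDs(res$dataset), c("snp1", "snp2"))
  expect_identical(nrow(res$report@removedSamples), 0L)
})

test_that("clean data in exact HWE proportions passes QC untouched", {
  ds <- hweExactDataset()
  res <- qcFilter(ds, removeDuplicates = FALSE)
  expect_identical(genotypes(res$dataset), genotypes(ds))
  expect_identical(nrow(res$report@removedSnps), 0L)
})

test_that("QC is idempotent and leaves call rates above threshold", {
  set.seed(31)
  g <- matrix(rbinom(60 * 40, 2, 0.35), 60, 40)
  g[sample(length(g), 350)] <- NA          # scattered missingness
  g[1:3, sample(40, 30)] <- NA             # three bad samples
  g[, 1] <- c(rep(NA_integer_, 30), rep(1L, 30))   # bad SNP call rate
  ds <- gd(g)
  res1 <- qcFilter(ds, removeDuplicates = FALSE)
  res2 <- qcFilter(res1$dataset, removeDuplicates = FALSE)
  expect_identical(genotypes(res2$dataset), genotypes(res1$dataset))
  expect_identical(nrow(res2$report@removedSnps), 0L)
  expect_identical(nrow(res2$report@removedSamples), 0L)
  g1 <- genotypes(res1$dataset)
  expect_true(all(colMeans(!is.na(g1)) >= 0.9))
  expect_true(all(rowMeans(!is.na(g1)) >= 0.9))
  # report dims consistent
  expect_identical(res1$report@dims, c(60L, 40L, dim(g1)))
})

test_that("QC erroring on empty output rather than silence", {
  ds <- gd(matrix(c(0L, 0L, 0L, 0L), 2, 2))   # monomorphic, MAF 0
  expect_error(qcFilter(ds, removeDuplicates = FALSE), "no SNPs left")
})

test_that("duplicate detection by mean IBS", {
  m <- matrix(rbinom(5 * 100, 2, 0.5), 5, 100)
  m[2, ] <- m[1, ]                    # exact duplicate pair
  m[4, ] <- 2L - m[3, ]               # opposite homozygotes where hom
  ds <- gd(m)
  hits <- findDuplicates(ds, ibsThreshold = 1)
  expect_identical(hits$id1, "s1")
  expect_identical(hits$id2, "s2")

  # two rows sharing 99 SNPs exactly plus one one-allele difference
  a <- rbinom(100, 2, 0.5)
  b <- a
  b[100] <- a[100] + if (a[100] < 2) 1L else -1L
  ds2 <- gd(rbind(a, b), ids = c("x1", "x2"))
  hits2 <- findDuplicates(ds2, ibsThreshold = 0.99)
  expect_identical(nrow(hits2), 1L)
  expect_equal(hits2$ibs, 0.995)

  # fully opposite homozygotes are never duplicates
  ds3 <- gd(rbind(rep(0L, 50), rep(2L, 50)), ids = c("y1", "y2"))
  expect_identical(nrow(findDuplicates(ds3, ibsThreshold = 0)), 1L)
  expect_identical(nrow(findDuplicates(ds3, ibsThreshold = 0.01)), 0L)

  # QC drops the later member of a duplicate pair
  res <- qcFilter(gd(m), removeDuplicates = TRUE)
  expect_true("s2" %in% res$report@removedSamples$id)
  expect_false("s1" %in% res$report@removedSamples$id)
})
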