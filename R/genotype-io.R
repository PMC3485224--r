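#' Construct a GenotypeDataset
#'
#' @param genotypes matrix of codes 0/1/2/NA; rownames sample IDs, colnames
#'   SNP IDs (supplied via \code{sampleIDs}/\code{snpIDs} if absent).
#' @param snpInfo optional data.frame with columns \code{chrom}, \code{pos}
#'   (and optionally \code{allele1}, \code{allele2}); defaults to unknown
#'   positions.
#' @param sampleIDs,snpIDs identifiers used when \code{genotypes} has no
#'   dimnames.
#' @return a [GenotypeDataset-class].
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("snp1", "snp2")))
#' genotypeDataset(g)
#' @export
genotypeDataset <- function(genotypes, snpInfo = NULL, sampleIDs = NULL,
                            snpIDs = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (!is.null(sampleIDs)) rownames(genotypes) <- sampleIDs
  if (!is.null(snpIDs)) colnames(genotypes) <- snpIDs
  if (is.null(snpInfo)) {
    snpInfo <- data.frame(chrom = rep("0", ncol(genotypes)),
                          pos = rep(NA_integer_, ncol(genotypes)),
                          allele1 = NA_character_, allele2 = NA_character_,
                          row.names = colnames(genotypes),
                          stringsAsFactors = FALSE)
  } else {
    if (is.null(snpInfo$allele1)) snpInfo$allele1 <- NA_character_
    if (is.null(snpInfo$allele2)) snpInfo$allele2 <- NA_character_
    rownames(snpInfo) <- colnames(genotypes)
  }
  new("GenotypeDataset", genotypes = genotypes, snpInfo = snpInfo)
}

#' Read PLINK text genotypes (PED/MAP)
#'
#' Parses whitespace-delimited PLINK PED/MAP files. Genotypes are coded as
#' the number of copies of the lexicographically later of the two alleles
#' observed at each SNP, a deterministic coding that makes downstream
#' distances reproducible regardless of file order. The PLINK missing
#' allele \code{"0"} gives a missing genotype.
#'
#' @param pedPath path to the PED file (6 leading columns, then two allele
#'   columns per SNP).
#' @param mapPath path to the MAP file (chromosome, SNP ID, genetic
#'   distance, base-pair position).
#' @return a [GenotypeDataset-class].
#' @seealso [writePlinkText()]
#' @export
readPlinkText <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, colClasses = "character",
                    col.names = c("chrom", "snp", "cm", "pos"))
  if (anyDuplicated(map$snp))
    stop("duplicate SNP IDs in MAP file: ",
         paste(unique(map$snp[duplicated(map$snp)]), collapse = ", "))
  nsnp <- nrow(map)
  lines <- readLines(pedPath)
  lines <- lines[nzchar(trimws(lines))]
  nsamp <- length(lines)
  if (!nsamp) stop("PED file is empty: ", pedPath)
  a1 <- matrix("0", nsamp, nsnp)
  a2 <- matrix("0", nsamp, nsnp)
  ids <- character(nsamp)
  fids <- character(nsamp)
  for (i in seq_len(nsamp)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * nsnp)
      stop(sprintf(
        "PED line %d has %d genotype columns; expected %d (2 per MAP SNP)",
        i, length(f) - 6L, 2L * nsnp))
    fids[i] <- f[1]
    ids[i] <- f[2]
    g <- f[-(1:6)]
    a1[i, ] <- g[c(TRUE, FALSE)]
    a2[i, ] <- g[c(FALSE, TRUE)]
  }
  if (anyDuplicated(ids)) ids <- paste(fids, ids, sep = "_")
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in PED file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  codes <- matrix(NA_integer_, nsamp, nsnp, dimnames = list(ids, map$snp))
  allele1 <- allele2 <- rep(NA_character_, nsnp)
  for (j in seq_len(nsnp)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2L)
      stop(sprintf("SNP %s has more than two alleles: %s",
                   map$snp[j], paste(obs, collapse = ", ")))
    if (length(obs) == 0L) next
    counted <- obs[length(obs)]            # lexicographically later allele
    allele2[j] <- counted
    allele1[j] <- obs[1L]
    codes[, j] <- (x1 == counted) + (x2 == counted)
    codes[miss, j] <- NA_integer_
  }
  pos <- suppressWarnings(as.integer(map$pos))
  genotypeDataset(codes,
                  snpInfo = data.frame(chrom = map$chrom, pos = pos,
                                       allele1 = allele1, allele2 = allele2,
                                       stringsAsFactors = FALSE))
}

#' Write PLINK text genotypes (PED/MAP)
#'
#' @param ds a [GenotypeDataset-class].
#' @param pedPath,mapPath output paths.
#' @param labels optional named vector of phenotype/population labels
#'   written to the PED family-ID column.
#' @return invisibly, the two paths.
#' @export
writePlinkText <- function(ds, pedPath, mapPath, labels = NULL) {
  info <- ds@snpInfo
  a1 <- ifelse(is.na(info$allele1), "A", info$allele1)
  a2 <- ifelse(is.na(info$allele2), "B", info$allele2)
  # monomorphic SNPs observed only for the counted allele
  a1[!is.na(info$allele2) & is.na(info$allele1)] <-
    a2[!is.na(info$allele2) & is.na(info$allele1)]
  map <- data.frame(chrom = info$chrom, snp = snpIDs(ds), cm = 0,
                    pos = ifelse(is.na(info$pos), 0L, info$pos))
  write.table(map, mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  g <- ds@genotypes
  ids <- rownames(g)
  fam <- if (is.null(labels)) ids else as.character(labels[ids])
  con <- file(pedPath, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1L, a2, a1))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi == 2L, a2, a1))
    writeLines(paste(c(fam[i], ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(x1, x2))), collapse = " "), con)
  }
  invisible(c(ped = pedPath, map = mapPath))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration. Monomorphic SNPs return 1.
#'
#' @param nAA,nAa,naa non-negative genotype counts.
#' @return the exact p-value.
#' @examples
#' hweExactP(5, 0, 5)   # extreme heterozygote deficit
#' @export
hweExactP <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0L) return(1)
  nm <- min(2 * nAA + nAa, 2 * naa + nAa)   # minor allele count
  if (nm == 0L) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  # P(het = h | n, nm) up to a constant, on the log scale
  logp <- vapply(hets, function(h) {
    nmin_hom <- (nm - h) / 2
    nmaj_hom <- n - h - nmin_hom
    if (nmaj_hom < 0) return(-Inf)
    h * log(2) - lfactorial(nmin_hom) - lfactorial(h) - lfactorial(nmaj_hom)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(nAa, hets)]
  sum(p[p <= obs * (1 + 1e-9)])
}

#' Detect duplicate samples by genotype similarity
#'
#' Compares all sample pairs by mean identity-by-state proportion over
#' pairwise-complete SNPs and reports pairs at or above the threshold.
#' Pairs with no overlapping non-missing SNPs are excluded with a warning.
#'
#' @param ds a [GenotypeDataset-class] with at least two samples.
#' @param ibsThreshold minimum mean IBS proportion (default 0.99).
#' @return data.frame with columns \code{id1}, \code{id2}, \code{ibs};
#'   zero rows when no pair qualifies.
#' @export
findDuplicates <- function(ds, ibsThreshold = 0.99) {
  g <- ds@genotypes
  if (nrow(g) < 2L) stop("need at least two samples")
  ov <- pairwiseAbsDiff(g)
  zero <- which(ov$overlap == 0 & upper.tri(ov$overlap), arr.ind = TRUE)
  if (nrow(zero))
    warning("pairs with no overlapping genotyped SNPs excluded: ",
            paste(rownames(g)[zero[, 1]], rownames(g)[zero[, 2]],
                  sep = "/", collapse = ", "))
  ibs <- 1 - ov$sumAbsDiff / (2 * ov$overlap)   # NaN where overlap == 0
  hits <- which(ibs >= ibsThreshold & upper.tri(ibs), arr.ind = TRUE)
  out <- data.frame(id1 = rownames(g)[hits[, 1]],
                    id2 = rownames(g)[hits[, 2]],
                    ibs = ibs[hits], stringsAsFactors = FALSE)
  out[order(out$id1, out$id2), , drop = FALSE]
}

#' Quality-control filtering of a genotype dataset
#'
#' Applies the standard SNP-chip editing filters in a fixed order: SNPs
#' without known positions (optional), samples with low call rate,
#' duplicate samples (optional), SNPs with low call rate, low minor allele
#' frequency, and departure from Hardy-Weinberg equilibrium by the exact
#' test. Sample-level filters run first because removing samples changes
#' every per-SNP statistic.
#'
#' @param ds a [GenotypeDataset-class].
#' @param minCallRate minimum call rate for SNPs and samples (default 0.9).
#' @param minMaf minimum minor allele frequency (default 0.01).
#' @param hweAlpha HWE exact-test significance threshold (default 0.001).
#' @param requirePosition drop SNPs without a known map position
#'   (default TRUE).
#' @param removeDuplicates drop the later member of each duplicate pair
#'   (default TRUE).
#' @param dupThreshold mean-IBS threshold declaring duplicates
#'   (default 0.99).
#' @return list with elements \code{dataset} (the filtered
#'   [GenotypeDataset-class]) and \code{report} (a [QcReport-class]).
#' @export
qcFilter <- function(ds, minCallRate = 0.9, minMaf = 0.01, hweAlpha = 0.001,
                     requirePosition = TRUE, removeDuplicates = TRUE,
                     dupThreshold = 0.99) {
  g <- ds@genotypes
  dims0 <- dim(g)
  removedSnps <- data.frame(id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  removedSamples <- data.frame(id = character(), reason = character(),
                               stringsAsFactors = FALSE)
  info <- ds@snpInfo

  if (requirePosition) {
    bad <- is.na(info$pos) | info$pos <= 0L
    if (any(bad)) {
      removedSnps <- rbind(removedSnps,
                           data.frame(id = colnames(g)[bad],
                                      reason = "no_position"))
      g <- g[, !bad, drop = FALSE]
      info <- info[!bad, , drop = FALSE]
    }
  }

  sampleCall <- rowMeans(!is.na(g))
  bad <- sampleCall < minCallRate
  if (any(bad)) {
    removedSamples <- rbind(removedSamples,
                            data.frame(id = rownames(g)[bad],
                                       reason = "low_call_rate"))
    g <- g[!bad, , drop = FALSE]
  }
  if (!nrow(g)) stop("no samples left after call-rate filtering")

  if (removeDuplicates && nrow(g) >= 2L) {
    dups <- findDuplicates(
      genotypeDataset(g, snpInfo = info), ibsThreshold = dupThreshold)
    if (nrow(dups)) {
      # drop the later-in-file member of each pair
      later <- ifelse(match(dups$id1, rownames(g)) > match(dups$id2, rownames(g)),
                      dups$id1, dups$id2)
      later <- unique(later)
      removedSamples <- rbind(removedSamples,
                              data.frame(id = later, reason = "duplicate"))
      g <- g[!(rownames(g) %in% later), , drop = FALSE]
    }
  }

  snpCall <- colMeans(!is.na(g))
  bad <- snpCall < minCallRate
  if (any(bad)) {
    removedSnps <- rbind(removedSnps,
                         data.frame(id = colnames(g)[bad],
                                    reason = "low_call_rate"))
    g <- g[, !bad, drop = FALSE]
    info <- info[!bad, , drop = FALSE]
  }

  freq <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  maf[is.nan(maf)] <- 0
  bad <- maf < minMaf
  if (any(bad)) {
    removedSnps <- rbind(removedSnps,
                         data.frame(id = colnames(g)[bad], reason = "low_maf"))
    g <- g[, !bad, drop = FALSE]
    info <- info[!bad, , drop = FALSE]
  }

  if (ncol(g)) {
    hweP <- vapply(seq_len(ncol(g)), function(j) {
      gj <- g[, j]
      hweExactP(sum(gj == 2L, na.rm = TRUE), sum(gj == 1L, na.rm = TRUE),
                sum(gj == 0L, na.rm = TRUE))
    }, numeric(1))
    bad <- hweP < hweAlpha
    if (any(bad)) {
      removedSnps <- rbind(removedSnps,
                           data.frame(id = colnames(g)[bad],
                                      reason = "hwe_fail"))
      g <- g[, !bad, drop = FALSE]
      info <- info[!bad, , drop = FALSE]
    }
  }

  if (!ncol(g)) stop("no SNPs left after quality-control filtering")

  out <- genotypeDataset(g, snpInfo = info)
  report <- new("QcReport", removedSnps = removedSnps,
                removedSamples = removedSamples,
                thresholds = list(minCallRate = minCallRate, minMaf = minMaf,
                                  hweAlpha = hweAlpha,
                                  requirePosition = requirePosition,
                                  removeDuplicates = removeDuplicates,
                                  dupThreshold = dupThreshold),
                dims = as.integer(c(dims0, dim(g))))
  list(dataset = out, report = report)
}

#' Write a QC report as TSV plus a JSON summary
#'
#' @param report a [QcReport-class].
#' @param prefix output path prefix; writes
#'   \code{<prefix>_removed_snps.tsv}, \code{<prefix>_removed_samples.tsv}
#'   and \code{<prefix>_summary.json}.
#' @return invisibly, the paths written.
#' @export
writeQcReport <- function(report, prefix) {
  pSnp <- paste0(prefix, "_removed_snps.tsv")
  pSam <- paste0(prefix, "_removed_samples.tsv")
  pJson <- paste0(prefix, "_summary.json")
  write.table(report@removedSnps, pSnp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report@removedSamples, pSam, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(thresholds = report@thresholds,
         samplesBefore = report@dims[1], snpsBefore = report@dims[2],
         samplesAfter = report@dims[3], snpsAfter = report@dims[4],
         removedSnpReasons = as.list(table(report@removedSnps$reason)),
         removedSampleReasons = as.list(table(report@removedSamples$reason))),
    pJson, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(pSnp, pSam, pJson))
}

# Sum of |g_i - g_j| and pairwise-complete overlap counts for all sample
# pairs, via indicator cross-products (codes 0/1/2; NA = missing).
pairwiseAbsDiff <- function(g) {
  i0 <- (!is.na(g) & g == 0L) + 0
  i1 <- (!is.na(g) & g == 1L) + 0
  i2 <- (!is.na(g) & g == 2L) + 0
  sumAbsDiff <- 2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0)) +
    tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1)
  overlap <- tcrossprod(i0 + i1 + i2)
  list(sumAbsDiff = sumAbsDiff, overlap = overlap)
}
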