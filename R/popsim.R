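#' Specify a hierarchical population scenario
#'
#' Builds a [PopTreeSpec-class] from a branch table. Per branch the drift
#' away from the parental allele frequencies is F = 1 - exp(-t / (2 Ne))
#' for a branch of t generations at effective size Ne; a precomputed
#' \code{f} column may be given instead of \code{generations}/\code{ne}.
#'
#' @param branches data.frame with columns \code{node}, \code{parent} and
#'   either \code{f} or both \code{generations} and \code{ne}.
#' @param samplesPerLeaf named integer vector of samples per leaf
#'   population.
#' @param nSnps number of SNPs.
#' @param ancestralRange range the per-SNP ancestral allele frequency is
#'   drawn from (default c(0.1, 0.9), keeping markers common enough to be
#'   informative, as on a genotyping array).
#' @return a [PopTreeSpec-class].
#' @export
popTreeSpec <- function(branches, samplesPerLeaf, nSnps = 5000L,
                        ancestralRange = c(0.1, 0.9)) {
  if (is.null(branches$f)) {
    if (is.null(branches$generations) || is.null(branches$ne))
      stop("branches need either 'f' or both 'generations' and 'ne'")
    branches$f <- 1 - exp(-branches$generations / (2 * branches$ne))
  }
  spl <- samplesPerLeaf
  storage.mode(spl) <- "integer"
  new("PopTreeSpec",
      branches = branches[, c("node", "parent", "f")],
      samplesPerLeaf = spl, nSnps = as.integer(nSnps),
      ancestralRange = as.numeric(ancestralRange))
}

#' Five-population scenario with two nested sub-splits
#'
#' An ancestral population splits into three (PopA, PopB, PopC) 3000 years
#' ago; PopA further splits into PopA1/PopA2 2000 years ago and PopB into
#' PopB1/PopB2 1000 years ago, at 26 years per generation and constant
#' effective size Ne = 3100 on every branch. Divergence is expressed as
#' per-branch Balding-Nichols drift F = 1 - exp(-t / (2 Ne)).
#'
#' @param samplesPerPop samples per leaf population: a single number
#'   (default 80) or a named vector over PopA1, PopA2, PopB1, PopB2, PopC
#'   (e.g. the heterogeneous collection
#'   \code{c(PopA1 = 80, PopA2 = 40, PopB1 = 20, PopB2 = 10, PopC = 5)}).
#' @param nSnps number of SNPs (default 5000).
#' @param ne effective population size on every branch (default 3100).
#' @param generationYears years per generation (default 26).
#' @return a [PopTreeSpec-class].
#' @export
fivePopPreset <- function(samplesPerPop = 80L, nSnps = 5000L, ne = 3100,
                        generationYears = 26) {
  if (nSnps < 1L) stop("nSnps must be positive")
  gen <- function(years) years / generationYears
  branches <- data.frame(
    node   = c("PopA",  "PopB",  "PopC",  "PopA1", "PopA2", "PopB1", "PopB2"),
    parent = c("ROOT",  "ROOT",  "ROOT",  "PopA",  "PopA",  "PopB",  "PopB"),
    generations = gen(c(1000, 2000, 3000, 2000, 2000, 1000, 1000)),
    ne = ne, stringsAsFactors = FALSE)
  leaves <- c("PopA1", "PopA2", "PopB1", "PopB2", "PopC")
  if (length(samplesPerPop) == 1L) {
    spl <- rep(as.integer(samplesPerPop), 5L)
    names(spl) <- leaves
  } else {
    if (is.null(names(samplesPerPop))) names(samplesPerPop) <- leaves
    spl <- as.integer(samplesPerPop)[match(leaves, names(samplesPerPop))]
    names(spl) <- leaves
  }
  popTreeSpec(branches, spl, nSnps = nSnps)
}

#' Simulate genotypes under hierarchical Balding-Nichols drift
#'
#' For each SNP an ancestral allele frequency is drawn uniformly from the
#' spec's range; along each branch with drift F the child frequency is
#' drawn from Beta(p (1-F)/F, (1-p) (1-F)/F), preserving the mean while
#' adding variance F p (1-p); leaf genotypes are Binomial(2, p_leaf).
#' Samples are output in shuffled order with the true population labels
#' returned separately, so downstream analyses stay label-blind.
#'
#' @param spec a [PopTreeSpec-class].
#' @param seed RNG seed (integer).
#' @return list with elements \code{dataset} (a [GenotypeDataset-class])
#'   and \code{labels} (named character vector: true population of every
#'   sample).
#' @export
simulateGenotypes <- function(spec, seed = 1L) {
  stopifnot(is(spec, "PopTreeSpec"))
  set.seed(as.integer(seed))
  b <- spec@branches
  nSnps <- spec@nSnps
  p <- list(ROOT = runif(nSnps, spec@ancestralRange[1], spec@ancestralRange[2]))
  # parents precede children: process branches until all frequencies drawn
  todo <- seq_len(nrow(b))
  while (length(todo)) {
    ready <- todo[b$parent[todo] %in% names(p)]
    if (!length(ready)) stop("branch table does not form a rooted tree")
    for (i in ready) {
      pp <- p[[b$parent[i]]]
      f <- b$f[i]
      p[[b$node[i]]] <- if (f == 0) pp else {
        x <- rbeta(nSnps, pp * (1 - f) / f, (1 - pp) * (1 - f) / f)
        pmin(pmax(x, 0), 1)
      }
    }
    todo <- setdiff(todo, ready)
  }
  leaves <- names(spec@samplesPerLeaf)
  total <- sum(spec@samplesPerLeaf)
  g <- matrix(NA_integer_, total, nSnps)
  labels <- character(total)
  row <- 0L
  for (leaf in leaves) {
    pf <- p[[leaf]]
    for (s in seq_len(spec@samplesPerLeaf[[leaf]])) {
      row <- row + 1L
      g[row, ] <- rbinom(nSnps, 2L, pf)
      labels[row] <- leaf
    }
  }
  ids <- sprintf("S%0*d", nchar(total), seq_len(total))
  perm <- sample.int(total)
  g <- g[perm, , drop = FALSE]
  labels <- labels[perm]
  rownames(g) <- ids
  names(labels) <- ids
  snpIds <- sprintf("snp%0*d", nchar(nSnps), seq_len(nSnps))
  colnames(g) <- snpIds
  info <- data.frame(chrom = "1", pos = seq_len(nSnps) * 1000L,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  list(dataset = genotypeDataset(g, snpInfo = info), labels = labels)
}

#' Write a simulated dataset as PED/MAP plus a labels TSV
#'
#' @param sim result of [simulateGenotypes()].
#' @param prefix output path prefix; writes \code{<prefix>.ped},
#'   \code{<prefix>.map} and \code{<prefix>_labels.tsv} (and
#'   \code{<prefix>_spec.json} when \code{spec} is given).
#' @param spec optional [PopTreeSpec-class] recorded alongside as JSON.
#' @return invisibly, the paths written.
#' @export
writeSimulated <- function(sim, prefix, spec = NULL) {
  ped <- paste0(prefix, ".ped")
  map <- paste0(prefix, ".map")
  lab <- paste0(prefix, "_labels.tsv")
  writePlinkText(sim$dataset, ped, map, labels = sim$labels)
  write.table(data.frame(sample = names(sim$labels),
                         population = unname(sim$labels)),
              lab, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(ped, map, lab)
  if (!is.null(spec)) {
    sj <- paste0(prefix, "_spec.json")
    jsonlite::write_json(
      list(branches = spec@branches,
           samplesPerLeaf = as.list(spec@samplesPerLeaf),
           nSnps = spec@nSnps, ancestralRange = spec@ancestralRange),
      sj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, sj)
  }
  invisible(paths)
}
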