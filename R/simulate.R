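#' Configuration for the two-population Wright-Fisher simulator
#'
#' Builds a validated configuration list for [simulateTwoPop()]. The
#' defaults describe the study conditions the simulator is meant to
#' emulate: two recently diverged populations (split drift T/2N = 0.1,
#' giving background F_ST of roughly 0.1) with an optional additive
#' selective sweep confined to the highland population. Population size,
#' chromosome length and rates are desk-scale rescalings of a large
#' outbred population (small N with correspondingly compressed time and
#' scaled-up per-generation rates).
#'
#' @param nDiploid diploid population size per population (default 1000).
#' @param nSampleDiploid diploids sampled per population at the end
#'   (default 30).
#' @param burnin generations of neutral evolution in the ancestral
#'   population after frequency initialisation (default 80).
#' @param splitGens generations of independent drift after the split
#'   (default 200).
#' @param mu per-site per-generation mutation rate on the grid, applied to
#'   not-yet-mutated sites (infinite-sites: one event per site; default
#'   2e-5).
#' @param crossover expected crossovers per transmitted chromosome per
#'   generation (default 0.5).
#' @param chromLength chromosome length in bp (default 1e6).
#' @param nSites number of grid sites (default 400, evenly spaced).
#' @param initFrac fraction of grid sites initialised as segregating from
#'   a neutral site-frequency spectrum (default 0.85); the rest start
#'   ancestral and may mutate during the run.
#' @param sweep logical: inject a selective sweep in the highland
#'   population at the split (default FALSE).
#' @param sweepPos sweep site position in bp; must lie on the grid.
#'   Default: the grid site nearest to the chromosome midpoint that falls
#'   inside a gene.
#' @param s selection coefficient of the sweep allele (default 0.05).
#' @param h dominance coefficient; genotype fitnesses 1, 1+hs, 1+s
#'   (default 0.5).
#' @param initCopies haplotypes carrying the sweep allele at injection,
#'   all copies of one background haplotype (default 10 percent of the
#'   2N haplotypes, i.e. a standing variant whose stochastic
#'   establishment phase is already past, so the deterministic s = 0.05
#'   trajectory nearly fixes within the default \code{splitGens}).
#' @param geneLength,geneGap gene tiling in bp (defaults 20000 / 5000).
#' @param cancerFraction fraction of genes labeled into the "cancer" set
#'   (default 0.25).
#' @param sweepGeneInSet force the sweep gene into (TRUE) or out of
#'   (FALSE) the cancer set; NA leaves it to the random draw (default NA).
#' @param chrom chromosome name (default "chr1").
#' @param maxRestarts restarts allowed when conditioning the sweep on
#'   non-loss (default 100).
#' @param seed integer random seed; all randomness flows from it.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nDiploid = 1000, nSampleDiploid = 30,
                             burnin = 80, splitGens = 200, mu = 2e-5,
                             crossover = 0.5, chromLength = 1e6,
                             nSites = 400, initFrac = 0.85,
                             sweep = FALSE, sweepPos = NULL, s = 0.05,
                             h = 0.5, initCopies = NULL,
                             geneLength = 20000, geneGap = 5000,
                             cancerFraction = 0.25,
                             sweepGeneInSet = NA, chrom = "chr1",
                             maxRestarts = 100, seed = 1) {
  if (is.null(initCopies))
    initCopies <- max(1L, round(0.1 * 2 * nDiploid))
  stopifnot(nDiploid >= 2, nSampleDiploid >= 2,
            nSampleDiploid <= nDiploid, burnin >= 0, splitGens >= 0,
            mu >= 0, crossover >= 0, nSites >= 2, s >= 0,
            h >= 0, h <= 1, initCopies >= 1,
            initCopies <= 2 * nDiploid, geneLength > 0, geneGap >= 0,
            cancerFraction >= 0, cancerFraction <= 1)
  grid <- .siteGrid(chromLength, nSites)
  geneStarts0 <- seq(0L, as.integer(chromLength) - geneLength,
                     by = geneLength + geneGap)
  if (is.null(sweepPos)) {
    inGene <- vapply(grid, function(p) {
      any(p > geneStarts0 & p <= geneStarts0 + geneLength)
    }, logical(1))
    cand <- grid[inGene]
    if (!length(cand)) stop("no grid site falls inside a gene")
    sweepPos <- cand[which.min(abs(cand - chromLength / 2))]
  }
  if (!sweepPos %in% grid)
    stop("sweep site position ", sweepPos, " is off the site grid")
  cfg <- list(nDiploid = as.integer(nDiploid),
              nSampleDiploid = as.integer(nSampleDiploid),
              burnin = as.integer(burnin),
              splitGens = as.integer(splitGens), mu = mu,
              crossover = crossover, chromLength = as.integer(chromLength),
              nSites = as.integer(nSites), initFrac = initFrac,
              sweep = isTRUE(sweep), sweepPos = as.integer(sweepPos),
              s = s, h = h, initCopies = as.integer(initCopies),
              geneLength = as.integer(geneLength),
              geneGap = as.integer(geneGap),
              cancerFraction = cancerFraction,
              sweepGeneInSet = sweepGeneInSet, chrom = chrom,
              maxRestarts = as.integer(maxRestarts),
              seed = as.integer(seed), grid = grid)
  class(cfg) <- "SimulationConfig"
  cfg
}

# evenly spaced 1-based grid positions
.siteGrid <- function(chromLength, nSites) {
  as.integer(round(seq_len(nSites) * chromLength / (nSites + 1)))
}

# one generation of Wright-Fisher reproduction for a 2N x G haplotype
# matrix; fitness: optional per-diploid weights. Crossovers are Poisson
# per transmission at uniform positions. The (common) single-crossover
# case is vectorized over offspring.
.reproduce <- function(H, crossover, positions, chromLength,
                       fitness = NULL) {
  nh <- nrow(H); N <- nh %/% 2L
  par <- sample.int(N, nh, replace = TRUE, prob = fitness)
  k <- rpois(nh, crossover)
  startB <- rbinom(nh, 1L, 0.5)
  rowA <- 2L * par - 1L + startB        # transmitted starting haplotype
  rowB <- 2L * par - startB             # the parent's other haplotype
  out <- H[rowA, , drop = FALSE]
  i1 <- which(k == 1L)
  if (length(i1)) {
    cuts <- runif(length(i1), 0, chromLength)
    M <- outer(cuts, positions, "<")
    OB <- H[rowB[i1], , drop = FALSE]
    block <- out[i1, , drop = FALSE]
    block[M] <- OB[M]
    out[i1, ] <- block
  }
  for (i in which(k > 1L)) {
    cuts <- sort.int(runif(k[i], 0, chromLength))
    seg <- findInterval(positions, cuts)
    useB <- seg %% 2L == 1L
    out[i, useB] <- H[rowB[i], useB]
  }
  out
}

# mutation step: for grid sites never mutated anywhere, a mutation event
# hits one random haplotype of one population with prob 1-(1-mu)^(2N)
.mutate <- function(pops, mutated, mu) {
  nhTot <- sum(vapply(pops, nrow, 0L))
  pEvent <- 1 - (1 - mu)^nhTot
  unmut <- which(!mutated)
  if (!length(unmut) || pEvent <= 0)
    return(list(pops = pops, mutated = mutated))
  hit <- unmut[runif(length(unmut)) < pEvent]
  for (s in hit) {
    j <- sample.int(nhTot, 1L)
    for (p in seq_along(pops)) {
      if (j <= nrow(pops[[p]])) { pops[[p]][j, s] <- 1L; break }
      j <- j - nrow(pops[[p]])
    }
    mutated[s] <- TRUE
  }
  list(pops = pops, mutated = mutated)
}

#' Simulate two diverged populations with an optional selective sweep
#'
#' Forward Wright-Fisher simulation with full ground truth. One ancestral
#' population is initialised with allele frequencies drawn from a neutral
#' site-frequency spectrum (probability of i copies proportional to 1/i)
#' at linkage equilibrium, evolves neutrally for the burn-in (drift +
#' recombination build linkage structure), then splits into a highland and
#' a lowland population that drift independently. New mutations arise on
#' never-mutated grid sites (at most one event per site; the mutated state
#' is derived and the pre-mutation state is recorded as ancestral).
#'
#' If \code{sweep} is enabled, immediately after the split the sweep
#' allele is placed on \code{initCopies} copies of a single highland
#' haplotype background and evolves under additive selection (genotype
#' fitnesses 1, 1+hs, 1+s) in the highland population only, conditioned on
#' non-loss by restarting the highland phase (restart count in the truth).
#'
#' Output haplotypes are a random sample of diploids per population from
#' the final generation. Genes are tiled deterministically along the
#' chromosome and a random fraction labeled as the "cancer" set.
#'
#' @param config a \code{SimulationConfig} from [simulationConfig()].
#' @return list with \code{haplotypes} (a [HaplotypeSet-class],
#'   populations "highland"/"lowland"), \code{genes} (\code{GRanges}),
#'   \code{geneSets} (named list with the "cancer" set), and \code{truth}
#'   (SimTruth: sweep site/index, s, sweep gene id, final sweep-allele DAF
#'   per population, restarts, per-gene set labels).
#' @export
simulateTwoPop <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  cf <- config
  G <- cf$nSites
  nh <- 2L * cf$nDiploid
  grid <- cf$grid
  sweepIdx <- match(cf$sweepPos, grid)

  # neutral-SFS initialisation at linkage equilibrium
  nInit <- round(cf$initFrac * G)
  initSites <- sort(sample.int(G, nInit))
  if (cf$sweep) initSites <- setdiff(initSites, sweepIdx)
  anc <- matrix(0L, nh, G)
  sfsP <- 1 / seq_len(nh - 1L)
  for (s in initSites) {
    i <- sample.int(nh - 1L, 1L, prob = sfsP)
    anc[sample.int(nh, i), s] <- 1L
  }
  mutated <- logical(G)
  mutated[initSites] <- TRUE
  if (cf$sweep) mutated[sweepIdx] <- TRUE  # reserved for the injection

  for (g in seq_len(cf$burnin)) {
    anc <- .reproduce(anc, cf$crossover, grid, cf$chromLength)
    ms <- .mutate(list(anc), mutated, cf$mu)
    anc <- ms$pops[[1L]]; mutated <- ms$mutated
  }

  highland0 <- anc[sample.int(nh, nh, replace = TRUE), , drop = FALSE]
  lowland <- anc[sample.int(nh, nh, replace = TRUE), , drop = FALSE]
  if (cf$sweep) {
    donor <- sample.int(nh, 1L)
    recip <- sample.int(nh, cf$initCopies)
    highland0[recip, ] <- highland0[rep(donor, cf$initCopies), ,
                                    drop = FALSE]
    highland0[recip, sweepIdx] <- 1L
  }

  runHighland <- function(H, mutated) {
    for (g in seq_len(cf$splitGens)) {
      fit <- NULL
      if (cf$sweep) {
        h1 <- H[seq(1L, nh, 2L), sweepIdx]
        h2 <- H[seq(2L, nh, 2L), sweepIdx]
        fit <- 1 + cf$s * (cf$h * (h1 + h2 == 1L) + (h1 + h2 == 2L))
      }
      H <- .reproduce(H, cf$crossover, grid, cf$chromLength, fitness = fit)
      ms <- .mutate(list(H), mutated, cf$mu)
      H <- ms$pops[[1L]]; mutated <- ms$mutated
      if (cf$sweep && sum(H[, sweepIdx]) == 0L)
        return(list(H = NULL, mutated = mutated))  # lost: restart
    }
    list(H = H, mutated = mutated)
  }

  restarts <- 0L
  repeat {
    res <- runHighland(highland0, mutated)
    if (!is.null(res$H)) break
    restarts <- restarts + 1L
    if (restarts > cf$maxRestarts)
      stop("sweep allele lost in every attempt (", cf$maxRestarts,
           " restarts); increase s or initCopies")
  }
  highland <- res$H
  mutatedH <- res$mutated

  for (g in seq_len(cf$splitGens)) {
    lowland <- .reproduce(lowland, cf$crossover, grid, cf$chromLength)
    ms <- .mutate(list(lowland), mutatedH, cf$mu)
    lowland <- ms$pops[[1L]]; mutatedH <- ms$mutated
  }

  sampleHaps <- function(H) {
    d <- sort(sample.int(cf$nDiploid, cf$nSampleDiploid))
    H[as.vector(rbind(2L * d - 1L, 2L * d)), , drop = FALSE]
  }
  hapH <- sampleHaps(highland)
  hapL <- sampleHaps(lowland)
  alleles <- rbind(hapH, hapL)
  ids <- c(sprintf("HGH%03d", seq_len(cf$nSampleDiploid)),
           sprintf("LWL%03d", seq_len(cf$nSampleDiploid)))
  pops <- rep(c("highland", "lowland"), each = cf$nSampleDiploid)
  hapset <- HaplotypeSet(alleles, chrom = cf$chrom, pos = grid,
                         sampleIds = ids, populations = pops)

  # deterministic gene tiling
  starts0 <- seq(0L, cf$chromLength - cf$geneLength,
                 by = cf$geneLength + cf$geneGap)
  genes <- GenomicRanges::GRanges(cf$chrom,
    IRanges::IRanges(starts0 + 1L, starts0 + cf$geneLength),
    gene_id = sprintf("GENE%04d", seq_along(starts0)))
  names(genes) <- genes$gene_id

  sweepGene <- NA_character_
  if (cf$sweep) {
    hit <- which(cf$sweepPos >= GenomicRanges::start(genes) &
                   cf$sweepPos <= GenomicRanges::end(genes))
    if (length(hit)) sweepGene <- names(genes)[hit[1L]]
  }

  nSet <- round(cf$cancerFraction * length(genes))
  setGenes <- sort(sample(names(genes), nSet))
  if (cf$sweep && !is.na(sweepGene) && !is.na(cf$sweepGeneInSet)) {
    if (isTRUE(cf$sweepGeneInSet) && !sweepGene %in% setGenes) {
      setGenes <- sort(c(setGenes[-1L], sweepGene))
    } else if (identical(cf$sweepGeneInSet, FALSE) &&
               sweepGene %in% setGenes) {
      pool <- setdiff(names(genes), c(setGenes, sweepGene))
      setGenes <- sort(c(setdiff(setGenes, sweepGene), pool[1L]))
    }
  }

  truth <- list(
    sweepEnabled = cf$sweep,
    sweepPos = if (cf$sweep) cf$sweepPos else NA_integer_,
    sweepSiteIndex = if (cf$sweep) sweepIdx else NA_integer_,
    s = if (cf$sweep) cf$s else 0,
    sweepGene = sweepGene,
    sweepDafHighland = if (cf$sweep)
      mean(hapH[, sweepIdx]) else NA_real_,
    sweepDafLowland = if (cf$sweep)
      mean(hapL[, sweepIdx]) else NA_real_,
    restarts = restarts,
    setGenes = setGenes)

  list(haplotypes = hapset, genes = genes,
       geneSets = list(cancer = setGenes), truth = truth)
}

#' Export simulation outputs as analysis-ready fixture files
#'
#' Writes a phased VCF (with the AA INFO key carrying the ancestral base;
#' roughly half the sites have the ancestral allele as ALT so that
#' polarization is exercised on re-read), a sample/population panel, a
#' BED4 gene annotation, one gene-set list per set, and a truth JSON.
#' The files round-trip exactly through [readHaplotypes()] /
#' [readGenes()] / [readGeneSets()].
#'
#' @param sim output of [simulateTwoPop()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory
#'   (default FALSE).
#' @return named list of the file paths written, invisibly.
#' @export
exportFixtures <- function(sim, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop("directory ", dir, " is not empty; use overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hs <- sim$haplotypes
  A <- alleleMatrix(hs)
  chrom <- siteChromosomes(hs)
  pos <- sitePositions(hs)
  ns <- nSites(hs)
  # deterministic base assignment: REF cycles bases; every other site has
  # the ancestral allele as ALT to exercise polarization on re-read
  bases <- c("A", "C", "G", "T")
  ancBase <- bases[(seq_len(ns) - 1L) %% 4L + 1L]
  derBase <- bases[(seq_len(ns)) %% 4L + 1L]
  ancIsRef <- seq_len(ns) %% 2L == 1L
  ref <- ifelse(ancIsRef, ancBase, derBase)
  alt <- ifelse(ancIsRef, derBase, ancBase)

  vcfPath <- file.path(dir, "sim.vcf")
  con <- file(vcfPath, "w")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", sampleIds(hs)),
                     collapse = "\t")), con)
  nSamp <- length(sampleIds(hs))
  for (j in seq_len(ns)) {
    code <- A[, j]                       # 0 = ancestral, 1 = derived
    refCode <- if (ancIsRef[j]) code else 1L - code
    gtChar <- ifelse(is.na(refCode), ".", as.character(refCode))
    h1 <- gtChar[seq(1L, 2L * nSamp, 2L)]
    h2 <- gtChar[seq(2L, 2L * nSamp, 2L)]
    gt <- paste0(h1, "|", h2)
    writeLines(paste(c(chrom[j], pos[j], sprintf("snp%d", j), ref[j],
                       alt[j], ".", "PASS", paste0("AA=", ancBase[j]),
                       "GT", gt), collapse = "\t"), con)
  }
  close(con)

  panelPath <- file.path(dir, "panel.tsv")
  writeLines(paste(sampleIds(hs),
                   haplotypePopulations(hs)[seq(1L, 2L * nSamp, 2L)],
                   sep = "\t"), panelPath)

  bedPath <- file.path(dir, "genes.bed")
  g <- sim$genes
  writeLines(paste(as.character(GenomicRanges::seqnames(g)),
                   GenomicRanges::start(g) - 1L,
                   GenomicRanges::end(g), names(g), sep = "\t"), bedPath)

  setPaths <- character(0)
  for (lab in names(sim$geneSets)) {
    p <- file.path(dir, paste0("geneset_", lab, ".txt"))
    writeLines(sim$geneSets[[lab]], p)
    setPaths[lab] <- p
  }

  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truthPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(vcf = vcfPath, panel = panelPath, bed = bedPath,
                 geneSets = setPaths, truth = truthPath))
}
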