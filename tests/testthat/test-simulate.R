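# small configurations keep the Monte-Carlo unit checks fast; the full
# study-scale configuration is exercised by the acceptance suite
miniNeutral <- function(seed, splitGens = 0)
  simulationConfig(nDiploid = 50, nSampleDiploid = 15, burnin = 15,
                   splitGens = splitGens, chromLength = 2e5, nSites = 80,
                   crossover = 0.25, seed = seed)

miniSweep <- function(seed)
  simulationConfig(nDiploid = 200, nSampleDiploid = 20, burnin = 50,
                   splitGens = 80, chromLength = 5e5, nSites = 200,
                   crossover = 0.25, sweep = TRUE, initCopies = 40,
                   seed = seed)

test_that("the simulator is deterministic under a fixed seed", {
  s1 <- simulateTwoPop(miniSweep(7))
  s2 <- simulateTwoPop(miniSweep(7))
  expect_identical(alleleMatrix(s1$haplotypes),
                   alleleMatrix(s2$haplotypes))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulateTwoPop(miniSweep(8))
  expect_false(identical(alleleMatrix(s1$haplotypes),
                         alleleMatrix(s3$haplotypes)))
})

test_that("an immediate split leaves no differentiation beyond noise", {
  med <- vapply(1:20, function(seed) {
    sim <- simulateTwoPop(miniNeutral(seed))
    theta <- weirCockerhamFst(sim$haplotypes, "highland", "lowland")
    median(abs(theta), na.rm = TRUE)
  }, numeric(1))
  # expectation 0; medians stay within Monte-Carlo tolerance of it
  expect_lt(mean(med), 0.05)
})

test_that("sweeps rise in the highland population", {
  daf <- vapply(1:20, function(seed) {
    sim <- simulateTwoPop(miniSweep(seed))
    i <- sim$truth$sweepSiteIndex
    d <- deltaDaf(sim$haplotypes, "highland", "lowland")
    d[i]
  }, numeric(1))
  expect_gte(mean(daf > 0), 0.9)
})

test_that("the neutral frequency spectrum is monotone over coarse bins", {
  pooled <- unlist(lapply(1:12, function(seed) {
    sim <- simulateTwoPop(miniNeutral(seed, splitGens = 10))
    daf <- derivedAlleleFreqs(sim$haplotypes)
    p <- rowMeans(cbind(daf$daf_highland, daf$daf_lowland))
    p[p > 0 & p < 1]
  }))
  counts <- table(cut(pooled, c(0, 0.25, 0.5, 0.75, 1)))
  expect_true(all(diff(as.integer(counts)) <= 0))
})

test_that("ground truth is internally consistent", {
  sim <- simulateTwoPop(miniSweep(3))
  tr <- sim$truth
  g <- sim$genes[tr$sweepGene]
  expect_true(tr$sweepPos >= GenomicRanges::start(g) &&
                tr$sweepPos <= GenomicRanges::end(g))
  expect_true(tr$sweepPos %in% sitePositions(sim$haplotypes))
  expect_true(all(tr$setGenes %in% names(sim$genes)))
  expect_error(simulateTwoPop(
    simulationConfig(nDiploid = 50, nSites = 80, sweep = TRUE,
                     sweepPos = 123458L)), "off the site grid")
  inSet <- simulateTwoPop(
    simulationConfig(nDiploid = 50, nSampleDiploid = 10, burnin = 10,
                     splitGens = 10, chromLength = 2e5, nSites = 80,
                     sweep = TRUE, initCopies = 20,
                     sweepGeneInSet = TRUE, seed = 5))
  expect_true(inSet$truth$sweepGene %in% inSet$truth$setGenes)
  outSet <- simulateTwoPop(
    simulationConfig(nDiploid = 50, nSampleDiploid = 10, burnin = 10,
                     splitGens = 10, chromLength = 2e5, nSites = 80,
                     sweep = TRUE, initCopies = 20,
                     sweepGeneInSet = FALSE, seed = 5))
  expect_false(outSet$truth$sweepGene %in% outSet$truth$setGenes)
})

test_that("fixtures export, round-trip exactly, and carry AA everywhere", {
  sim <- simulateTwoPop(miniSweep(11))
  dir <- file.path(tempdir(), "fixtures-rt")
  unlink(dir, recursive = TRUE)
  paths <- exportFixtures(sim, dir)
  vcfLines <- readLines(paths$vcf)
  body <- vcfLines[!startsWith(vcfLines, "#")]
  expect_true(all(grepl("AA=[ACGT]", body)))
  expect_error(exportFixtures(sim, dir), "not empty")

  back <- readHaplotypes(paths$vcf, paths$panel)
  expect_identical(unname(alleleMatrix(back)),
                   unname(alleleMatrix(sim$haplotypes)))
  expect_equal(sitePositions(back), sitePositions(sim$haplotypes))
  expect_equal(haplotypePopulations(back),
               haplotypePopulations(sim$haplotypes))

  genes <- readGenes(paths$bed)
  expect_equal(names(genes), names(sim$genes))
  expect_equal(unname(GenomicRanges::start(genes)),
               unname(GenomicRanges::start(sim$genes)))
  sets <- readGeneSets(c(cancer = unname(paths$geneSets["cancer"])))
  expect_equal(sort(sets$cancer), sort(sim$geneSets$cancer))
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_true(truth$sweepGene %in% names(genes))

  # byte-identical re-export under the same seed
  dir2 <- file.path(tempdir(), "fixtures-rt2")
  unlink(dir2, recursive = TRUE)
  paths2 <- exportFixtures(simulateTwoPop(miniSweep(11)), dir2)
  expect_identical(readLines(paths$vcf), readLines(paths2$vcf))
})
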