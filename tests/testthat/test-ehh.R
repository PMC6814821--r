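test_that("EHH curve boundary values match the definition", {
  # 4 derived carriers splitting into extended groups {2,1,1} one site out
  m <- rbind(c(1L, 0L, 0L),
             c(1L, 0L, 1L),
             c(1L, 1L, 0L),
             c(1L, 1L, 1L),
             c(0L, 0L, 0L),
             c(0L, 0L, 0L))
  # at the right flank of core 1: groups by column 2 are {0,0},{1,1}
  hs <- hapsetFromMatrix(m)
  cv <- ehhCurve(hs, "A", core = 1, group = "derived")
  right <- cv[cv$side == "right", ]
  expect_equal(right$ehh[right$distance == 0], 1)
  # one site out: groups {2, 2} -> (1+1)/6
  expect_equal(right$ehh[2], 2 / 6)
  # two sites out: all four extended haplotypes distinct -> 0
  expect_equal(right$ehh[3], 0)
  # oracle agreement: exhaustive pair counting
  A <- alleleMatrix(hs)
  expect_equal(right$ehh[2], pairCountEHH(A, 1:4, 1, 2))
  expect_equal(right$ehh[3], pairCountEHH(A, 1:4, 1, 3))
  solo <- hapsetFromMatrix(rbind(c(1L, 0L), c(1L, 1L), c(1L, 0L),
                                 c(1L, 1L), c(1L, 0L), c(0L, 1L)))
  expect_error(ehhCurve(solo, "A", core = 1, group = "ancestral"),
               "uninformative")
})

test_that("EHH stays 1 for identical carriers and splits as {2,1,1} -> 1/6", {
  ident <- matrix(rep(c(1L, 1L, 1L, 1L, 0L, 0L), 5), nrow = 6)
  hs <- hapsetFromMatrix(ident)
  cv <- ehhCurve(hs, "A", core = 3, group = "derived")
  expect_true(all(cv$ehh == 1))
  # groups of sizes {2,1,1}: EHH = C(2,2)/C(4,2) = 1/6
  m2 <- rbind(c(1L, 0L, 0L),
              c(1L, 0L, 0L),
              c(1L, 1L, 0L),
              c(1L, 1L, 1L),
              c(0L, 0L, 0L),
              c(0L, 0L, 0L))
  hs2 <- hapsetFromMatrix(m2)
  cv2 <- ehhCurve(hs2, "A", core = 1, group = "derived")
  r2 <- cv2[cv2$side == "right", ]
  expect_equal(r2$ehh[3], 1 / 6)
})

test_that("EHH curves are monotone non-increasing, even with missing", {
  for (seed in 1:5) {
    hs <- randomHapset(nSampPerPop = 6, nSitesWanted = 15,
                       pMissing = 0.06, seed = 100 + seed)
    A <- alleleMatrix(hs)
    core <- 8L
    daf <- mean(A[, core], na.rm = TRUE)
    grp <- if (daf >= 0.5) "derived" else "ancestral"
    cv <- ehhCurve(hs, "A", core, group = grp)
    for (sd_ in c("left", "right")) {
      e <- cv$ehh[cv$side == sd_][order(cv$distance[cv$side == sd_])]
      expect_true(all(diff(e) <= 1e-12))
    }
    # all-haplotype curve agrees with pair counting beyond the core
    cva <- ehhCurve(hs, "A", core, group = "all")
    ra <- cva[cva$side == "right", ]
    rows <- which(haplotypePopulations(hs) == "A")
    for (k in seq_len(nrow(ra))[-1]) {
      s <- which(sitePositions(hs) == ra$position[k])
      expect_equal(ra$ehh[k], pairCountEHH(A, rows, core, s))
    }
  }
})

test_that("iHH integrates trapezoids with the stated truncation", {
  mkCurve <- function(dist, ehh) {
    half <- function(side) data.frame(side = side, position = dist,
                                      distance = dist, ehh = ehh,
                                      stringsAsFactors = FALSE)
    out <- rbind(half("left"), half("right"))
    class(out) <- c("EHHCurve", "data.frame")
    out
  }
  # constant 1 over exactly 1000 bp each side, curve ends: 2000, edge flag
  c1 <- mkCurve(c(0, 400, 1000), c(1, 1, 1))
  i1 <- integratedHH(c1)
  expect_equal(i1$ihh, 2000)
  expect_true(i1$edgeTruncated)
  # already below cutoff at the first flank: single trapezoid only
  c2 <- mkCurve(c(0, 200, 800), c(1, 0.01, 0.001))
  i2 <- integratedHH(c2)
  expect_equal(i2$left, (1 + 0.01) / 2 * 200)
  expect_false(i2$edgeTruncated)
  # piecewise-linear toy curve: hand-summed trapezoids
  c3 <- mkCurve(c(0, 100, 300, 600), c(1, 0.8, 0.3, 0.02))
  hand <- (1 + 0.8) / 2 * 100 + (0.8 + 0.3) / 2 * 200 +
    (0.3 + 0.02) / 2 * 300
  expect_equal(integratedHH(c3)$ihh, 2 * hand)
  # a gap larger than maxGap stops the side and sets the flag
  i4 <- integratedHH(c3, maxGap = 150)
  expect_true(i4$gapTruncated)
  expect_equal(i4$left, (1 + 0.8) / 2 * 100)
})

test_that("iHS is zero for mirrored haplotype structure", {
  # ancestral and derived carriers with identical flank structure that
  # fully decays before the chromosome edge
  flankOuter <- c(0L, 1L, 0L, 1L)
  flankInner <- c(0L, 0L, 1L, 1L)
  m <- cbind(c(flankOuter, flankOuter),
             c(flankInner, flankInner),
             rep(c(1L, 0L), each = 4),
             c(flankInner, flankInner),
             c(flankOuter, flankOuter))
  hs <- hapsetFromMatrix(m)
  raw <- ihsScan(hs, "A", mafFilter = 0, minBinSize = 1)$ihsRaw[3]
  expect_equal(raw, 0)
})

test_that("scan iHS matches the naive quadratic pair-counting reference", {
  for (seed in 1:3) {
    hs <- randomHapset(nSampPerPop = 12, nSitesWanted = 40, seed = 200 + seed)
    sc <- suppressWarnings(ihsScan(hs, "A", mafFilter = 0.05,
                                   minBinSize = 5))
    idx <- which(!is.na(sc$ihsRaw))
    expect_gt(length(idx), 3)
    for (core in sample(idx, min(4, length(idx)))) {
      expect_equal(sc$ihsRaw[core], naiveIhsRaw(hs, "A", core),
                   tolerance = 1e-10)
    }
    # z-scores have mean ~0, sd ~1 over the standardized sites
    z <- sc$ihsStd[!is.na(sc$ihsStd)]
    if (length(z) > 10) {
      expect_lt(abs(mean(z)), 0.2)
      expect_equal(sd(z), 1, tolerance = 0.35)
    }
  }
})

test_that("XP-EHH vanishes for identical populations and is antisymmetric", {
  set.seed(31)
  block <- matrix(rbinom(20 * 30, 1, 0.5), 20, 30)
  hs <- hapsetFromMatrix(rbind(block, block),
                         pops = rep(c("A", "B"), each = 10))
  xp <- xpehhScan(hs, "A", "B", mafFilter = 0.05)
  scored <- xp$xpehhRaw[!is.na(xp$xpehhRaw)]
  expect_gt(length(scored), 5)
  expect_true(all(scored == 0))

  hs2 <- randomHapset(nSampPerPop = 10, nSitesWanted = 30, seed = 32)
  a <- xpehhScan(hs2, "A", "B")
  b <- xpehhScan(hs2, "B", "A")
  expect_equal(a$xpehhRaw, -b$xpehhRaw)
  expect_equal(a$xpehhStd, -b$xpehhStd)
})

test_that("large inter-site gaps flag the scan rather than erroring", {
  set.seed(33)
  m <- matrix(rbinom(20 * 10, 1, 0.5), 20, 10)
  pos <- c(1:5 * 1000L, 500000L + 1:5 * 1000L)  # 495 kb gap in the middle
  hs <- hapsetFromMatrix(rbind(m, m), pops = rep(c("A", "B"), each = 10),
                         pos = pos)
  xp <- xpehhScan(hs, "A", "B", mafFilter = 0, maxGap = 200000)
  expect_true(any(xp$gapFlag[!is.na(xp$xpehhRaw)]))
})

test_that("haplotype statistics detect a simulated highland sweep", {
  # young, strong, hard sweep against a long neutral history: the regime
  # where EHH-based statistics are informative
  nRep <- 20
  ihsAtSweep <- xpzAtSweep <- rep(NA_real_, nRep)
  for (seed in seq_len(nRep)) {
    sim <- simulateTwoPop(
      simulationConfig(nDiploid = 600, nSampleDiploid = 50, burnin = 400,
                       splitGens = 30, chromLength = 5e5, nSites = 600,
                       crossover = 0.25, initCopies = 60, s = 0.3,
                       sweep = TRUE, seed = seed))
    i <- sim$truth$sweepSiteIndex
    ih <- suppressWarnings(ihsScan(sim$haplotypes, "highland"))
    xp <- xpehhScan(sim$haplotypes, "highland", "lowland")
    ihsAtSweep[seed] <- ih$ihsStd[i]
    xpzAtSweep[seed] <- xp$xpehhStd[i]
  }
  # longer haplotypes in the swept population: positive XP-EHH
  expect_gt(mean(xpzAtSweep, na.rm = TRUE), 0)
  expect_gte(mean(xpzAtSweep > 0, na.rm = TRUE), 0.75)
  # derived core haplotypes longer than ancestral: negative iHS
  expect_lt(mean(ihsAtSweep, na.rm = TRUE), -0.5)
  expect_gte(mean(ihsAtSweep < 0, na.rm = TRUE), 0.8)
})
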