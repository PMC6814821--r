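test_that("rank-based selection probabilities follow r/(N+1)", {
  expect_equal(selectionProbability(c(1, 5, 9), "high"),
               c(0.25, 0.5, 0.75))
  expect_equal(selectionProbability(c(1, 5, 9), "low"),
               c(0.75, 0.5, 0.25))
  expect_equal(selectionProbability(c(-9, 1, 5), "absolute"),
               c(0.75, 0.25, 0.5))
  expect_warning(ps <- selectionProbability(c(2, 2), "high"), "identical")
  expect_equal(ps, c(0.5, 0.5))
  # NAs propagate; remaining ranks unaffected
  expect_equal(selectionProbability(c(1, NA, 9), "high"),
               c(1 / 3, NA, 2 / 3))
  p <- selectionProbability(rnorm(50), "high", method = "normal")
  expect_true(all(p > 0 & p < 1))
  expect_error(selectionProbability(c(1, NA), "high"), "at least 2")
})

test_that("iFXD is the product of per-method odds", {
  for (n in 1:5)
    expect_equal(ifxdSites(matrix(0.5, 1, n))$ifxd, 1)
  expect_equal(ifxdSites(cbind(0.9, 0.9, 0.9))$ifxd, 729)
  expect_equal(ifxdSites(cbind(0.75))$ifxd, 3)
  expect_error(ifxdSites(cbind(1.0, 0.5)), "strictly inside")
  out <- ifxdSites(rbind(c(0.5, 0.5), c(NA, 0.9)))
  expect_true(is.na(out$ifxd[2]))
  expect_equal(attr(out, "nSkipped"), 1L)
})

test_that("log iFXD equals the sum of logits and is monotone in each Ps", {
  set.seed(41)
  ps <- matrix(runif(3e4, 0.01, 0.99), ncol = 3)
  out <- ifxdSites(ps)
  expect_equal(out$logIfxd, rowSums(log(ps / (1 - ps))), tolerance = 1e-12)
  # raising one component strictly raises iFXD
  ps2 <- ps[1:100, , drop = FALSE]
  bumped <- ps2
  bumped[, 2] <- pmin(ps2[, 2] + 0.005, 0.995)
  expect_true(all(ifxdSites(bumped)$ifxd > ifxdSites(ps2)$ifxd))
})

test_that("Ps marginals average to one half", {
  set.seed(42)
  v <- rnorm(501)
  expect_equal(mean(selectionProbability(v, "high")), 0.5,
               tolerance = 1e-9)
})

test_that("gene scores aggregate, rank and report the top k", {
  stats <- data.frame(
    chrom = "chr1", pos = c(150L, 180L, 250L, 260L, 270L, 900L),
    ifxd = c(1, 3, 5, 2, NA, 7),
    fst = c(0.1, 0.4, 0.2, 0.3, 0.9, 0),
    ihsStd = c(2.5, -3, 0, 1, NA, 0),
    xpehhStd = c(2.1, 0, 2.2, -2.5, 0, 0))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101L, 201L, 401L), c(200L, 300L, 500L)),
    gene_id = c("gA", "gB", "gC"))
  names(genes) <- genes$gene_id
  gs <- geneScores(stats, genes, topK = 2)
  expect_equal(gs$gene_id, c("gB", "gA"))       # means 3.5 vs 2
  expect_equal(gs$ifxdMean, c(3.5, 2))
  expect_equal(gs$nSnps, c(3L, 2L))
  expect_equal(gs$rank, 1:2)
  expect_equal(gs$fstMax, c(0.9, 0.4))
  expect_equal(gs$ihsSigNum, c(0L, 2L))         # |ihsStd| > 2
  expect_equal(gs$xpehhSigNum, c(1L, 1L))       # xpehhStd > 2
  expect_equal(attr(gs, "nOmitted"), 1L)        # gC has no SNP
  expect_equal(attr(gs, "topK")$gene_id, c("gB", "gA"))
  expect_error(geneScores(stats, genes[0]), "empty")
})

test_that("window scan computes +1-corrected empirical p-values", {
  # 99 windows of one SNP each; one window strictly exceeds the rest
  pos <- as.integer(50 + 100 * (0:98))
  vals <- rep(1, 99); vals[40] <- 10
  w <- windowScan(rep("chr1", 99), pos, vals, size = 100, step = 100)
  expect_equal(nrow(w), 99L)
  top <- which.max(w$mean)
  expect_equal(w$empiricalP[top], 1 / 100)
  expect_equal(w$negLog10P[top], 2)
  expect_true(all(w$empiricalP[-top] == 99 / 100))
  # all values equal: every window at the maximal tied p
  w2 <- windowScan(rep("chr1", 99), pos, rep(3, 99), size = 100,
                   step = 100)
  expect_true(all(w2$empiricalP == w2$empiricalP[1]))
  expect_equal(w2$empiricalP[1], 99 / 100)
  expect_error(windowScan("chr1", 1L, 1, size = 0), "positive")
  expect_error(windowScan("chr1", 1L, 1, size = 10, step = 20), ">=")
})

test_that("window empirical ranks are uniform under permutation", {
  set.seed(43)
  pos <- sort(sample.int(100000L, 120))
  vals <- rexp(120)
  base <- windowScan(rep("chr1", 120), pos, vals, size = 10000,
                     step = 5000)
  n <- nrow(base)
  ranks <- replicate(200, {
    w <- windowScan(rep("chr1", 120), pos, sample(vals), size = 10000,
                    step = 5000)
    w$empiricalP[1]
  })
  # permuting SNP values makes the first window's p roughly uniform
  expect_gt(suppressWarnings(
    stats::ks.test(ranks, "punif", 1 / (n + 1), n / (n + 1)))$p.value,
    0.01)
})

test_that("siteStats assembles Ps columns and the composite", {
  hs <- randomHapset(nSampPerPop = 10, nSitesWanted = 40, seed = 44,
                     pops = c("highland", "lowland"))
  ss <- siteStats(hs, "highland", "lowland")
  expect_true(all(c("fst", "deltaDaf", "xpehhStd", "ps_fst", "ps_xpehh",
                    "ps_ddaf", "ifxd", "logIfxd") %in% names(ss)))
  ok <- !is.na(ss$ifxd)
  expect_gt(sum(ok), 5)
  expect_true(all(ss$ifxd[ok] > 0))
  byHand <- ss$ps_fst * ss$ps_xpehh * ss$ps_ddaf /
    ((1 - ss$ps_fst) * (1 - ss$ps_xpehh) * (1 - ss$ps_ddaf))
  expect_equal(ss$ifxd[ok], byHand[ok], tolerance = 1e-10)
})
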