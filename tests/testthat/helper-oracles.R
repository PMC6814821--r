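# Independent oracles and small fixture builders shared across tests.
# Every oracle here recomputes its quantity by a route different from the
# package implementation (direct pair counting, exhaustive enumeration,
# standalone formula transcription).

# random HaplotypeSet: nSamp diploids per population, iid alleles
randomHapset <- function(nSampPerPop = 5, nSitesWanted = 12, pops = c("A", "B"),
                         pMissing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nSamp <- nSampPerPop * length(pops)
  nh <- 2L * nSamp
  a <- matrix(rbinom(nh * nSitesWanted, 1L, runif(nSitesWanted, 0.1, 0.9)),
              nrow = nh, byrow = TRUE)
  if (pMissing > 0)
    a[runif(length(a)) < pMissing] <- NA_integer_
  HaplotypeSet(a, chrom = "chr1",
               pos = sort(sample.int(nSitesWanted * 1000L, nSitesWanted)),
               sampleIds = sprintf("s%02d", seq_len(nSamp)),
               populations = rep(pops, each = nSampPerPop))
}

# EHH by exhaustive pair counting: identity over the sites strictly
# between the core and s (inclusive of s), pairs with any missing call in
# the span count as non-identical; denominator fixed at C(n0, 2)
pairCountEHH <- function(A, rows, core, s) {
  n0 <- length(rows)
  if (n0 < 2) return(NA_real_)
  span <- if (s > core) (core + 1):s else if (s < core) s:(core - 1)
    else integer(0)
  same <- 0L
  for (i in seq_len(n0 - 1)) {
    for (j in (i + 1):n0) {
      hi <- A[rows[i], span]; hj <- A[rows[j], span]
      if (!anyNA(hi) && !anyNA(hj) && all(hi == hj)) same <- same + 1L
    }
  }
  same / choose(n0, 2)
}

# directional iHH by pair counting + trapezoids, mirroring the stated
# truncation convention (include the first below-cutoff site)
pairCountIHH <- function(A, rows, core, pos, cutoff = 0.05) {
  oneSide <- function(dirn) {
    idx <- core; e <- 1; ihh <- 0
    j <- core
    repeat {
      j2 <- j + dirn
      if (j2 < 1 || j2 > ncol(A)) break
      e2 <- pairCountEHH(A, rows, core, j2)
      ihh <- ihh + (e + e2) / 2 * abs(pos[j2] - pos[j])
      j <- j2; e <- e2
      if (e2 < cutoff) break
    }
    ihh
  }
  oneSide(-1L) + oneSide(+1L)
}

# naive iHS for one site from pair counting (NA on <2 carriers/zero iHH)
naiveIhsRaw <- function(hapset, pop, core, cutoff = 0.05) {
  A <- alleleMatrix(hapset)
  pos <- sitePositions(hapset)
  rows <- which(haplotypePopulations(hapset) == pop)
  a <- A[rows, core]
  anc <- rows[!is.na(a) & a == 0L]
  der <- rows[!is.na(a) & a == 1L]
  if (length(anc) < 2 || length(der) < 2) return(NA_real_)
  iA <- pairCountIHH(A, anc, core, pos, cutoff)
  iD <- pairCountIHH(A, der, core, pos, cutoff)
  if (iA <= 0 || iD <= 0) return(NA_real_)
  log(iA / iD)
}

# Weir & Cockerham (1984) two-population theta-hat for haploid samples,
# transcribed step by step from the variance-components definitions
wc84HaploidOracle <- function(dA, nA, dB, nB) {
  r <- 2
  pA <- dA / nA; pB <- dB / nB
  nbar <- (nA + nB) / 2
  nc <- ((nA + nB) - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (nA + nB)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2)
  a / (a + b)
}

# one-sided Mann-Whitney p (first group greater) by exhaustive
# enumeration of all C(n1+n2, n1) rank assignments
mwuEnumP <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x); n <- length(vals)
  r <- rank(vals)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(us >= uObs)
}

# two-sided Fisher p by enumeration of the hypergeometric support
fisherEnumP <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- vapply(support, function(k) {
    choose(rs[1], k) * choose(rs[2], cs[1] - k) / choose(n, cs[1])
  }, numeric(1))
  pObs <- probs[support == m[1, 1]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# build a HaplotypeSet from an explicit haplotype x site matrix, one pop
hapsetFromMatrix <- function(m, pops = NULL, pos = NULL) {
  m <- as.matrix(m)
  nh <- nrow(m)
  stopifnot(nh %% 2 == 0)
  if (is.null(pops)) pops <- rep("A", nh / 2)
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 1000L
  HaplotypeSet(m, chrom = "chr1", pos = pos,
               sampleIds = sprintf("s%02d", seq_len(nh / 2)),
               populations = pops)
}

# write a minimal phased VCF for I/O tests
writeTestVcf <- function(path, samples, records) {
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
  for (rec in records)
    lines <- c(lines, paste(rec, collapse = "\t"))
  writeLines(lines, path)
  path
}
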