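#' Per-population derived allele frequencies
#'
#' DAF = derived-allele count / non-missing haplotype count, computed per
#' population per site. Sites with no non-missing call in a population get
#' \code{NA} there.
#'
#' @param hapset a polarized [HaplotypeSet-class].
#' @param pops population labels to tabulate (default: all).
#' @return data.frame with \code{chrom}, \code{pos} and one DAF column per
#'   population, named \code{daf_<pop>}.
#' @export
derivedAlleleFreqs <- function(hapset, pops = populationNames(hapset)) {
  out <- data.frame(chrom = siteChromosomes(hapset),
                    pos = sitePositions(hapset),
                    stringsAsFactors = FALSE)
  A <- alleleMatrix(hapset)
  for (p in pops) {
    rows <- .popRows(hapset, p)
    sub <- A[rows, , drop = FALSE]
    der <- colSums(sub == 1L, na.rm = TRUE)
    n <- colSums(!is.na(sub))
    daf <- der / n
    daf[n == 0L] <- NA_real_
    out[[paste0("daf_", p)]] <- daf
  }
  out
}

# per-site derived counts and non-missing haplotype counts for one pop
.popCounts <- function(hapset, pop) {
  sub <- alleleMatrix(hapset)[.popRows(hapset, pop), , drop = FALSE]
  list(der = colSums(sub == 1L, na.rm = TRUE), n = colSums(!is.na(sub)))
}

#' Per-SNP Weir-Cockerham F_ST between two populations
#'
#' Variance-components estimator theta-hat of Weir & Cockerham for two
#' populations at each site. The default treats phased haplotypes as
#' haploid allele samples (no heterozygosity component); the diploid
#' genotype variant (with the full a/b/c components, heterozygotes counted
#' from the phased sample pairs) is available via \code{ploidy =
#' "diploid"}. Sites monomorphic in both populations (0/0) and sites with
#' fewer than two non-missing haplotypes in either population return
#' \code{NA}. Slightly negative estimates are reported unclipped.
#'
#' @param hapset a [HaplotypeSet-class].
#' @param popA,popB population labels.
#' @param ploidy \code{"haploid"} (default) or \code{"diploid"}.
#' @return numeric vector of per-site theta-hat.
#' @export
weirCockerhamFst <- function(hapset, popA, popB,
                             ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  cA <- .popCounts(hapset, popA)
  cB <- .popCounts(hapset, popB)
  if (ploidy == "haploid") {
    .wcHaploid(cA$der, cA$n, cB$der, cB$n)
  } else {
    .wcDiploid(hapset, popA, popB)
  }
}

# WC84 theta-hat for haploid allele samples, r = 2 populations
.wcHaploid <- function(dA, nA, dB, nB) {
  r <- 2
  ok <- nA >= 2L & nB >= 2L
  pA <- dA / nA
  pB <- dB / nB
  nbar <- (nA + nB) / 2
  nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pbar <- (dA + dB) / (nA + nB)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * inner
  theta <- a / (a + b)
  theta[!ok] <- NA_real_
  mono <- (dA + dB) == 0L | (dA + dB) == (nA + nB)  # 0/0: monomorphic in both
  theta[mono] <- NA_real_
  theta
}

# WC84 diploid estimator (a, b, c components) from phased sample pairs
.wcDiploid <- function(hapset, popA, popB) {
  A <- alleleMatrix(hapset)
  r <- 2
  stat <- function(pop) {
    rows <- .popRows(hapset, pop)
    h1 <- A[rows[seq(1L, length(rows), 2L)], , drop = FALSE]
    h2 <- A[rows[seq(2L, length(rows), 2L)], , drop = FALSE]
    ok <- !is.na(h1) & !is.na(h2)  # individuals with a complete genotype
    n <- colSums(ok)
    p <- colSums((h1 + h2) * ok, na.rm = TRUE) / (2 * n)
    het <- colSums((h1 != h2) & ok, na.rm = TRUE) / n
    list(n = n, p = p, h = het)
  }
  sA <- stat(popA); sB <- stat(popB)
  nA <- sA$n; nB <- sB$n
  ok <- nA >= 1L & nB >= 1L & (nA + nB) >= 3L
  nbar <- (nA + nB) / 2
  nc <- (nA + nB - (nA^2 + nB^2) / (nA + nB)) / (r - 1)
  pbar <- (nA * sA$p + nB * sB$p) / (nA + nB)
  s2 <- (nA * (sA$p - pbar)^2 + nB * (sB$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * sA$h + nB * sB$h) / (nA + nB)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  theta <- a / (a + b + cc)
  theta[!ok] <- NA_real_
  mono <- pbar %in% c(0, 1)
  theta[mono] <- NA_real_
  theta
}

#' Per-SNP derived-allele-frequency difference (dDAF)
#'
#' dDAF = DAF(highland) - DAF(lowland) at each site; positive values mean
#' the derived allele is commoner in the highland population.
#'
#' @param hapset a [HaplotypeSet-class].
#' @param highland,lowland distinct population labels.
#' @return numeric vector of per-site dDAF in [-1, 1].
#' @export
deltaDaf <- function(hapset, highland, lowland) {
  if (identical(highland, lowland))
    stop("highland and lowland must be different populations")
  cH <- .popCounts(hapset, highland)
  cL <- .popCounts(hapset, lowland)
  dafH <- ifelse(cH$n > 0L, cH$der / cH$n, NA_real_)
  dafL <- ifelse(cL$n > 0L, cL$der / cL$n, NA_real_)
  dafH - dafL
}

# minor allele frequency pooled over the given populations
.pooledMaf <- function(hapset, pops) {
  rows <- unlist(lapply(pops, .popRows, hapset = hapset))
  sub <- alleleMatrix(hapset)[rows, , drop = FALSE]
  der <- colSums(sub == 1L, na.rm = TRUE)
  n <- colSums(!is.na(sub))
  p <- ifelse(n > 0L, der / n, NA_real_)
  pmin(p, 1 - p)
}
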