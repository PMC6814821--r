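# Extended haplotype homozygosity and derived scan statistics.
#
# The walk keeps, for a fixed set of haplotype rows, a compact integer
# labelling of the distinct extended haplotypes spanning core -> current
# site, updated incrementally (label := match of (label, allele) pairs).
# EHH(s) = sum_h C(n_h, 2) / C(n0, 2) over the label classes. A haplotype
# hitting a missing call is removed from its class but the denominator
# stays C(n0, 2), so every produced curve is monotone non-increasing.

# walk outward from coreIdx in direction dirn (+1/-1); stops after
# recording the first EHH < cutoff, at the chromosome edge, or at a
# physical gap > maxGap. Haplotype identity spans the sites strictly
# beyond the core, so EHH at the core is 1 for every group.
.ehhWalk <- function(alleles, rows, coreIdx, chrom, pos, dirn,
                     cutoff, maxGap) {
  n0 <- length(rows)
  denom <- n0 * (n0 - 1) / 2
  g <- rep(1L, n0)
  active <- rep(TRUE, n0)
  nc <- ncol(alleles)
  idx <- integer(256); ehh <- numeric(256)
  idx[1L] <- coreIdx; ehh[1L] <- 1  # EHH at distance 0 is 1 by convention
  m <- 1L
  edge <- FALSE; gap <- FALSE
  j <- coreIdx
  coreChrom <- chrom[coreIdx]
  repeat {
    j2 <- j + dirn
    if (j2 < 1L || j2 > nc || chrom[j2] != coreChrom) { edge <- TRUE; break }
    if (abs(pos[j2] - pos[j]) > maxGap) { gap <- TRUE; break }
    a <- alleles[rows, j2]
    active <- active & !is.na(a)
    na <- sum(active)
    if (na < 2L) {
      e <- 0
    } else {
      key <- g[active] * 2L + a[active]
      g[active] <- match(key, unique(key))
      cnt <- tabulate(g[active])
      e <- sum(cnt * (cnt - 1)) / 2 / denom
    }
    m <- m + 1L
    if (m > length(idx)) { length(idx) <- 2L * m; length(ehh) <- 2L * m }
    idx[m] <- j2; ehh[m] <- e
    j <- j2
    if (e < cutoff) break
  }
  list(idx = idx[seq_len(m)], ehh = ehh[seq_len(m)], edge = edge, gap = gap)
}

# trapezoidal integral of a walk over physical distance (bp * EHH units)
.ihhFromWalk <- function(walk, pos) {
  if (length(walk$idx) < 2L) return(0)
  p <- pos[walk$idx]
  e <- walk$ehh
  sum((e[-1L] + e[-length(e)]) / 2 * abs(diff(p)))
}

#' EHH curve around a core SNP
#'
#' Extended haplotype homozygosity as a function of physical distance from
#' a core site, for the carriers of the ancestral or derived core allele or
#' for all haplotypes of a population (\code{group = "all"}, the grouping
#' used by the cross-population statistic). Haplotype identity spans the
#' sites strictly beyond the core in each direction, so EHH at distance 0
#' is 1 for every group.
#'
#' @param hapset a [HaplotypeSet-class].
#' @param pop population label.
#' @param core site index (column of the allele matrix).
#' @param group \code{"derived"}, \code{"ancestral"} or \code{"all"}.
#' @param maxGap stop a direction at a physical gap larger than this (bp).
#' @return data.frame of class \code{EHHCurve} with columns \code{side}
#'   (left/right), \code{position}, \code{distance} (bp from the core) and
#'   \code{ehh}; attributes record the core index/position, group and
#'   carrier count.
#' @export
ehhCurve <- function(hapset, pop, core,
                     group = c("derived", "ancestral", "all"),
                     maxGap = Inf) {
  group <- match.arg(group)
  A <- alleleMatrix(hapset)
  chrom <- siteChromosomes(hapset)
  pos <- sitePositions(hapset)
  rows <- .popRows(hapset, pop)
  coreAllele <- A[rows, core]
  if (group != "all") {
    want <- if (group == "derived") 1L else 0L
    rows <- rows[!is.na(coreAllele) & coreAllele == want]
  }
  if (length(rows) < 2L)
    stop("uninformative core: fewer than 2 carriers of the ",
         group, " allele at site ", core)
  walkOne <- function(dirn) {
    w <- .ehhWalk(A, rows, core, chrom, pos, dirn, cutoff = 0,
                  maxGap = maxGap)
    data.frame(side = if (dirn < 0) "left" else "right",
               position = pos[w$idx],
               distance = abs(pos[w$idx] - pos[core]),
               ehh = w$ehh, stringsAsFactors = FALSE)
  }
  out <- rbind(walkOne(-1L), walkOne(+1L))
  attr(out, "core") <- core
  attr(out, "corePosition") <- pos[core]
  attr(out, "group") <- group
  attr(out, "nCarriers") <- length(rows)
  class(out) <- c("EHHCurve", "data.frame")
  out
}

#' Integrated haplotype homozygosity (iHH) of an EHH curve
#'
#' Trapezoidal integral of EHH over physical distance, per direction,
#' truncated after the first site whose EHH falls below \code{cutoff} (that
#' site's trapezoid is included); the two directional integrals are summed.
#' A direction that reaches the chromosome edge (or a gap larger than
#' \code{maxGap}) before decaying below the cutoff is flagged rather than
#' erroring.
#'
#' @param curve an \code{EHHCurve} from [ehhCurve()].
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param maxGap maximum physical gap (bp) between adjacent sites before a
#'   direction is stopped and flagged (default 200000).
#' @return list with \code{ihh} (bp x EHH units), per-direction integrals
#'   \code{left}/\code{right}, and flags \code{edgeTruncated},
#'   \code{gapTruncated}.
#' @export
integratedHH <- function(curve, cutoff = 0.05, maxGap = 200000) {
  stopifnot(inherits(curve, "EHHCurve"))
  oneSide <- function(side) {
    s <- curve[curve$side == side, , drop = FALSE]
    s <- s[order(s$distance), , drop = FALSE]
    if (nrow(s) < 2L)
      return(list(ihh = 0, edge = TRUE, gap = FALSE))
    ihh <- 0; edge <- TRUE; gap <- FALSE
    for (k in 2:nrow(s)) {
      step <- s$distance[k] - s$distance[k - 1L]
      if (step > maxGap) { gap <- TRUE; edge <- FALSE; break }
      ihh <- ihh + (s$ehh[k] + s$ehh[k - 1L]) / 2 * step
      if (s$ehh[k] < cutoff) { edge <- FALSE; break }
    }
    list(ihh = ihh, edge = edge, gap = gap)
  }
  l <- oneSide("left"); r <- oneSide("right")
  list(ihh = l$ihh + r$ihh, left = l$ihh, right = r$ihh,
       edgeTruncated = l$edge || r$edge,
       gapTruncated = l$gap || r$gap)
}

# truncated walk + integral in one pass (scan workhorse)
.ihhSite <- function(A, rows, core, chrom, pos, cutoff, maxGap) {
  wl <- .ehhWalk(A, rows, core, chrom, pos, -1L, cutoff, maxGap)
  wr <- .ehhWalk(A, rows, core, chrom, pos, +1L, cutoff, maxGap)
  list(ihh = .ihhFromWalk(wl, pos) + .ihhFromWalk(wr, pos),
       edge = wl$edge || wr$edge, gap = wl$gap || wr$gap)
}

#' Genome scan of the integrated haplotype score (iHS)
#'
#' For each site passing the minor-allele-frequency filter,
#' \code{ihsRaw = ln(iHH_ancestral / iHH_derived)} from the carriers of
#' each core allele, and \code{ihsStd}, the z-score of \code{ihsRaw}
#' within derived-allele-frequency bins. Sites whose EHH walk hits the
#' chromosome edge before decaying below the cutoff (either allele), or
#' with fewer than two carriers of either allele, or with zero iHH, are
#' reported missing; gap-truncated sites keep their value and are flagged.
#'
#' @param hapset a [HaplotypeSet-class].
#' @param pop population to scan.
#' @param mafFilter minimum minor allele frequency in \code{pop}
#'   (default 0.05).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param maxGap maximum bp gap before truncation + flag (default 200000).
#' @param nBins number of equal-width DAF bins for standardization
#'   (default 50); bins with fewer than \code{minBinSize} raw values are
#'   merged with their neighbour (with a warning).
#' @param minBinSize minimum sites per standardization bin (default 10).
#' @return data.frame with \code{chrom}, \code{pos}, \code{daf},
#'   \code{ihsRaw}, \code{ihsStd}, \code{gapFlag}; one row per site of
#'   \code{hapset}, \code{NA} where the statistic is undefined or filtered.
#' @export
ihsScan <- function(hapset, pop, mafFilter = 0.05, cutoff = 0.05,
                    maxGap = 200000, nBins = 50, minBinSize = 10) {
  A <- alleleMatrix(hapset)
  chrom <- siteChromosomes(hapset)
  pos <- sitePositions(hapset)
  rows <- .popRows(hapset, pop)
  maf <- .pooledMaf(hapset, pop)
  cnt <- .popCounts(hapset, pop)
  daf <- ifelse(cnt$n > 0L, cnt$der / cnt$n, NA_real_)
  ns <- ncol(A)
  raw <- rep(NA_real_, ns)
  gapFlag <- rep(FALSE, ns)
  eligible <- which(!is.na(maf) & maf >= mafFilter)
  for (s in eligible) {
    a <- A[rows, s]
    ancRows <- rows[!is.na(a) & a == 0L]
    derRows <- rows[!is.na(a) & a == 1L]
    if (length(ancRows) < 2L || length(derRows) < 2L) next
    iA <- .ihhSite(A, ancRows, s, chrom, pos, cutoff, maxGap)
    iD <- .ihhSite(A, derRows, s, chrom, pos, cutoff, maxGap)
    if (iA$edge || iD$edge) next           # edge-truncated: dropped
    gapFlag[s] <- iA$gap || iD$gap
    if (iA$ihh <= 0 || iD$ihh <= 0) next
    raw[s] <- log(iA$ihh / iD$ihh)
  }
  std <- .standardizeByBin(raw, daf, nBins, minBinSize)
  data.frame(chrom = chrom, pos = pos, daf = daf,
             ihsRaw = raw, ihsStd = std, gapFlag = gapFlag,
             stringsAsFactors = FALSE)
}

# z-score within DAF bins; sparse bins merged left-to-right
.standardizeByBin <- function(raw, daf, nBins, minBinSize) {
  std <- rep(NA_real_, length(raw))
  ok <- which(!is.na(raw) & !is.na(daf))
  if (!length(ok)) return(std)
  br <- seq(0, 1, length.out = nBins + 1L)
  bin <- findInterval(daf[ok], br, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nBins)
  # merge bins (in ascending DAF order) until each merged group has
  # >= minBinSize sites; a sparse trailing group joins its predecessor
  counts <- tabulate(bin, nBins)
  groupOf <- integer(nBins)
  g <- 0L; acc <- 0L
  for (b in seq_len(nBins)) {
    if (acc == 0L) g <- g + 1L
    groupOf[b] <- g
    acc <- acc + counts[b]
    if (acc >= minBinSize) acc <- 0L
  }
  if (acc > 0L && g > 1L)
    groupOf[groupOf == g] <- g - 1L
  if (max(groupOf) < nBins && any(counts > 0L & counts < minBinSize))
    warning("merged sparse DAF bins for iHS standardization (",
            max(groupOf), " merged bins from ", nBins, ")")
  grp <- groupOf[bin]
  for (gg in unique(grp)) {
    sel <- ok[grp == gg]
    v <- raw[sel]
    if (length(v) >= 2L && sd(v) > 0) {
      std[sel] <- (v - mean(v)) / sd(v)
    }
  }
  std
}

#' Genome scan of cross-population EHH (XP-EHH)
#'
#' For each site passing the pooled minor-allele-frequency filter,
#' \code{xpehhRaw = ln(iHH_popA / iHH_popB)}, where each population's iHH
#' integrates the EHH of all its haplotypes from the shared core, and
#' \code{xpehhStd}, the
#' genome-wide z-score. Positive values indicate longer haplotypes in
#' \code{popA}. Sites with zero iHH or an edge-truncated walk in either
#' population are missing; gap truncation is flagged.
#'
#' @inheritParams ihsScan
#' @param popA,popB population labels; the statistic is oriented
#'   \code{popA} over \code{popB} (antisymmetric under swap).
#' @param mafFilter minimum minor allele frequency pooled over both
#'   populations (default 0.05).
#' @return data.frame with \code{chrom}, \code{pos}, \code{xpehhRaw},
#'   \code{xpehhStd}, \code{gapFlag}; one row per site.
#' @export
xpehhScan <- function(hapset, popA, popB, mafFilter = 0.05, cutoff = 0.05,
                      maxGap = 200000) {
  A <- alleleMatrix(hapset)
  chrom <- siteChromosomes(hapset)
  pos <- sitePositions(hapset)
  rowsA <- .popRows(hapset, popA)
  rowsB <- .popRows(hapset, popB)
  maf <- .pooledMaf(hapset, c(popA, popB))
  ns <- ncol(A)
  raw <- rep(NA_real_, ns)
  gapFlag <- rep(FALSE, ns)
  eligible <- which(!is.na(maf) & maf >= mafFilter)
  for (s in eligible) {
    aA <- A[rowsA, s]; aB <- A[rowsB, s]
    rA <- rowsA[!is.na(aA)]; rB <- rowsB[!is.na(aB)]
    if (length(rA) < 2L || length(rB) < 2L) next
    iA <- .ihhSite(A, rA, s, chrom, pos, cutoff, maxGap)
    iB <- .ihhSite(A, rB, s, chrom, pos, cutoff, maxGap)
    if (iA$edge || iB$edge) next
    gapFlag[s] <- iA$gap || iB$gap
    if (iA$ihh <= 0 || iB$ihh <= 0) next
    raw[s] <- log(iA$ihh / iB$ihh)
  }
  okv <- raw[!is.na(raw)]
  std <- rep(NA_real_, ns)
  if (length(okv) >= 2L && sd(okv) > 0)
    std <- (raw - mean(okv)) / sd(okv)
  data.frame(chrom = chrom, pos = pos, xpehhRaw = raw, xpehhStd = std,
             gapFlag = gapFlag, stringsAsFactors = FALSE)
}
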