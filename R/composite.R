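#' Per-site selection probability from a statistic
#'
#' Converts a per-site statistic into a probability of positive selection
#' Ps strictly inside (0, 1). The default (\code{method = "rank"}) is the
#' empirical rank probability Ps = r / (N + 1), where r is the value's rank
#' among the N non-missing genome-wide values (1 = least selection-like
#' under the stated direction, average ranks for ties). The parametric
#' alternative (\code{method = "normal"}) maps the value's z-score to the
#' normal CDF under the same orientation, clipped away from 0/1.
#'
#' @param values numeric vector of a per-site statistic (NAs allowed and
#'   propagated).
#' @param direction \code{"high"} (larger = more selected), \code{"low"},
#'   or \code{"absolute"} (larger magnitude = more selected).
#' @param method \code{"rank"} (default) or \code{"normal"}.
#' @return numeric vector of Ps in (0, 1), NA where the input was NA.
#' @export
selectionProbability <- function(values,
                                 direction = c("high", "low", "absolute"),
                                 method = c("rank", "normal")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  v <- switch(direction, high = values, low = -values,
              absolute = abs(values))
  ok <- !is.na(v)
  if (sum(ok) < 2L) stop("need at least 2 non-missing values")
  ps <- rep(NA_real_, length(values))
  if (method == "rank") {
    if (length(unique(v[ok])) == 1L)
      warning("all values identical; every Ps = 0.5")
    r <- rank(v[ok], ties.method = "average")
    ps[ok] <- r / (sum(ok) + 1)
  } else {
    z <- (v[ok] - mean(v[ok])) / sd(v[ok])
    eps <- 1 / (sum(ok) + 1)
    ps[ok] <- pmin(pmax(pnorm(z), eps), 1 - eps)
  }
  ps
}

#' Per-site iFXD composite statistic
#'
#' The product-of-odds composite over methods:
#' iFXD = prod_i Ps_i / (1 - Ps_i), where Ps_i is the per-method
#' probability of positive selection at the site. Also returns
#' log(iFXD) = sum_i logit(Ps_i) for numerical inspection. Sites missing
#' any method's Ps are skipped (NA) and counted.
#'
#' @param psMatrix numeric matrix or data.frame, one row per site, one
#'   column per method, entries strictly in (0, 1) or NA.
#' @return data.frame with \code{ifxd}, \code{logIfxd}; attribute
#'   \code{nSkipped} counts sites missing at least one method.
#' @examples
#' ifxdSites(cbind(0.9, 0.9, 0.9))$ifxd  # 729
#' @export
ifxdSites <- function(psMatrix) {
  ps <- as.matrix(psMatrix)
  vals <- ps[!is.na(ps)]
  if (length(vals) && (any(vals <= 0) || any(vals >= 1)))
    stop("Ps values must be strictly inside (0, 1)")
  complete <- rowSums(is.na(ps)) == 0L
  logIfxd <- rep(NA_real_, nrow(ps))
  logIfxd[complete] <- rowSums(log(ps[complete, , drop = FALSE] /
                                     (1 - ps[complete, , drop = FALSE])))
  out <- data.frame(ifxd = exp(logIfxd), logIfxd = logIfxd)
  attr(out, "nSkipped") <- sum(!complete)
  out
}

#' Assemble the per-SNP statistics table (SiteStats)
#'
#' Runs the per-site and haplotype statistics for a highland/lowland
#' contrast, converts each chosen method to a selection probability, and
#' computes the iFXD composite. Methods: \code{"fst"} (Weir-Cockerham,
#' negative estimates floored at 0 before ranking, direction high),
#' \code{"ddaf"} (direction high), \code{"xpehh"} (highland over lowland
#' standardized XP-EHH, direction high), \code{"ihs"} (highland |iHS|,
#' direction absolute). The default method set \code{c("fst", "xpehh",
#' "ddaf")} matches a two-population mammal-style scan; use
#' \code{c("fst", "xpehh", "ihs")} for a human-style scan.
#'
#' @param hapset a [HaplotypeSet-class].
#' @param highland,lowland population labels.
#' @param methods character subset of \code{c("fst", "xpehh", "ddaf",
#'   "ihs")}.
#' @param psMethod passed to [selectionProbability()].
#' @param mafFilter,cutoff,maxGap haplotype-statistic parameters, see
#'   [ihsScan()] / [xpehhScan()].
#' @param ... further arguments to [ihsScan()] (binning).
#' @return data.frame with chrom, pos, per-population DAFs, the per-method
#'   statistics, \code{ps_<method>} columns, \code{ifxd} and
#'   \code{logIfxd}.
#' @export
siteStats <- function(hapset, highland, lowland,
                      methods = c("fst", "xpehh", "ddaf"),
                      psMethod = c("rank", "normal"),
                      mafFilter = 0.05, cutoff = 0.05, maxGap = 200000,
                      ...) {
  methods <- match.arg(methods, c("fst", "xpehh", "ddaf", "ihs"),
                       several.ok = TRUE)
  psMethod <- match.arg(psMethod)
  out <- derivedAlleleFreqs(hapset, pops = c(highland, lowland))
  out$deltaDaf <- out[[paste0("daf_", highland)]] -
    out[[paste0("daf_", lowland)]]
  out$fst <- weirCockerhamFst(hapset, highland, lowland)
  if ("xpehh" %in% methods || "ihs" %in% methods) {
    if ("xpehh" %in% methods) {
      xp <- xpehhScan(hapset, highland, lowland, mafFilter = mafFilter,
                      cutoff = cutoff, maxGap = maxGap)
      out$xpehhRaw <- xp$xpehhRaw
      out$xpehhStd <- xp$xpehhStd
    }
    if ("ihs" %in% methods) {
      ih <- ihsScan(hapset, highland, mafFilter = mafFilter,
                    cutoff = cutoff, maxGap = maxGap, ...)
      out$ihsRaw <- ih$ihsRaw
      out$ihsStd <- ih$ihsStd
    }
  }
  psCols <- character(0)
  for (m in methods) {
    ps <- switch(m,
      fst = selectionProbability(pmax(out$fst, 0), "high", psMethod),
      ddaf = selectionProbability(out$deltaDaf, "high", psMethod),
      xpehh = selectionProbability(out$xpehhStd, "high", psMethod),
      ihs = selectionProbability(out$ihsStd, "absolute", psMethod))
    col <- paste0("ps_", m)
    out[[col]] <- ps
    psCols <- c(psCols, col)
  }
  comp <- ifxdSites(out[psCols])
  out$ifxd <- comp$ifxd
  out$logIfxd <- comp$logIfxd
  attr(out, "nSkipped") <- attr(comp, "nSkipped")
  out
}

#' Gene-level aggregation and ranking of per-SNP statistics
#'
#' For each gene containing at least one SNP: the arithmetic mean iFXD of
#' its SNPs, the maximum per-SNP F_ST, and the counts of SNPs with
#' significantly high haplotype statistics (|iHS| and XP-EHH above their
#' thresholds). Genes are ranked by mean iFXD, rank 1 = highest; genes
#' containing no SNP are omitted and counted in the \code{nOmitted}
#' attribute. A top-k report is attached as the \code{topK} attribute.
#'
#' @param stats a SiteStats data.frame from [siteStats()] (needs
#'   \code{chrom}, \code{pos}, \code{ifxd}; uses \code{fst},
#'   \code{ihsStd}, \code{xpehhStd} when present).
#' @param genes a \code{GRanges} of gene intervals from [readGenes()].
#' @param ihsSigThreshold count SNPs with |ihsStd| above this (default 2).
#' @param xpehhSigThreshold count SNPs with xpehhStd above this
#'   (default 2).
#' @param topK how many top-ranked genes the report lists (default 2).
#' @param flank extend each gene by this many bp on both sides when
#'   assigning SNPs (default 0: strictly within the gene).
#' @return data.frame (GeneScore) with \code{gene_id}, \code{nSnps},
#'   \code{ifxdMean}, \code{rank}, \code{fstMax}, \code{ihsSigNum},
#'   \code{xpehhSigNum}, sorted by rank.
#' @export
geneScores <- function(stats, genes, ihsSigThreshold = 2,
                       xpehhSigThreshold = 2, topK = 2, flank = 0) {
  if (length(genes) == 0L) stop("empty gene table")
  snps <- GenomicRanges::GRanges(stats$chrom,
                                 IRanges::IRanges(stats$pos, stats$pos))
  target <- if (flank > 0) {
    GenomicRanges::resize(genes, GenomicRanges::width(genes) + 2 * flank,
                          fix = "center")
  } else genes
  hits <- GenomicRanges::findOverlaps(snps, target)
  if (length(hits) == 0L) stop("no SNP falls inside any gene")
  siteIdx <- S4Vectors::queryHits(hits)
  geneIdx <- S4Vectors::subjectHits(hits)
  ids <- names(genes)[geneIdx]
  agg <- function(v, f) {
    x <- tapply(v[siteIdx], ids, f)
    x[match(uniqIds, names(x))]
  }
  uniqIds <- unique(ids)
  meanNA <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  maxNA <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  out <- data.frame(
    gene_id = uniqIds,
    nSnps = as.integer(agg(rep(1L, nrow(stats)), sum)),
    ifxdMean = as.numeric(agg(stats$ifxd, meanNA)),
    stringsAsFactors = FALSE)
  out$fstMax <- if ("fst" %in% names(stats))
    as.numeric(agg(stats$fst, maxNA)) else NA_real_
  out$ihsSigNum <- if ("ihsStd" %in% names(stats))
    as.integer(agg(abs(stats$ihsStd) > ihsSigThreshold,
                   function(x) sum(x, na.rm = TRUE))) else NA_integer_
  out$xpehhSigNum <- if ("xpehhStd" %in% names(stats))
    as.integer(agg(stats$xpehhStd > xpehhSigThreshold,
                   function(x) sum(x, na.rm = TRUE))) else NA_integer_
  ord <- order(-out$ifxdMean, out$gene_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("gene_id", "nSnps", "ifxdMean", "rank", "fstMax",
                 "ihsSigNum", "xpehhSigNum")]
  attr(out, "nOmitted") <- length(genes) - length(uniqIds)
  attr(out, "topK") <- head(out[, c("gene_id", "ifxdMean", "rank")],
                            topK)
  out
}

#' Sliding-window empirical p-value scan
#'
#' Tiles each chromosome with windows of \code{size} bp stepped by
#' \code{step} bp (anchored at position 0), averages the statistic over the
#' SNPs in each window (empty windows omitted), and assigns every window
#' the empirical p-value p_w = #\{windows with mean >= mean_w\} /
#' (N_windows + 1) (the +1 correction keeps -log10 p finite).
#'
#' @param chrom,pos per-site coordinates.
#' @param values per-site statistic to average (NAs ignored within a
#'   window).
#' @param size window size in bp (default 50000).
#' @param step window step in bp (default 25000).
#' @return data.frame (WindowScore) with \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive bounds of the \code{[start, start +
#'   size)} window), \code{nSnps}, \code{mean}, \code{empiricalP},
#'   \code{negLog10P}.
#' @export
windowScan <- function(chrom, pos, values, size = 50000, step = 25000) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (size < step) stop("window size must be >= step")
  pieces <- lapply(unique(chrom), function(ch) {
    sel <- chrom == ch & !is.na(values)
    p <- pos[sel]; v <- values[sel]
    if (!length(p)) return(NULL)
    starts <- seq(0L, max(p), by = step)
    res <- lapply(starts, function(s0) {
      inw <- p >= s0 + 1L & p <= s0 + size  # [s0, s0 + size) in 0-based
      if (!any(inw)) return(NULL)
      data.frame(chrom = ch, start = s0 + 1L, end = s0 + size,
                 nSnps = sum(inw), mean = mean(v[inw]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L)
    stop("no window contains a non-missing value")
  n <- nrow(out)
  out$empiricalP <- vapply(out$mean,
                           function(m) sum(out$mean >= m) / (n + 1),
                           numeric(1))
  out$negLog10P <- -log10(out$empiricalP)
  rownames(out) <- NULL
  out
}
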