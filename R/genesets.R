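#' Mann-Whitney U comparison of two groups
#'
#' U is computed with average ranks for ties (U of the first group,
#' counting pairs where the first group's value exceeds the second's).
#' The p-value is exact (full rank-permutation distribution) when
#' n1 + n2 <= 12 and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param valuesSet,valuesOther numeric vectors, both non-empty.
#' @param alternative \code{"greater"} (the set tends to exceed the other
#'   group; default) or \code{"two.sided"}.
#' @return list with \code{U}, \code{p}, \code{negLog10P},
#'   \code{meanSet}, \code{meanOther}, \code{nSet}, \code{nOther},
#'   \code{exact} (logical).
#' @export
mwuCompare <- function(valuesSet, valuesOther,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- valuesSet[!is.na(valuesSet)]
  y <- valuesOther[!is.na(valuesOther)]
  if (!length(x) || !length(y))
    stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  hasTies <- anyDuplicated(c(x, y)) > 0L
  exact <- (n1 + n2) <= 12L && !hasTies
  if (length(unique(c(x, y))) == 1L) {
    # fully degenerate: every value tied; no evidence either way
    p <- 1
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = alternative, exact = exact,
                  correct = TRUE))
    p <- wt$p.value
  }
  list(U = U, p = p, negLog10P = -log10(p),
       meanSet = mean(x), meanOther = mean(y),
       nSet = n1, nOther = n2, exact = exact)
}

#' Gene-level gene-set enrichment of a selection summary
#'
#' Partitions scored genes into a named set versus all other scored genes
#' and compares the chosen per-gene summary (\code{"fstMax"},
#' \code{"ihsSigNum"}, \code{"xpehhSigNum"} or \code{"ifxdMean"}) with a
#' Mann-Whitney U test (one-sided, set > other, by default). Catalog gene
#' ids absent from the scored table are counted in \code{nUnmatched}.
#'
#' @param scores GeneScore data.frame from [geneScores()].
#' @param catalog named list of gene-id vectors (see [readGeneSets()]).
#' @param setLabel which catalog entry to test.
#' @param summary name of the per-gene summary column.
#' @param alternative passed to [mwuCompare()].
#' @return one-row data.frame (SetComparison) with the set label, summary
#'   name, group sizes and means, U, p, negLog10P, nUnmatched.
#' @export
geneLevelCompare <- function(scores, catalog, setLabel,
                             summary = c("fstMax", "ihsSigNum",
                                         "xpehhSigNum", "ifxdMean"),
                             alternative = c("greater", "two.sided")) {
  summary <- match.arg(summary)
  if (!setLabel %in% names(catalog))
    stop("unknown gene set: ", setLabel)
  members <- catalog[[setLabel]]
  inSet <- scores$gene_id %in% members
  nUnmatched <- sum(!members %in% scores$gene_id)
  if (!any(inSet))
    stop("gene set '", setLabel, "' shares no gene with the scored table")
  if (all(inSet))
    stop("gene set '", setLabel, "' covers every scored gene; ",
         "no background group")
  cmp <- mwuCompare(scores[[summary]][inSet], scores[[summary]][!inSet],
                    alternative)
  data.frame(set = setLabel, summary = summary,
             nInSet = cmp$nSet, nOther = cmp$nOther,
             meanSet = cmp$meanSet, meanOther = cmp$meanOther,
             U = cmp$U, p = cmp$p, negLog10P = cmp$negLog10P,
             nUnmatched = nUnmatched, stringsAsFactors = FALSE)
}

#' SNP-level gene-set enrichment of a per-SNP statistic
#'
#' Compares a per-SNP statistic between SNPs inside set-member genes and
#' SNPs inside all other genes (intergenic SNPs excluded by default;
#' \code{includeIntergenic = TRUE} adds them to the background). SNPs
#' inside both a set gene and a non-set gene count as set SNPs.
#'
#' @param stats SiteStats data.frame (needs chrom, pos and the statistic
#'   column).
#' @param genes \code{GRanges} of gene intervals.
#' @param catalog named list of gene-id vectors.
#' @param setLabel which catalog entry to test.
#' @param statistic column of \code{stats} to compare (e.g. \code{"fst"},
#'   \code{"xpehhStd"}, \code{"deltaDaf"}).
#' @param alternative passed to [mwuCompare()].
#' @param includeIntergenic include SNPs outside every gene in the
#'   background group (default FALSE).
#' @return one-row data.frame (SetComparison), as [geneLevelCompare()].
#' @export
snpLevelCompare <- function(stats, genes, catalog, setLabel, statistic,
                            alternative = c("greater", "two.sided"),
                            includeIntergenic = FALSE) {
  if (!statistic %in% names(stats))
    stop("statistic column not present: ", statistic)
  v <- stats[[statistic]]
  if (all(is.na(v))) stop("statistic entirely missing: ", statistic)
  if (!setLabel %in% names(catalog))
    stop("unknown gene set: ", setLabel)
  members <- catalog[[setLabel]]
  snps <- GenomicRanges::GRanges(stats$chrom,
                                 IRanges::IRanges(stats$pos, stats$pos))
  hits <- GenomicRanges::findOverlaps(snps, genes)
  geneOf <- names(genes)[S4Vectors::subjectHits(hits)]
  siteOf <- S4Vectors::queryHits(hits)
  inSetSite <- unique(siteOf[geneOf %in% members])
  genicSite <- unique(siteOf)
  otherSite <- setdiff(genicSite, inSetSite)
  if (includeIntergenic)
    otherSite <- union(otherSite, setdiff(seq_len(nrow(stats)), genicSite))
  cmp <- .mwuOrNA(v[inSetSite], v[otherSite], alternative)
  data.frame(set = setLabel, summary = statistic,
             nInSet = cmp$nSet, nOther = cmp$nOther,
             meanSet = cmp$meanSet, meanOther = cmp$meanOther,
             U = cmp$U, p = cmp$p, negLog10P = cmp$negLog10P,
             nUnmatched = sum(!members %in% names(genes)),
             stringsAsFactors = FALSE)
}

# a group with no non-missing value yields an NA comparison row rather
# than an error (scans can leave a statistic missing for a whole set)
.mwuOrNA <- function(x, y, alternative) {
  if (!sum(!is.na(x)) || !sum(!is.na(y))) {
    return(list(U = NA_real_, p = NA_real_, negLog10P = NA_real_,
                meanSet = NA_real_, meanOther = NA_real_,
                nSet = sum(!is.na(x)), nOther = sum(!is.na(y)),
                exact = NA))
  }
  mwuCompare(x, y, alternative)
}

#' Run a battery of set comparisons (bar-chart-ready table)
#'
#' Convenience wrapper: for each catalog set and each statistic name,
#' run [snpLevelCompare()] and stack the rows (the -log10 p column is the
#' bar-height quantity for enrichment bar plots).
#'
#' @inheritParams snpLevelCompare
#' @param statistics character vector of SiteStats column names.
#' @return data.frame with one row per (set, statistic).
#' @export
enrichmentTable <- function(stats, genes, catalog,
                            statistics = c("fst", "xpehhStd", "deltaDaf"),
                            alternative = c("greater", "two.sided"),
                            includeIntergenic = FALSE) {
  rows <- list()
  for (lab in names(catalog)) {
    for (st in statistics) {
      rows[[paste(lab, st)]] <-
        snpLevelCompare(stats, genes, catalog, lab, st,
                        alternative = alternative,
                        includeIntergenic = includeIntergenic)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
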