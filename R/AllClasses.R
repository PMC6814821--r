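#' HaplotypeSet: phased, polarized haplotypes with population labels
#'
#' The central container of the package. Holds a matrix of phased binary
#' haplotypes (rows = haplotypes, columns = SNP sites) polarized against the
#' ancestral allele (0 = ancestral, 1 = derived, \code{NA} = missing call),
#' together with per-site chromosome/position coordinates (1-based, as in
#' VCF) and per-haplotype sample and population labels. Diploid phased
#' input is assumed: haplotype rows come in consecutive pairs, two per
#' sample.
#'
#' Validity requires: allele codes in \{0, 1, NA\}; positions strictly
#' increasing within each chromosome (no duplicated chromosome/position
#' pair); haplotype count equal to twice the sample count; and at least two
#' haplotypes in every referenced population.
#'
#' @slot alleles integer matrix, haplotypes x sites, codes 0/1/NA.
#' @slot chrom character vector, chromosome per site.
#' @slot pos integer vector, 1-based base-pair position per site.
#' @slot sampleIds character vector, one id per diploid sample.
#' @slot popOf character vector, population label per haplotype row.
#' @slot metadata list of provenance/bookkeeping (e.g. site drop reports).
#'
#' @seealso [HaplotypeSet()] for construction, [readHaplotypes()] to build
#'   one from VCF + panel files, [simulateTwoPop()] to simulate one.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(
    alleles  = "matrix",
    chrom    = "character",
    pos      = "integer",
    sampleIds = "character",
    popOf    = "character",
    metadata = "list"
  )
)

.validHaplotypeSet <- function(object) {
  msg <- character(0)
  a <- object@alleles
  if (!is.numeric(a) && !is.integer(a))
    msg <- c(msg, "allele matrix must be numeric")
  bad <- a[!is.na(a)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    msg <- c(msg, "allele codes must be 0 (ancestral), 1 (derived) or NA")
  if (length(object@chrom) != ncol(a))
    msg <- c(msg, "chrom length must equal site count")
  if (length(object@pos) != ncol(a))
    msg <- c(msg, "pos length must equal site count")
  if (length(object@popOf) != nrow(a))
    msg <- c(msg, "popOf length must equal haplotype count")
  if (nrow(a) != 2L * length(object@sampleIds))
    msg <- c(msg, "haplotype count must be 2 x sample count (phased diploid)")
  if (ncol(a) > 0L) {
    key <- paste(object@chrom, object@pos)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chromosome, position) pairs")
    for (ch in unique(object@chrom)) {
      p <- object@pos[object@chrom == ch]
      if (is.unsorted(p, strictly = TRUE))
        msg <- c(msg, sprintf("positions not strictly increasing on %s", ch))
    }
  }
  if (nrow(a) > 0L) {
    tab <- table(object@popOf)
    if (any(tab < 2L))
      msg <- c(msg, "every population needs at least 2 haplotypes")
  }
  if (length(msg)) msg else TRUE
}
setValidity("HaplotypeSet", .validHaplotypeSet)
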