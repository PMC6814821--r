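#' Construct a HaplotypeSet
#'
#' Build the package's central haplotype container from an allele matrix and
#' its annotation. Columns are reordered by (chromosome, position) if
#' needed; chromosomes keep their order of first appearance.
#'
#' @param alleles integer matrix, rows = haplotypes (two consecutive rows
#'   per sample), columns = sites; codes 0 = ancestral, 1 = derived,
#'   NA = missing.
#' @param chrom chromosome identifier per site (recycled if length 1).
#' @param pos 1-based base-pair position per site.
#' @param sampleIds one id per diploid sample (haplotype rows 2i-1, 2i
#'   belong to sample i).
#' @param populations population label per sample, or per haplotype row.
#' @param metadata optional list of bookkeeping values.
#' @return A [HaplotypeSet-class] object.
#' @examples
#' hs <- HaplotypeSet(matrix(c(0L,1L,1L,0L), 2, 2), chrom = "chr1",
#'                    pos = c(100L, 200L), sampleIds = "s1",
#'                    populations = "popA")
#' nSites(hs)
#' @export
HaplotypeSet <- function(alleles, chrom, pos, sampleIds, populations,
                         metadata = list()) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(chrom) == 1L) chrom <- rep(chrom, ncol(alleles))
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(populations) == length(sampleIds)) {
    popOf <- rep(as.character(populations), each = 2L)
  } else {
    popOf <- as.character(populations)
  }
  ord <- order(match(chrom, unique(chrom)), pos)
  if (!identical(ord, seq_along(pos))) {
    alleles <- alleles[, ord, drop = FALSE]
    chrom <- chrom[ord]
    pos <- pos[ord]
  }
  new("HaplotypeSet", alleles = alleles, chrom = chrom, pos = pos,
      sampleIds = as.character(sampleIds), popOf = popOf,
      metadata = metadata)
}

#' Accessors for HaplotypeSet
#'
#' @param x a [HaplotypeSet-class].
#' @return \code{alleleMatrix}: the integer haplotype-by-site matrix;
#'   \code{sitePositions}/\code{siteChromosomes}: per-site coordinates;
#'   \code{sampleIds}: per-sample ids; \code{haplotypePopulations}:
#'   per-haplotype population labels; \code{populationNames}: the distinct
#'   labels; \code{nHaplotypes}/\code{nSites}: dimensions.
#' @name HaplotypeSet-accessors
NULL

#' @rdname HaplotypeSet-accessors
setMethod("alleleMatrix", "HaplotypeSet", function(x) x@alleles)
#' @rdname HaplotypeSet-accessors
setMethod("sitePositions", "HaplotypeSet", function(x) x@pos)
#' @rdname HaplotypeSet-accessors
setMethod("siteChromosomes", "HaplotypeSet", function(x) x@chrom)
#' @rdname HaplotypeSet-accessors
setMethod("sampleIds", "HaplotypeSet", function(x) x@sampleIds)
#' @rdname HaplotypeSet-accessors
setMethod("haplotypePopulations", "HaplotypeSet", function(x) x@popOf)
#' @rdname HaplotypeSet-accessors
setMethod("populationNames", "HaplotypeSet", function(x) unique(x@popOf))
#' @rdname HaplotypeSet-accessors
setMethod("nHaplotypes", "HaplotypeSet", function(x) nrow(x@alleles))
#' @rdname HaplotypeSet-accessors
setMethod("nSites", "HaplotypeSet", function(x) ncol(x@alleles))

#' @describeIn HaplotypeSet-accessors subset by haplotype rows (i) and/or
#'   site columns (j); row subsetting must keep sample pairs intact.
#' @param i,j,...,drop row (haplotype) and column (site) indices; `drop` is
#'   ignored.
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@alleles))
  if (missing(j)) j <- seq_len(ncol(x@alleles))
  i <- seq_len(nrow(x@alleles))[i]
  j <- seq_len(ncol(x@alleles))[j]
  odd <- i[seq_along(i) %% 2L == 1L]
  if (length(i) %% 2L != 0L || !all(i[seq_along(i) %% 2L == 0L] == odd + 1L) ||
      !all(odd %% 2L == 1L))
    stop("haplotype subsetting must keep diploid sample pairs intact")
  new("HaplotypeSet",
      alleles = x@alleles[i, j, drop = FALSE],
      chrom = x@chrom[j], pos = x@pos[j],
      sampleIds = x@sampleIds[(odd + 1L) / 2L],
      popOf = x@popOf[i], metadata = x@metadata)
})

setMethod("show", "HaplotypeSet", function(object) {
  tab <- table(object@popOf)
  cat("HaplotypeSet:", nrow(object@alleles), "haplotypes (",
      length(object@sampleIds), "samples ) x", ncol(object@alleles),
      "sites\n")
  cat("  chromosomes:", paste(unique(object@chrom), collapse = ", "), "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  nmiss <- sum(is.na(object@alleles))
  if (nmiss > 0L) cat("  missing calls:", nmiss, "\n")
  invisible(NULL)
})

# haplotype row indices belonging to one population
.popRows <- function(hapset, pop) {
  rows <- which(hapset@popOf == pop)
  if (!length(rows))
    stop(sprintf("population '%s' not present in HaplotypeSet", pop))
  rows
}
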