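#' Read phased haplotypes from VCF + population panel
#'
#' Parses a phased diploid VCF, polarizes alleles against the ancestral
#' allele (so that 1 = derived), and attaches population labels from a
#' panel file. Only biallelic SNP records with a usable ancestral allele
#' are kept; everything else is dropped and counted in a drop report kept
#' in the returned object's metadata.
#'
#' The ancestral allele comes either from the VCF's \code{AA} INFO key
#' (\code{ancestral = "AA"}) or from a three-column table
#' (chromosome, position, ancestral base). A site whose ancestral allele is
#' missing, is not a single A/C/G/T base, or matches neither REF nor ALT is
#' dropped. When the ancestral allele equals ALT the genotype codes are
#' flipped so that 1 always means derived.
#'
#' @param vcfPath path to a VCF (plain or gzipped) with phased GT fields.
#' @param panelPath path to a whitespace-separated two-column file mapping
#'   sample id to population label; \code{#} comments allowed.
#' @param ancestral \code{"AA"} (default) to read the AA INFO key, or a
#'   path to a chromosome/position/allele table.
#' @return A [HaplotypeSet-class]; \code{metadata(x)$dropReport} counts the
#'   sites removed by each rule (accessible via \code{x@metadata}).
#' @export
readHaplotypes <- function(vcfPath, panelPath, ancestral = "AA") {
  panel <- readPanel(panelPath)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcf@fix
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  samples <- colnames(vcf@gt)[-1L]

  missingSamp <- setdiff(samples, panel$sample)
  if (length(missingSamp))
    stop("sample(s) absent from panel: ", paste(missingSamp, collapse = ", "))
  key <- paste(chrom, pos)
  if (anyDuplicated(key))
    stop("duplicate positions in VCF: ",
         paste(head(key[duplicated(key)], 3L), collapse = "; "))

  # biallelic SNPs only; multi-allelic / indel records are dropped whole
  isSnp <- !grepl(",", alt, fixed = TRUE) & nchar(ref) == 1L &
    nchar(alt) == 1L & ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  nMulti <- sum(!isSnp)

  aa <- if (identical(ancestral, "AA")) {
    toupper(vcfR::extract.info(vcf, "AA"))
  } else {
    lookupAncestral(ancestral, chrom, pos)
  }
  aaMissing <- is.na(aa) | !(aa %in% c("A", "C", "G", "T"))
  aaMismatch <- !aaMissing & !(aa == ref | aa == alt)
  keep <- isSnp & !aaMissing & !aaMismatch
  nAaMissing <- sum(isSnp & aaMissing)
  nAaMismatch <- sum(isSnp & aaMismatch)
  if (!any(keep))
    stop("no usable biallelic polarized SNPs in ", vcfPath)

  gt <- vcfR::extract.gt(vcf, "GT")
  gt <- gt[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  ref <- ref[keep]; alt <- alt[keep]; aa <- aa[keep]

  nSite <- nrow(gt); nSamp <- length(samples)
  h1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  h2 <- substr(gt, 3L, 3L)
  isMiss <- is.na(gt) | h1 == "."
  unphased <- !isMiss & sep != "|"
  if (any(unphased)) {
    w <- which(unphased, arr.ind = TRUE)[1L, ]
    stop(sprintf("unphased genotype for sample %s at %s:%d",
                 samples[w[2L]], chrom[w[1L]], pos[w[1L]]))
  }
  a1 <- suppressWarnings(as.integer(h1))
  a2 <- suppressWarnings(as.integer(h2))
  a2[!is.na(gt) & h2 == "."] <- NA_integer_
  # polarize: when the ancestral allele is ALT, flip 0 <-> 1
  flip <- aa == alt
  dim(a1) <- dim(a2) <- c(nSite, nSamp)
  a1[flip, ] <- 1L - a1[flip, ]
  a2[flip, ] <- 1L - a2[flip, ]

  alleles <- matrix(NA_integer_, nrow = 2L * nSamp, ncol = nSite)
  alleles[seq(1L, 2L * nSamp, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * nSamp, by = 2L), ] <- t(a2)

  pops <- panel$population[match(samples, panel$sample)]
  HaplotypeSet(alleles, chrom = chrom, pos = pos, sampleIds = samples,
               populations = pops,
               metadata = list(dropReport = list(
                 nMultiallelicOrIndel = nMulti,
                 nAncestralMissing = nAaMissing,
                 nAncestralMismatch = nAaMismatch,
                 nKept = nSite)))
}

readPanel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample))
    stop("duplicated sample id(s) in panel: ", path)
  tab
}

lookupAncestral <- function(path, chrom, pos) {
  if (!file.exists(path)) stop("ancestral allele table not found: ", path)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "pos", "allele"))
  idx <- match(paste(chrom, pos), paste(tab$chrom, tab$pos))
  toupper(ifelse(is.na(idx), NA_character_, tab$allele[idx]))
}

#' Read gene intervals from a BED4 file
#'
#' Reads a 4+ column BED file (chrom, start, end, name; 0-based half-open
#' per the BED standard) into a \code{GRanges} of 1-based closed gene
#' intervals, named by gene id.
#'
#' @param bedPath path to a BED4(+) file.
#' @return a \code{GRanges} with \code{gene_id} metadata column and names.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tgeneA", f)
#' readGenes(f)  # covers 1-based positions 101..200
#' @export
readGenes <- function(bedPath) {
  if (!file.exists(bedPath)) stop("BED file not found: ", bedPath)
  lines <- readLines(bedPath)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$gene_id <- character(0)
    return(gr)
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n < 4L))
    stop("malformed BED line ", lineNo[which(n < 4L)[1L]],
         ": fewer than 4 fields")
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  name <- vapply(fields, `[`, "", 4L)
  bad <- is.na(start0) | is.na(end0)
  if (any(bad))
    stop("malformed BED line ", lineNo[which(bad)[1L]],
         ": non-integer coordinates")
  if (any(start0 >= end0))
    stop("malformed BED line ", lineNo[which(start0 >= end0)[1L]],
         ": start >= end")
  if (anyDuplicated(name))
    stop("duplicated gene id(s) in BED: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  strand <- rep("*", length(lines))
  has6 <- n >= 6L
  strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = strand, gene_id = name)
  names(gr) <- name
  gr
}

#' Read gene-set membership lists
#'
#' Each file holds one gene id per line; duplicates within a file are
#' collapsed. Labels (list names) must be unique and non-empty.
#'
#' @param paths named character vector of file paths; names are set labels
#'   (e.g. \code{c(CGC = "cgc.txt", TAG = "tag.txt")}).
#' @return named list of unique gene-id character vectors.
#' @export
readGeneSets <- function(paths) {
  labels <- names(paths)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("every gene-set path must carry a non-empty label")
  if (anyDuplicated(labels)) stop("gene-set labels must be unique")
  out <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[[i]]))
      stop("gene-set file not found: ", paths[[i]])
    ids <- trimws(readLines(paths[[i]]))
    unique(ids[nzchar(ids)])
  })
  names(out) <- labels
  out
}

#' Write / read a score table as TSV
#'
#' Tab-separated serialization for the per-site, per-gene and per-window
#' score tables. Columns keep their order; numeric values are written with
#' 8 significant digits; missing values appear as the literal \code{NA}.
#' \code{readScores} reads such a file back.
#'
#' @param table a data.frame (SiteStats, GeneScore or WindowScore table).
#' @param path output (input) file path.
#' @return \code{writeScores}: the path, invisibly; \code{readScores}: a
#'   data.frame.
#' @export
writeScores <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.8g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}
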