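#' Configuration for a full composite scan
#'
#' Describes one reproducible end-to-end run: either file inputs (VCF +
#' panel + BED + gene-set lists) or a simulation config, the population
#' contrast, the iFXD method set, all thresholds, and the output
#' directory.
#'
#' @param vcf,panel,bed optional input file paths (all three required for
#'   a file-based run); \code{geneSets} a named vector of gene-set list
#'   paths.
#' @param simConfig optional [simulationConfig()]; used when file inputs
#'   are absent.
#' @param highland,lowland population labels (defaults match the
#'   simulator's).
#' @param methods iFXD method set, see [siteStats()].
#' @param mafFilter,ehhCutoff,maxGap haplotype-statistic parameters.
#' @param ihsSigThreshold,xpehhSigThreshold gene-level significance
#'   count thresholds.
#' @param windowSize,windowStep sliding-window parameters in bp.
#' @param topK genes listed in the top-k report.
#' @param outDir output directory for [runScan()].
#' @param seed integer seed governing any randomness in the run.
#' @return list of class \code{ScanConfig}.
#' @export
scanConfig <- function(vcf = NULL, panel = NULL, bed = NULL,
                       geneSets = NULL, simConfig = NULL,
                       highland = "highland", lowland = "lowland",
                       methods = c("fst", "xpehh", "ddaf"),
                       mafFilter = 0.05, ehhCutoff = 0.05,
                       maxGap = 200000, ihsSigThreshold = 2,
                       xpehhSigThreshold = 2, windowSize = 50000,
                       windowStep = 25000, topK = 2,
                       outDir = "popsweep_run", seed = 1) {
  if (windowSize < windowStep) stop("window size must be >= step")
  if (topK < 1) stop("topK must be >= 1")
  fileMode <- !is.null(vcf)
  if (fileMode && (is.null(panel) || is.null(bed)))
    stop("file-based runs need vcf, panel and bed paths")
  if (!fileMode && is.null(simConfig))
    stop("provide either file inputs or a simulation config")
  cfg <- list(vcf = vcf, panel = panel, bed = bed, geneSets = geneSets,
              simConfig = simConfig, highland = highland,
              lowland = lowland, methods = methods,
              mafFilter = mafFilter, ehhCutoff = ehhCutoff,
              maxGap = maxGap, ihsSigThreshold = ihsSigThreshold,
              xpehhSigThreshold = xpehhSigThreshold,
              windowSize = windowSize, windowStep = windowStep,
              topK = topK, outDir = outDir, seed = as.integer(seed))
  class(cfg) <- "ScanConfig"
  cfg
}

#' Run the full composite selection scan
#'
#' Executes input loading (or simulation), per-site statistics, haplotype
#' statistics, the iFXD composite, gene aggregation/ranking, the
#' sliding-window empirical p scan, and gene-set enrichment, writing all
#' artifacts into the configured output directory: \code{sites.tsv},
#' \code{genes.tsv}, \code{windows.tsv}, \code{topk.json},
#' \code{enrichment.tsv} (when gene sets are available) and
#' \code{manifest.json} (config, package version, seed, per-stage row and
#' drop counts). Identical config and inputs give byte-identical outputs.
#'
#' @param config a [scanConfig()].
#' @return invisibly, a list with the in-memory tables
#'   (\code{sites}, \code{genes}, \code{windows}, \code{enrichment},
#'   \code{topK}) and the output directory.
#' @export
runScan <- function(config) {
  stopifnot(inherits(config, "ScanConfig"))
  set.seed(config$seed)
  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$vcf)) {
      hapset <- readHaplotypes(config$vcf, config$panel)
      genes <- readGenes(config$bed)
      catalog <- if (length(config$geneSets))
        readGeneSets(config$geneSets) else list()
      truth <- NULL
    } else {
      sim <- simulateTwoPop(config$simConfig)
      hapset <- sim$haplotypes
      genes <- sim$genes
      catalog <- sim$geneSets
      truth <- sim$truth
    }
    for (lab in c(config$highland, config$lowland)) {
      if (!lab %in% populationNames(hapset))
        stop("population '", lab, "' absent from the panel")
    }

    stage <- "persite_and_haplotype_stats"
    sites <- siteStats(hapset, config$highland, config$lowland,
                       methods = config$methods,
                       mafFilter = config$mafFilter,
                       cutoff = config$ehhCutoff,
                       maxGap = config$maxGap)

    stage <- "gene_scores"
    gsc <- geneScores(sites, genes,
                      ihsSigThreshold = config$ihsSigThreshold,
                      xpehhSigThreshold = config$xpehhSigThreshold,
                      topK = config$topK)

    stage <- "window_scan"
    win <- windowScan(sites$chrom, sites$pos, sites$ifxd,
                      size = config$windowSize, step = config$windowStep)

    stage <- "enrichment"
    enr <- NULL
    if (length(catalog)) {
      enr <- enrichmentTable(sites, genes, catalog,
        statistics = intersect(c("fst", "xpehhStd", "deltaDaf",
                                 "ihsStd"), names(sites)))
    }

    stage <- "output"
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeScores(sites, file.path(config$outDir, "sites.tsv"))
    writeScores(gsc, file.path(config$outDir, "genes.tsv"))
    writeScores(win, file.path(config$outDir, "windows.tsv"))
    if (!is.null(enr))
      writeScores(enr, file.path(config$outDir, "enrichment.tsv"))
    jsonlite::write_json(
      list(topK = attr(gsc, "topK")),
      file.path(config$outDir, "topk.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

    manifest <- list(
      package = "popsweep",
      version = as.character(utils::packageVersion("popsweep")),
      seed = config$seed,
      highland = config$highland, lowland = config$lowland,
      methods = config$methods,
      parameters = config[c("mafFilter", "ehhCutoff", "maxGap",
                            "ihsSigThreshold", "xpehhSigThreshold",
                            "windowSize", "windowStep", "topK")],
      counts = list(
        nHaplotypes = nHaplotypes(hapset),
        nSitesIn = nSites(hapset),
        nSitesCompositeScored = sum(!is.na(sites$ifxd)),
        nSitesCompositeSkipped = attr(sites, "nSkipped"),
        nGenesScored = nrow(gsc),
        nGenesOmitted = attr(gsc, "nOmitted"),
        nWindows = nrow(win)),
      dropReport = hapset@metadata$dropReport)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    list(sites = sites, genes = gsc, windows = win,
         enrichment = enr, topK = attr(gsc, "topK"),
         truth = truth, outDir = config$outDir)
  }, error = function(e) {
    stop("scan failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
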