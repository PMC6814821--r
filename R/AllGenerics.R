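#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("siteChromosomes", function(x) standardGeneric("siteChromosomes"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("haplotypePopulations", function(x) standardGeneric("haplotypePopulations"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname HaplotypeSet-accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
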