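#' @rdname SpatialGraph-class
#' @param object,x an object.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname SpatialGraph-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname SpatialGraph-class
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @rdname ICARStructure-class
#' @export
setGeneric("icarPrecision", function(x) standardGeneric("icarPrecision"))

#' @rdname ICARStructure-class
#' @export
setGeneric("icarComponents", function(x) standardGeneric("icarComponents"))

#' @rdname ICARStructure-class
#' @export
setGeneric("icarRank", function(x) standardGeneric("icarRank"))

#' @rdname RegionYearPanel-class
#' @export
setGeneric("panelOutcomes", function(x) standardGeneric("panelOutcomes"))

#' @rdname RegionYearPanel-class
#' @export
setGeneric("panelCovariates", function(x) standardGeneric("panelCovariates"))

#' @rdname PosteriorSamples-class
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' Extract a matrix of posterior draws
#'
#' @param x a [PosteriorSamples-class] object.
#' @param pattern optional regular expression selecting parameter columns
#'   (e.g. `"^beta\\."`, `"^b\\."`); `NULL` keeps all.
#' @param combine if `TRUE` (default) chains are stacked row-wise; otherwise a
#'   list of per-chain matrices is returned.
#' @return numeric matrix (or list of matrices) of draws.
#' @export
setGeneric("drawMatrix",
  function(x, pattern = NULL, combine = TRUE) standardGeneric("drawMatrix"))
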