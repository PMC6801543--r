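#' @include AllClasses.R
NULL

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("gridUnits", function(x) standardGeneric("gridUnits"))

#' @export
setGeneric("normalizeMinMax", function(x, ...) standardGeneric("normalizeMinMax"))

#' @export
setGeneric("gridComplement", function(x) standardGeneric("gridComplement"))

#' @export
setGeneric("resampleMean", function(x, factor) standardGeneric("resampleMean"))

#' @export
setGeneric("processName", function(x) standardGeneric("processName"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
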