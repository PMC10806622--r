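#' @title Accessor generics
#' @description Read-only accessors for the package's S4 containers.
#' @param x An object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x) standardGeneric("boxLengths"))

#' @rdname accessors
#' @export
setGeneric("atomLabels", function(x) standardGeneric("atomLabels"))

#' @rdname accessors
#' @export
setGeneric("moleculeIndex", function(x) standardGeneric("moleculeIndex"))

#' @rdname accessors
#' @export
setGeneric("rGrid", function(x) standardGeneric("rGrid"))

#' @rdname accessors
#' @export
setGeneric("qGrid", function(x) standardGeneric("qGrid"))

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname accessors
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname accessors
#' @export
setGeneric("gValues", function(x) standardGeneric("gValues"))

#' @rdname accessors
#' @export
setGeneric("partnerDensity", function(x) standardGeneric("partnerDensity"))

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("signalTerms", function(x) standardGeneric("signalTerms"))
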