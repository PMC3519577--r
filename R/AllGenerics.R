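#' @include AllClasses.R
NULL

#' @rdname TwinBetaSet-class
#' @export
setGeneric("betaValues", function(x, ...) standardGeneric("betaValues"))

#' @rdname TwinBetaSet-class
#' @export
setGeneric("studyDesign", function(x, ...) standardGeneric("studyDesign"))

#' @rdname TwinBetaSet-class
#' @export
setGeneric("probeManifest", function(x, ...) standardGeneric("probeManifest"))

#' @rdname TwinBetaSet-class
#' @export
setGeneric("pairIds", function(x, ...) standardGeneric("pairIds"))

#' @rdname TwinBetaSet-class
#' @export
setGeneric("nPairs", function(x, ...) standardGeneric("nPairs"))

#' @rdname completePairs
#' @export
setGeneric("completePairs", function(x, probe, ...) standardGeneric("completePairs"))
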