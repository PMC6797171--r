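#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))

#' @export
setGeneric("pairSummary", function(x, ...) standardGeneric("pairSummary"))

#' @export
setGeneric("pdUnion", function(x, ...) standardGeneric("pdUnion"))

#' @export
setGeneric("meanPdFstMatrix", function(x, ...) standardGeneric("meanPdFstMatrix"))
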