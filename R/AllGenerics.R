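#' @rdname AluLocusSet-class
#' @param x,object An `AluLocusSet`.
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))

#' @rdname AluLocusSet-class
#' @export
setGeneric("lociSeqs", function(x) standardGeneric("lociSeqs"))

#' @rdname AluLocusSet-class
#' @export
setGeneric("lociRanges", function(x) standardGeneric("lociRanges"))

#' @rdname AluLocusSet-class
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname ConsensusLibrary-class
#' @param x A `ConsensusLibrary`.
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))

#' @rdname ConsensusLibrary-class
#' @export
setGeneric("ageClasses", function(x) standardGeneric("ageClasses"))
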