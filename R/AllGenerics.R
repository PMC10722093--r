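#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' Query read depth at reference positions
#'
#' @param x a [DepthTrack-class].
#' @param contig contig name.
#' @param pos0 integer vector of 0-based positions.
#' @return integer vector of depths; positions outside the track are 0.
#' @export
setGeneric("depthAt", function(x, contig, pos0) standardGeneric("depthAt"))

#' Realize a target or template sequence for one grouped allele
#'
#' @param x a [TargetSeq-class] or [DesignTemplate-class].
#' @param ... further arguments (see methods).
#' @return a character scalar, the allele-realized sequence.
#' @export
setGeneric("realizedSeq", function(x, ...) standardGeneric("realizedSeq"))
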