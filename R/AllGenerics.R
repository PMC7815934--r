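#' @export
setGeneric("vertexCount", function(x) standardGeneric("vertexCount"))

#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @export
setGeneric("degree", function(x, v) standardGeneric("degree"))

#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @export
setGeneric("nGraphs", function(x) standardGeneric("nGraphs"))

#' @export
setGeneric("graphLabels", function(x) standardGeneric("graphLabels"))

#' @export
setGeneric("isWeighted", function(x) standardGeneric("isWeighted"))

#' @export
setGeneric("libraries", function(x) standardGeneric("libraries"))

#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))

#' @export
setGeneric("spikes", function(x) standardGeneric("spikes"))
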