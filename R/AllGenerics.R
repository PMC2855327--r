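#' @rdname nodes
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("graphName", function(x) standardGeneric("graphName"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("totalWeight", function(x) standardGeneric("totalWeight"))

#' @rdname accessors
#' @export
setGeneric("graphs", function(x) standardGeneric("graphs"))

#' @rdname accessors
#' @export
setGeneric("commonTotal", function(x) standardGeneric("commonTotal"))

#' @rdname accessors
#' @export
setGeneric("alphas", function(x) standardGeneric("alphas"))

#' @rdname accessors
#' @export
setGeneric("alphas<-", function(x, value) standardGeneric("alphas<-"))

#' @rdname accessors
#' @export
setGeneric("className", function(x) standardGeneric("className"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("modularityMatrix", function(x) standardGeneric("modularityMatrix"))

#' @rdname accessors
#' @export
setGeneric("minModularityScores", function(x) standardGeneric("minModularityScores"))

#' @rdname accessors
#' @export
setGeneric("treeLeaves", function(x) standardGeneric("treeLeaves"))
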