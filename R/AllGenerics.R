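# Generics for the graph containers.

#' @rdname DirectedGraph-class
#' @param x a graph-like object.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname DirectedGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname DirectedGraph-class
#' @export
setGeneric("edgeDensity", function(x) standardGeneric("edgeDensity"))

#' @rdname DirectedGraph-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname DirectedGraph-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname Multigraph-class
#' @param x a graph-like object.
#' @export
setGeneric("outDegrees", function(x) standardGeneric("outDegrees"))

#' @rdname Multigraph-class
#' @export
setGeneric("inDegrees", function(x) standardGeneric("inDegrees"))

#' @rdname Multigraph-class
#' @export
setGeneric("symPart", function(x) standardGeneric("symPart"))

#' @rdname Multigraph-class
#' @export
setGeneric("asymPart", function(x) standardGeneric("asymPart"))

#' @rdname Multigraph-class
#' @export
setGeneric("reciprocatedEdgeCount", function(x) standardGeneric("reciprocatedEdgeCount"))

#' @rdname Multigraph-class
#' @export
setGeneric("nonReciprocatedEdgeCount", function(x) standardGeneric("nonReciprocatedEdgeCount"))

#' @rdname MotifSet-class
#' @param x an object holding a motif multiset.
#' @export
setGeneric("motifIds", function(x) standardGeneric("motifIds"))

#' @rdname MotifSet-class
#' @export
setGeneric("multiplicities", function(x) standardGeneric("multiplicities"))
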