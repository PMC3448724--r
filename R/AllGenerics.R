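#' @rdname HybridNetwork-accessors
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))

#' @rdname HybridNetwork-accessors
#' @export
setGeneric("nodeKinds", function(object) standardGeneric("nodeKinds"))

#' @rdname HybridNetwork-accessors
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname HybridNetwork-accessors
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname HybridNetwork-accessors
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname neighbors
#' @export
setGeneric("neighbors", function(object, node) standardGeneric("neighbors"))

#' @rdname LabelTable-accessors
#' @export
setGeneric("membershipMatrix",
           function(object) standardGeneric("membershipMatrix"))

#' @rdname LabelTable-accessors
#' @export
setGeneric("nodeClasses", function(object, node)
  standardGeneric("nodeClasses"))

#' @rdname LabelTable-accessors
#' @export
setGeneric("labelCounts", function(object) standardGeneric("labelCounts"))
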