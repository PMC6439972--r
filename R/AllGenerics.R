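#' @rdname CandidateVertex-class
#' @param x a vertex, graph or prediction object
#' @export
setGeneric("vertexPairs", function(x) standardGeneric("vertexPairs"))

#' @rdname CandidateVertex-class
#' @export
setGeneric("vertexEnergy", function(x) standardGeneric("vertexEnergy"))

#' @rdname CandidateVertex-class
#' @export
setGeneric("vertexWeight", function(x) standardGeneric("vertexWeight"))

#' @rdname CandidateVertex-class
#' @export
setGeneric("isEmptyVertex", function(x) standardGeneric("isEmptyVertex"))

#' @rdname CandidateVertex-class
#' @export
setGeneric("isPseudoknotted", function(x) standardGeneric("isPseudoknotted"))

#' @rdname StrandSet-class
#' @param x a StrandSet (or object holding one)
#' @export
setGeneric("strandIDs", function(x) standardGeneric("strandIDs"))

#' Pairwise compatibility of two candidate vertices
#'
#' Two candidates are incompatible exactly when (a) some nucleotide position
#' takes part in a base pair in both of them, or (b) both are secondary
#' structures of the same strand. Interleaved but position-disjoint pair
#' sets (crossing interactions, external pseudoknots) remain compatible:
#' any structural motif may appear in a complex.
#'
#' @param u,v candidate vertices
#' @return logical scalar; the relation is symmetric.
#' @examples
#' s <- structureVertex("A", cbind(0L, 9L))
#' i <- interactionVertex("A", "B", cbind(0L, 5L))
#' areCompatible(s, i)  # FALSE: position (A, 0) is paired in both
#' @export
setGeneric("areCompatible", function(u, v) standardGeneric("areCompatible"))
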