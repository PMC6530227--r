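#' @rdname ProteinGroup-class
#' @param x,object A package object.
#' @export
setGeneric("groupName", function(x) standardGeneric("groupName"))

#' @rdname ProteinGroup-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ProteinGroup-class
#' @param value Replacement value.
#' @export
setGeneric("classLabels<-",
           function(x, value) standardGeneric("classLabels<-"))

#' @rdname ProteinGroup-class
#' @export
setGeneric("residuePolicy", function(x) standardGeneric("residuePolicy"))

#' @rdname ProteinGroup-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Compute adjacency vectors
#'
#' @param x A [ProteinGroup], [Biostrings::AAStringSet], or character vector
#'   of sequences.
#' @param ... Passed between methods.
#' @return An [AdjacencySet].
#' @export
setGeneric("adjacencyVectors", function(x, ...)
    standardGeneric("adjacencyVectors"))

#' @rdname AdjacencySet-class
#' @param x An `AdjacencySet`.
#' @export
setGeneric("adjacencyCounts", function(x) standardGeneric("adjacencyCounts"))

#' @rdname AdjacencySet-class
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname AdjacencySet-class
#' @export
setGeneric("skippedPairs", function(x) standardGeneric("skippedPairs"))

#' Build the group representative vector
#'
#' @param x An [AdjacencySet] or [ProteinGroup].
#' @param ... Passed between methods.
#' @return A [GroupRepresentative].
#' @export
setGeneric("groupRepresentative", function(x, ...)
    standardGeneric("groupRepresentative"))

#' @rdname GroupRepresentative-class
#' @param x A `GroupRepresentative`.
#' @export
setGeneric("grValues", function(x) standardGeneric("grValues"))

#' @rdname GroupRepresentative-class
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))

#' @rdname GroupRepresentative-class
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))

#' Score a sample against a group representative
#'
#' @param x An [AdjacencySet] or [ProteinGroup].
#' @param gr A [GroupRepresentative]; by default the sample's own (computed
#'   on the fly).
#' @param ... Passed between methods.
#' @return A [SimilarityResult].
#' @export
setGeneric("similarityVector", function(x, gr = NULL, ...)
    standardGeneric("similarityVector"))

#' Cross-group comparison against a foreign representative
#'
#' @inheritParams similarityVector
#' @param gr A [GroupRepresentative] built from a different family.
#' @return A [SimilarityResult] tagged with both group names.
#' @export
setGeneric("crossGroup", function(x, gr, ...) standardGeneric("crossGroup"))

#' Conventional all-pairs distance matrix
#'
#' @param x An [AdjacencySet] or [ProteinGroup].
#' @param metric `"D"` (Euclidean magnitude) or `"theta"` (angle, radians).
#' @param ... Passed between methods.
#' @return Square symmetric numeric matrix with a zero diagonal and attribute
#'   `nEvaluations` equal to `n * (n - 1) / 2`.
#' @export
setGeneric("pairwiseMatrix", function(x, metric = c("D", "theta"), ...)
    standardGeneric("pairwiseMatrix"))

#' @rdname SimilarityResult-class
#' @param x A `SimilarityResult`.
#' @export
setGeneric("similarityTable", function(x) standardGeneric("similarityTable"))
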