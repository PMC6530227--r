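# Elementwise median of the member adjacency vectors.
#
# The standard median is used: middle order statistic for odd n, mean of
# the two central order statistics for even n. Values therefore stay exact
# (integers, or half-integers for even n) and are never rounded, because
# the D and theta statistics consume them directly.

#' @describeIn groupRepresentative Elementwise median over the columns of an
#'   adjacency set. A single-member set yields that member's own vector,
#'   with a warning.
#' @export
setMethod("groupRepresentative", "AdjacencySet", function(x, ...) {
    n <- ncol(x)
    if (n == 0L)
        stop("cannot build a representative from an empty sample")
    if (n == 1L)
        warning("representative of a single-member sample equals that ",
                "member's adjacency vector")
    cnt <- adjacencyCounts(x)
    vals <- apply(cnt, 1L, stats::median)
    names(vals) <- .PAIR_LABELS
    new("GroupRepresentative",
        groupName = groupName(x),
        values = vals,
        nSequences = as.integer(n),
        memberIds = colnames(x))
})

#' @describeIn groupRepresentative Convenience: compute the adjacency
#'   vectors of the family, then the representative.
#' @export
setMethod("groupRepresentative", "ProteinGroup", function(x, ...) {
    groupRepresentative(adjacencyVectors(x))
})

#' @describeIn GroupRepresentative-class The 400 named median values.
#' @export
setMethod("grValues", "GroupRepresentative", function(x) x@values)

#' @describeIn GroupRepresentative-class Number of member sequences.
#' @export
setMethod("nSequences", "GroupRepresentative", function(x) x@nSequences)

#' @describeIn GroupRepresentative-class Member ids in input order.
#' @export
setMethod("memberIds", "GroupRepresentative", function(x) x@memberIds)

#' @describeIn GroupRepresentative-class Group the representative summarises.
#' @export
setMethod("groupName", "GroupRepresentative", function(x) x@groupName)
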