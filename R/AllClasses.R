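#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ProteinGroup: a named family of protein sequences
#'
#' Container for one sequence family (a "group"): an [Biostrings::AAStringSet]
#' whose names are the record identifiers, the group label, optional per-record
#' class labels (e.g. coronavirus spike classes), and the residue-validation
#' policy the records were admitted under.
#'
#' Validity requires non-empty, uniquely named, non-zero-length sequences.
#' Under `policy = "strict"` every residue must be one of the 20 canonical
#' one-letter codes; under `"mask"` non-canonical characters are retained in
#' the sequence but every adjacent pair touching one is skipped during
#' counting; under `"drop"` they were removed before construction (joining
#' their neighbours).
#'
#' @slot groupName Single string, the family label.
#' @slot sequences [Biostrings::AAStringSet], names are record ids; the full
#'   FASTA headers, when read from file, are kept in
#'   `S4Vectors::mcols(sequences)$description`.
#' @slot classLabels Named character vector mapping record id to class label;
#'   length zero when no labels are attached.
#' @slot policy One of `"strict"`, `"mask"`, `"drop"`.
#'
#' @seealso [ProteinGroup()], [readProteinGroup()], [adjacencyVectors()]
#' @aliases ProteinGroup-class
#' @exportClass ProteinGroup
setClass("ProteinGroup",
    slots = c(
        groupName = "character",
        sequences = "AAStringSet",
        classLabels = "character",
        policy = "character"
    )
)

.validProteinGroup <- function(object) {
    msgs <- character()
    if (length(object@groupName) != 1L || is.na(object@groupName) ||
        !nzchar(object@groupName))
        msgs <- c(msgs, "groupName must be a single non-empty string")
    n <- length(object@sequences)
    if (n < 1L)
        msgs <- c(msgs, "a ProteinGroup must contain at least one record")
    ids <- names(object@sequences)
    if (is.null(ids) || any(!nzchar(ids)))
        msgs <- c(msgs, "every record must have a non-empty id")
    else if (anyDuplicated(ids))
        msgs <- c(msgs, paste0("duplicate record ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", ")))
    if (n >= 1L && any(Biostrings::width(object@sequences) == 0L))
        msgs <- c(msgs, "zero-length sequences are not allowed")
    if (length(object@policy) != 1L ||
        !object@policy %in% c("strict", "mask", "drop"))
        msgs <- c(msgs, "policy must be one of 'strict', 'mask', 'drop'")
    if (length(object@classLabels) > 0L) {
        if (is.null(names(object@classLabels)))
            msgs <- c(msgs, "classLabels must be named by record id")
        else {
            unknown <- setdiff(names(object@classLabels), ids)
            if (length(unknown))
                msgs <- c(msgs, paste0("classLabels name unknown ids: ",
                                       paste(unknown, collapse = ", ")))
        }
    }
    # strict policy guarantees the 20-letter alphabet
    if (identical(object@policy, "strict") && length(object@sequences)) {
        bad <- .nonCanonicalPositions(object@sequences)
        if (nrow(bad))
            msgs <- c(msgs, sprintf(
                "non-canonical residue '%s' in record '%s' at position %d (policy = strict)",
                bad$char[1L], bad$id[1L], bad$pos[1L]))
    }
    if (length(msgs)) msgs else TRUE
}
setValidity("ProteinGroup", .validProteinGroup)

#' AdjacencySet: adjacency vectors of a sequence family
#'
#' The 400-element adjacency vectors of all members of a [ProteinGroup],
#' stored as a [SummarizedExperiment::SummarizedExperiment] with one row per
#' ordered residue pair (rownames `AA` ... `VV` in canonical layout order) and
#' one column per sequence. Assay `"counts"` holds the integer pair counts;
#' `colData` records each sequence's length, its number of counted pairs and
#' the number of pairs skipped under the masking policy. Metadata keeps the
#' group name and the residue policy.
#'
#' For every column, `sum(counts) + skippedPairs = max(seqLength - 1, 0)`:
#' a length-L sequence read left to right with a width-2 sliding window
#' yields L - 1 ordered pairs.
#'
#' @seealso [adjacencyVectors()], [adjacencyCounts()], [groupRepresentative()]
#' @aliases AdjacencySet-class AdjacencySet
#' @exportClass AdjacencySet
setClass("AdjacencySet", contains = "SummarizedExperiment")

.validAdjacencySet <- function(object) {
    msgs <- character()
    if (nrow(object) != 400L)
        msgs <- c(msgs, "an AdjacencySet must have exactly 400 rows")
    else if (!identical(rownames(object), .PAIR_LABELS))
        msgs <- c(msgs, "rownames must be the canonical pair labels AA..VV")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msgs <- c(msgs, "assay 'counts' is required")
    else {
        cnt <- SummarizedExperiment::assay(object, "counts")
        if (any(cnt < 0L) || any(cnt != round(cnt)))
            msgs <- c(msgs, "counts must be non-negative integers")
    }
    cd <- SummarizedExperiment::colData(object)
    need <- c("seqLength", "nPairs", "skippedPairs")
    if (!all(need %in% colnames(cd)))
        msgs <- c(msgs, paste0("colData must contain ",
                               paste(need, collapse = ", ")))
    else if (ncol(object)) {
        cnt <- SummarizedExperiment::assay(object, "counts")
        expected <- pmax(cd$seqLength - 1L, 0L) - cd$skippedPairs
        if (!all(colSums(cnt) == expected))
            msgs <- c(msgs,
                "column sums must equal max(seqLength - 1, 0) - skippedPairs")
    }
    if (length(msgs)) msgs else TRUE
}
setValidity("AdjacencySet", .validAdjacencySet)

#' GroupRepresentative: the median descriptor of a family
#'
#' The group representative vector: each of its 400 elements is the median of
#' the corresponding elements across the member adjacency vectors. With an
#' even number of members the standard median (mean of the two central order
#' statistics) can yield half-integers; values are kept exact, never rounded.
#'
#' @slot groupName Single string, the family the representative summarises.
#' @slot values Named numeric vector of length 400 (names `AA` ... `VV`),
#'   non-negative, integers or half-integers.
#' @slot nSequences Number of member sequences the medians were taken over.
#' @slot memberIds Character vector of member ids, in input order.
#'
#' @seealso [groupRepresentative()], [grValues()], [similarityVector()]
#' @aliases GroupRepresentative-class GroupRepresentative
#' @exportClass GroupRepresentative
setClass("GroupRepresentative",
    slots = c(
        groupName = "character",
        values = "numeric",
        nSequences = "integer",
        memberIds = "character"
    )
)

.validGroupRepresentative <- function(object) {
    msgs <- character()
    if (length(object@values) != 400L)
        msgs <- c(msgs, "values must have length 400")
    else if (!identical(names(object@values), .PAIR_LABELS))
        msgs <- c(msgs, "values must be named by the canonical pair labels")
    if (any(object@values < 0))
        msgs <- c(msgs, "representative values must be non-negative")
    if (length(object@nSequences) != 1L || object@nSequences < 1L)
        msgs <- c(msgs, "nSequences must be a single positive integer")
    if (length(object@memberIds) != object@nSequences)
        msgs <- c(msgs, "memberIds must have length nSequences")
    if (length(msgs)) msgs else TRUE
}
setValidity("GroupRepresentative", .validGroupRepresentative)

#' SimilarityResult: per-sequence similarity to a representative
#'
#' One entry per member of a sample, in input order, each holding the two
#' dissimilarity statistics against a group representative: `D`, the
#' Euclidean magnitude of the difference between the adjacency vector and the
#' representative, and `theta`, the angle between the two vectors in radians
#' (`acos` of their cosine similarity, clamped to `[-1, 1]`). The number of
#' entries equals the number of sequences in the sample; each statistic is
#' evaluated exactly once per sequence, which is the linear-cost advantage of
#' the similarity vector over the quadratic all-pairs matrix.
#'
#' `sampleGroup` and `grGroup` differ in a cross-group comparison, where a
#' sample is scored against a foreign family's representative.
#'
#' @slot table [S4Vectors::DataFrame] with columns `id`, `D`, `theta`.
#' @slot sampleGroup Group name of the scored sample.
#' @slot grGroup Group name of the representative used.
#' @slot normalize Normalisation applied inside `D` (`"none"`, `"unit"` or
#'   `"length"`; `theta` is scale-free and unaffected).
#' @slot nEvaluations Number of statistic evaluations performed per metric.
#'
#' @seealso [similarityVector()], [crossGroup()], [pairwiseMatrix()]
#' @aliases SimilarityResult-class SimilarityResult
#' @exportClass SimilarityResult
setClass("SimilarityResult",
    slots = c(
        table = "DataFrame",
        sampleGroup = "character",
        grGroup = "character",
        normalize = "character",
        nEvaluations = "integer"
    )
)

.validSimilarityResult <- function(object) {
    msgs <- character()
    need <- c("id", "D", "theta")
    if (!all(need %in% colnames(object@table)))
        msgs <- c(msgs, "table must have columns id, D, theta")
    else {
        if (any(object@table$D < 0))
            msgs <- c(msgs, "D must be non-negative")
        th <- object@table$theta
        if (any(th < 0 | th > pi + 1e-12))
            msgs <- c(msgs, "theta must lie in [0, pi]")
    }
    if (length(msgs)) msgs else TRUE
}
setValidity("SimilarityResult", .validSimilarityResult)
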