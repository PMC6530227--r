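#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
NULL

# Count ordered adjacent residue pairs in one sequence.
# Returns list(counts = integer(400), skipped = integer(1)).
# A length-L sequence has L - 1 width-2 sliding windows; under policy
# "mask" a window touching a non-canonical character contributes nothing
# and is counted as skipped. Length <= 1 yields the zero vector.
.countPairs <- function(chars) {
    L <- length(chars)
    if (L < 2L)
        return(list(counts = integer(400L), skipped = 0L))
    idx <- match(chars, .RESIDUE_ORDER)
    i <- idx[-L]
    j <- idx[-1L]
    ok <- !is.na(i) & !is.na(j)
    counts <- tabulate((i[ok] - 1L) * 20L + j[ok], nbins = 400L)
    list(counts = counts, skipped = sum(!ok))
}

#' Adjacency vector of a single sequence
#'
#' Counts, for each of the 400 ordered pairs of canonical amino acids, how
#' often the pair occurs among the adjacent positions of the sequence read
#' left to right (sliding window of width 2, step 1). A length-L sequence
#' yields L - 1 ordered pairs; a pair that never occurs counts 0, so the
#' counts sum to L - 1 minus any pairs skipped by the masking policy.
#'
#' A length-1 sequence gives the all-zero vector with a warning (the angle
#' statistic rejects zero vectors downstream); an empty sequence is an
#' error.
#'
#' @param x A single sequence: character string or [Biostrings::AAString].
#' @param policy Residue policy (see [ProteinGroup()]): `"strict"` errors on
#'   non-canonical characters, `"mask"` skips pairs touching them, `"drop"`
#'   removes them first (joining neighbours).
#' @return Named integer vector of length 400 (names `AA` ... `VV`), with
#'   attribute `skipped` giving the number of masked pairs.
#' @examples
#' v <- adjacencyVector("WTFE")
#' v[v > 0]
#' sum(adjacencyVector("AA"))  # one pair, A followed by A
#' @export
adjacencyVector <- function(x, policy = c("strict", "mask", "drop")) {
    policy <- match.arg(policy)
    x <- toupper(as.character(x))
    if (length(x) != 1L)
        stop("adjacencyVector() takes a single sequence; ",
             "use adjacencyVectors() for a set")
    if (!nzchar(x))
        stop("empty sequence")
    chars <- strsplit(x, "", fixed = TRUE)[[1L]]
    bad <- !chars %in% .RESIDUE_ORDER
    if (any(bad)) {
        if (policy == "strict")
            stop(sprintf("non-canonical residue '%s' at position %d (policy = strict)",
                         chars[which(bad)[1L]], which(bad)[1L]))
        if (policy == "drop") {
            chars <- chars[!bad]
            if (!length(chars))
                stop("sequence empty after dropping non-canonical residues")
        }
    }
    if (length(chars) == 1L)
        warning("length-1 sequence yields the all-zero adjacency vector")
    res <- .countPairs(chars)
    out <- res$counts
    names(out) <- .PAIR_LABELS
    attr(out, "skipped") <- res$skipped
    out
}

.buildAdjacencySet <- function(seqStrings, ids, groupName, policy) {
    n <- length(seqStrings)
    counts <- matrix(0L, nrow = 400L, ncol = n,
                     dimnames = list(.PAIR_LABELS, ids))
    skipped <- integer(n)
    lens <- integer(n)
    for (k in seq_len(n)) {
        chars <- strsplit(seqStrings[k], "", fixed = TRUE)[[1L]]
        if (policy == "drop")
            chars <- chars[chars %in% .RESIDUE_ORDER]
        lens[k] <- length(chars)
        if (length(chars) < 2L)
            warning("sequence '", ids[k],
                    "' has fewer than 2 residues; its adjacency vector is all zero")
        res <- .countPairs(chars)
        counts[, k] <- res$counts
        skipped[k] <- res$skipped
    }
    first <- rep(.RESIDUE_ORDER, each = 20L)
    second <- rep(.RESIDUE_ORDER, times = 20L)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(first = first, second = second,
                            row.names = .PAIR_LABELS),
        colData = DataFrame(seqLength = lens,
                            nPairs = pmax(lens - 1L, 0L) - skipped,
                            skippedPairs = skipped,
                            row.names = ids))
    metadata(se)$groupName <- groupName
    metadata(se)$policy <- policy
    new("AdjacencySet", se)
}

#' @describeIn adjacencyVectors Adjacency vectors of all members of a
#'   validated family; the group name and residue policy are carried over.
#' @export
setMethod("adjacencyVectors", "ProteinGroup", function(x, ...) {
    .buildAdjacencySet(as.character(x@sequences), names(x@sequences),
                       x@groupName, x@policy)
})

#' @describeIn adjacencyVectors Adjacency vectors of a named
#'   [Biostrings::AAStringSet].
#' @param policy Residue policy (see [ProteinGroup()]).
#' @param groupName Group label to record in the result.
#' @export
setMethod("adjacencyVectors", "AAStringSet",
    function(x, policy = c("strict", "mask", "drop"), groupName = "sample",
             ...) {
    policy <- match.arg(policy)
    pg <- ProteinGroup(groupName, x, policy = policy)
    adjacencyVectors(pg)
})

#' @describeIn adjacencyVectors Adjacency vectors of a named character
#'   vector of sequences.
#' @export
setMethod("adjacencyVectors", "character",
    function(x, policy = c("strict", "mask", "drop"), groupName = "sample",
             ...) {
    policy <- match.arg(policy)
    if (is.null(names(x)))
        names(x) <- paste0("seq", seq_along(x))
    adjacencyVectors(AAStringSet(x), policy = policy, groupName = groupName)
})

#' @describeIn AdjacencySet-class Integer matrix of pair counts
#'   (400 rows, one column per sequence).
#' @export
setMethod("adjacencyCounts", "AdjacencySet", function(x)
    assay(x, "counts"))

#' @describeIn AdjacencySet-class Residue lengths of the source sequences
#'   (after any `drop` policy).
#' @export
setMethod("seqLengths", "AdjacencySet", function(x)
    stats::setNames(colData(x)$seqLength, colnames(x)))

#' @describeIn AdjacencySet-class Number of sliding-window pairs skipped per
#'   sequence under the masking policy (0 under `strict`).
#' @export
setMethod("skippedPairs", "AdjacencySet", function(x)
    stats::setNames(colData(x)$skippedPairs, colnames(x)))

#' @describeIn AdjacencySet-class Group name recorded at construction.
#' @export
setMethod("groupName", "AdjacencySet", function(x)
    metadata(x)$groupName)
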