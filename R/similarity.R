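# The two dissimilarity statistics between a sequence's adjacency vector
# and a group representative:
#   D     = Euclidean norm of the elementwise difference (magnitude)
#   theta = acos of the cosine similarity, in radians (scale-free)
# Both are evaluated once per sequence against the representative, so a
# sample of n sequences costs n evaluations per metric, versus the
# n (n - 1) / 2 evaluations of the conventional all-pairs matrix.

.asVec400 <- function(x, what = "vector") {
    if (is(x, "GroupRepresentative")) x <- x@values
    x <- as.numeric(x)
    if (length(x) != 400L)
        stop(what, " must have length 400, got ", length(x))
    x
}

#' Magnitude of the difference between two descriptors
#'
#' The Euclidean norm of the elementwise difference between an adjacency
#' vector and a representative (or any two 400-element descriptors). By
#' default the raw count vectors are used. Two optional normalisation modes
#' are provided for exploration: `"unit"` divides each vector by its own
#' Euclidean norm before differencing, and `"length"` divides each vector by
#' its total pair count. `D` is a true metric on descriptors (symmetric,
#' zero iff the vectors are identical, triangle inequality).
#'
#' @param a,b Numeric vectors of length 400, or a [GroupRepresentative].
#' @param normalize `"none"` (default), `"unit"` or `"length"`.
#' @return Single non-negative number.
#' @examples
#' gr <- rep(0, 400); a <- gr; a[1] <- 3
#' magnitudeD(a, gr)  # 3
#' @export
magnitudeD <- function(a, b, normalize = c("none", "unit", "length")) {
    normalize <- match.arg(normalize)
    a <- .asVec400(a, "a")
    b <- .asVec400(b, "b")
    if (normalize == "unit") {
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0 || nb == 0)
            stop("cannot unit-normalize a zero vector")
        a <- a / na; b <- b / nb
    } else if (normalize == "length") {
        sa <- sum(a); sb <- sum(b)
        if (sa == 0 || sb == 0)
            stop("cannot length-normalize a zero-count vector")
        a <- a / sa; b <- b / sb
    }
    sqrt(sum((a - b)^2))
}

#' Angle between two descriptors
#'
#' The angle in radians between an adjacency vector and a representative:
#' the arccosine of their cosine similarity. It is evaluated in the
#' numerically stable chord form `2*asin(|u - v|/2)` on the unit-normalised
#' vectors, with the argument clamped to `[-1, 1]`, so floating-point
#' overshoot cannot produce `NaN` at either the parallel (`cos = 1`) or the
#' antiparallel (`cos = -1`) limit and tiny angles keep full relative
#' accuracy. The angle is
#' invariant under positive rescaling of either vector, which makes it
#' insensitive to sequence length; it is 0 iff the vectors are positive
#' scalar multiples of each other, and `pi/2` for vectors with disjoint
#' support. Zero-norm inputs (from length-1 sequences, or an all-zero
#' representative) are rejected because the angle is undefined.
#'
#' @inheritParams magnitudeD
#' @param degrees If `TRUE`, return degrees instead of radians.
#' @return Single number in `[0, pi]` radians (or `[0, 180]` degrees).
#' @examples
#' a <- c(1, 2, rep(0, 398))
#' angleTheta(a, 10 * a)       # 0: parallel
#' b <- c(0, 0, 5, rep(0, 397))
#' angleTheta(a, b) - pi / 2   # orthogonal supports
#' @export
angleTheta <- function(a, b, degrees = FALSE) {
    a <- .asVec400(a, "a")
    b <- .asVec400(b, "b")
    ma <- max(abs(a))
    mb <- max(abs(b))
    if (ma == 0)
        stop("first vector has zero norm; the angle is undefined")
    if (mb == 0)
        stop("second vector has zero norm; the angle is undefined")
    # scale by the largest component first so extreme magnitudes cannot
    # overflow, then use the chord form 2*asin(|u - v|/2), which equals
    # acos(cos similarity) but is exact at the parallel limit and clamps
    # the antiparallel one
    u <- a / ma; u <- u / sqrt(sum(u^2))
    v <- b / mb; v <- v / sqrt(sum(v^2))
    theta <- 2 * asin(min(1, 0.5 * sqrt(sum((u - v)^2))))
    if (degrees) theta * 180 / pi else theta
}

.similarityCore <- function(aset, gr, normalize, grGroupOverride = NULL) {
    cnt <- adjacencyCounts(aset)
    n <- ncol(cnt)
    ids <- colnames(cnt)
    D <- numeric(n)
    theta <- numeric(n)
    for (k in seq_len(n)) {
        D[k] <- magnitudeD(cnt[, k], gr@values, normalize = normalize)
        theta[k] <- tryCatch(
            angleTheta(cnt[, k], gr@values),
            error = function(e) stop("record '", ids[k], "': ",
                                     conditionMessage(e), call. = FALSE))
    }
    grGroup <- if (is.null(grGroupOverride)) gr@groupName else
        grGroupOverride
    new("SimilarityResult",
        table = DataFrame(id = ids, D = D, theta = theta),
        sampleGroup = groupName(aset),
        grGroup = grGroup,
        normalize = normalize,
        nEvaluations = as.integer(n))
}

#' @describeIn similarityVector One `(D, theta)` entry per member of the
#'   adjacency set, in input order, against `gr` (the set's own
#'   representative when `gr` is `NULL`). Exactly `n` statistic evaluations
#'   are performed per metric.
#' @param normalize Normalisation mode for `D` (see [magnitudeD()]);
#'   `theta` is unaffected.
#' @export
setMethod("similarityVector", "AdjacencySet",
    function(x, gr = NULL, normalize = c("none", "unit", "length"), ...) {
    normalize <- match.arg(normalize)
    if (is.null(gr))
        gr <- suppressWarnings(groupRepresentative(x))
    stopifnot(is(gr, "GroupRepresentative"))
    .similarityCore(x, gr, normalize)
})

#' @describeIn similarityVector Convenience for a [ProteinGroup]: adjacency
#'   vectors are computed first.
#' @export
setMethod("similarityVector", "ProteinGroup",
    function(x, gr = NULL, normalize = c("none", "unit", "length"), ...) {
    similarityVector(adjacencyVectors(x), gr = gr,
                     normalize = match.arg(normalize))
})

#' @describeIn crossGroup Score an adjacency set against another family's
#'   representative; the result records both the sample's and the
#'   representative's group names. Passing the sample's own representative
#'   degenerates to [similarityVector()].
#' @inheritParams similarityVector
#' @export
setMethod("crossGroup", c("AdjacencySet", "GroupRepresentative"),
    function(x, gr, normalize = c("none", "unit", "length"), ...) {
    normalize <- match.arg(normalize)
    .similarityCore(x, gr, normalize)
})

#' @describeIn crossGroup Convenience for a [ProteinGroup].
#' @export
setMethod("crossGroup", c("ProteinGroup", "GroupRepresentative"),
    function(x, gr, normalize = c("none", "unit", "length"), ...) {
    crossGroup(adjacencyVectors(x), gr, normalize = match.arg(normalize))
})

#' @describeIn pairwiseMatrix Conventional mode for contrast with the
#'   similarity vector: the full symmetric matrix of pairwise statistics
#'   between member adjacency vectors (no representative involved), with a
#'   zero diagonal. Exactly `n (n - 1) / 2` metric evaluations are
#'   performed, recorded in attribute `nEvaluations`.
#' @param normalize Normalisation mode for `metric = "D"`.
#' @export
setMethod("pairwiseMatrix", "AdjacencySet",
    function(x, metric = c("D", "theta"),
             normalize = c("none", "unit", "length"), ...) {
    metric <- match.arg(metric)
    normalize <- match.arg(normalize)
    cnt <- adjacencyCounts(x)
    n <- ncol(cnt)
    if (n < 2L)
        stop("pairwiseMatrix() needs at least 2 sequences")
    m <- matrix(0, n, n, dimnames = list(colnames(cnt), colnames(cnt)))
    evals <- 0L
    for (i in seq_len(n - 1L)) {
        for (j in seq(i + 1L, n)) {
            v <- if (metric == "D")
                magnitudeD(cnt[, i], cnt[, j], normalize = normalize)
            else
                angleTheta(cnt[, i], cnt[, j])
            m[i, j] <- v
            m[j, i] <- v
            evals <- evals + 1L
        }
    }
    attr(m, "nEvaluations") <- evals
    m
})

#' @describeIn pairwiseMatrix Convenience for a [ProteinGroup].
#' @export
setMethod("pairwiseMatrix", "ProteinGroup",
    function(x, metric = c("D", "theta"),
             normalize = c("none", "unit", "length"), ...) {
    pairwiseMatrix(adjacencyVectors(x), metric = match.arg(metric),
                   normalize = match.arg(normalize))
})

#' Export a distance matrix in PHYLIP format
#'
#' Writes a square matrix from [pairwiseMatrix()] in the lower-triangle-plus-
#' diagonal-free PHYLIP square format accepted by neighbour-joining tools.
#'
#' @param m Square symmetric numeric matrix with row names.
#' @param path Output path.
#' @param precision Decimals to print.
#' @return Invisibly, `path`.
#' @export
writePhylipMatrix <- function(m, path, precision = 6L) {
    stopifnot(is.matrix(m), nrow(m) == ncol(m))
    ids <- rownames(m)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
        nm <- formatC(substr(ids[i], 1L, 10L), width = -10L)
        writeLines(paste(nm, paste(
            formatC(m[i, ], format = "f", digits = precision),
            collapse = "  ")), con)
    }
    invisible(path)
}

#' @describeIn SimilarityResult-class The `(id, D, theta)` table as a
#'   [S4Vectors::DataFrame].
#' @export
setMethod("similarityTable", "SimilarityResult", function(x) x@table)

#' @describeIn SimilarityResult-class Group name of the scored sample.
#' @export
setMethod("groupName", "SimilarityResult", function(x) x@sampleGroup)

#' Coerce a SimilarityResult to a data.frame
#'
#' Columns `id`, `group` (the sample's), `gr_group` (the representative's),
#' `D`, `theta`, in input order.
#'
#' @param x A [SimilarityResult].
#' @param row.names,optional,... Ignored; present for the generic.
#' @return `data.frame`.
#' @method as.data.frame SimilarityResult
#' @export
as.data.frame.SimilarityResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    data.frame(id = x@table$id,
               group = x@sampleGroup,
               gr_group = x@grGroup,
               D = x@table$D,
               theta = x@table$theta,
               stringsAsFactors = FALSE)
}

setMethod("as.data.frame", "SimilarityResult",
          as.data.frame.SimilarityResult)
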