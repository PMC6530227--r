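# End-to-end orchestration: one-call group analysis (adjacency table,
# representative, similarity vector, run log) and the class-coherence
# report.

#' Run a full group analysis
#'
#' Reads (or accepts) one protein family, computes its adjacency vectors,
#' group representative and similarity vector, and writes four artifacts to
#' `outDir`: `adjacency.tsv`, `representative.tsv`, `similarity.tsv` and
#' `run_log.json` (inputs, their md5 hashes, policy, normalisation,
#' precision, package version — enough to reproduce the run). Reruns with
#' an identical configuration produce byte-identical tables; nothing in the
#' pipeline is randomised. If any stage fails, partial outputs are removed
#' and the error names the stage.
#'
#' @param input Path to a FASTA file, or a [ProteinGroup].
#' @param outDir Output directory (created if missing).
#' @param name Group label (defaults to the file name or the group's own).
#' @param policy Residue policy (see [ProteinGroup()]).
#' @param normalize Normalisation mode for `D` (see [magnitudeD()]).
#' @param precision Decimals for floating-point table columns (>= 1).
#' @param sort If `TRUE`, the similarity table is sorted by `theta`
#'   ascending; by default input order is preserved.
#' @return Invisibly, a list with the [SimilarityResult], the
#'   [GroupRepresentative] and the paths written.
#' @export
runGroupAnalysis <- function(input, outDir,
                             name = NULL,
                             policy = c("strict", "mask", "drop"),
                             normalize = c("none", "unit", "length"),
                             precision = 4L,
                             sort = FALSE) {
    policy <- match.arg(policy)
    normalize <- match.arg(normalize)
    if (precision < 1L) stop("precision must be >= 1")
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    written <- character()
    stage <- "read"
    tryCatch({
        if (is(input, "ProteinGroup")) {
            pg <- input
            inputPath <- NA_character_
        } else {
            pg <- readProteinGroup(input, name = name, policy = policy)
            inputPath <- normalizePath(input)
        }
        if (!is.null(name)) pg@groupName <- name

        stage <- "adjacency"
        aset <- adjacencyVectors(pg)
        p1 <- file.path(outDir, "adjacency.tsv")
        writeAdjacencyTable(aset, p1); written <- c(written, p1)

        stage <- "representative"
        if (ncol(aset) == 1L)
            warning("single-sequence group: the representative equals the ",
                    "only member and its similarity entry is (0, 0)")
        gr <- suppressWarnings(groupRepresentative(aset))
        p2 <- file.path(outDir, "representative.tsv")
        writeRepresentative(gr, p2); written <- c(written, p2)

        stage <- "similarity"
        sv <- similarityVector(aset, gr = gr, normalize = normalize)
        df <- as.data.frame(sv)
        if (sort) df <- df[order(df$theta), , drop = FALSE]
        p3 <- file.path(outDir, "similarity.tsv")
        writeSimilarityTable(df, p3, format = "tsv",
                             precision = precision)
        written <- c(written, p3)

        stage <- "log"
        log <- list(
            input = inputPath,
            input_md5 = if (is.na(inputPath)) NA_character_ else
                unname(tools::md5sum(inputPath)),
            group = groupName(pg),
            n_sequences = length(pg@sequences),
            policy = policy,
            normalize = normalize,
            precision = precision,
            sorted = sort,
            package_version = as.character(
                utils::packageVersion("ProtAdjacency")),
            r_version = as.character(getRversion()))
        p4 <- file.path(outDir, "run_log.json")
        jsonlite::write_json(log, p4, auto_unbox = TRUE, pretty = TRUE,
                             na = "null")
        written <- c(written, p4)

        invisible(list(similarity = sv, representative = gr,
                       files = written))
    }, error = function(e) {
        unlink(written)
        stop("group analysis failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Class-coherence rule on a set of angle values
#'
#' Operationalises "each class forms a single coherent class" as
#' non-overlapping theta intervals. For each sequence the rule compares its
#' theta with the range of its *other* class members (leave-one-out, so a
#' sequence cannot trivially cover itself); the sequence is flagged as
#' misplaced when its theta falls outside that range but inside the full
#' range of some other class. Singleton classes are never flagged (their
#' leave-one-out range is undefined).
#'
#' @param theta Numeric vector of angle values.
#' @param classes Character vector of class labels, parallel to `theta`.
#' @param ids Optional sequence ids, parallel to `theta`.
#' @return A list with `classRanges` (`data.frame`: class, n, min, max) and
#'   `flagged` (`data.frame`: id, class, theta, overlapping class(es)).
#' @examples
#' th <- c(0.10, 0.12, 0.30, 0.11)
#' classCoherence(th, c("a", "a", "b", "b"), ids = paste0("s", 1:4))$flagged
#' @export
classCoherence <- function(theta, classes, ids = NULL) {
    stopifnot(length(theta) == length(classes))
    if (is.null(ids)) ids <- paste0("seq", seq_along(theta))
    if (anyNA(classes) || any(!nzchar(classes)))
        stop("missing class labels for: ",
             paste(ids[is.na(classes) | !nzchar(classes)], collapse = ", "))
    cls <- unique(classes)
    ranges <- data.frame(
        class = cls,
        n = vapply(cls, function(cl) sum(classes == cl), integer(1L)),
        min = vapply(cls, function(cl) min(theta[classes == cl]),
                     numeric(1L)),
        max = vapply(cls, function(cl) max(theta[classes == cl]),
                     numeric(1L)),
        row.names = NULL)
    flagged <- lapply(seq_along(theta), function(k) {
        own <- classes[k]
        peers <- theta[setdiff(which(classes == own), k)]
        if (!length(peers)) return(NULL)   # singleton class
        outsideOwn <- theta[k] < min(peers) || theta[k] > max(peers)
        if (!outsideOwn) return(NULL)
        others <- ranges[ranges$class != own, , drop = FALSE]
        inOther <- others$class[theta[k] >= others$min &
                                theta[k] <= others$max]
        if (!length(inOther)) return(NULL)
        data.frame(id = ids[k], class = own, theta = theta[k],
                   overlaps = paste(inOther, collapse = ","))
    })
    flagged <- do.call(rbind, flagged)
    if (is.null(flagged))
        flagged <- data.frame(id = character(), class = character(),
                              theta = numeric(), overlaps = character())
    list(classRanges = ranges, flagged = flagged)
}

#' Class-coherence report for a labelled family
#'
#' Computes the similarity vector of a family against its own
#' representative and applies the [classCoherence()] interval rule to the
#' theta values. Every record must carry a class label.
#'
#' @param x A [ProteinGroup] whose `classLabels` cover all records, or an
#'   [AdjacencySet] plus an explicit `classLabels` vector.
#' @param classLabels Named character vector (id to class); taken from the
#'   group when omitted.
#' @param outPath Optional path: when given, the flagged table is written
#'   as TSV and the ranges as `<outPath>.ranges.tsv`.
#' @return The [classCoherence()] list, plus element `similarity` (the
#'   underlying [SimilarityResult]).
#' @export
runClassReport <- function(x, classLabels = NULL, outPath = NULL) {
    if (is(x, "ProteinGroup")) {
        if (is.null(classLabels)) classLabels <- x@classLabels
        aset <- adjacencyVectors(x)
    } else if (is(x, "AdjacencySet")) {
        aset <- x
    } else stop("x must be a ProteinGroup or AdjacencySet")
    ids <- colnames(aset)
    missing <- setdiff(ids, names(classLabels))
    if (length(missing))
        stop("missing class labels for: ", paste(missing, collapse = ", "))
    sv <- similarityVector(aset)
    theta <- similarityTable(sv)$theta
    rep <- classCoherence(theta, unname(classLabels[ids]), ids = ids)
    rep$similarity <- sv
    if (!is.null(outPath)) {
        writeSimilarityTable(rep$flagged, outPath, format = "tsv")
        writeSimilarityTable(rep$classRanges,
                             paste0(outPath, ".ranges.tsv"), format = "tsv")
    }
    rep
}
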