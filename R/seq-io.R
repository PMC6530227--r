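#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
NULL

# positions of residues outside the 20-letter canonical alphabet;
# returns data.frame(id, pos, char), one row per offending character
.nonCanonicalPositions <- function(seqs) {
    out <- lapply(seq_along(seqs), function(k) {
        ch <- strsplit(as.character(seqs[[k]]), "", fixed = TRUE)[[1L]]
        bad <- which(!ch %in% .RESIDUE_ORDER)
        if (!length(bad)) return(NULL)
        data.frame(id = names(seqs)[k], pos = bad, char = ch[bad])
    })
    out <- do.call(rbind, out)
    if (is.null(out)) data.frame(id = character(), pos = integer(),
                                 char = character())
    else out
}

#' Construct a ProteinGroup
#'
#' Builds a validated [ProteinGroup] from sequences already in memory.
#' Sequences are upper-cased, then the residue policy is applied:
#' `"strict"` (default) rejects any character outside the 20 canonical
#' one-letter codes, `"mask"` keeps non-canonical characters (adjacent pairs
#' touching them are skipped during counting), and `"drop"` deletes them,
#' joining their neighbours. `"*"` and `"-"` are never canonical. Records
#' that are empty after the policy is applied are rejected.
#'
#' @param name Group label (single string).
#' @param sequences Named character vector or [Biostrings::AAStringSet];
#'   names are the record ids.
#' @param classLabels Optional named character vector, id to class label.
#' @param policy `"strict"`, `"mask"` or `"drop"`.
#' @return A [ProteinGroup].
#' @examples
#' pg <- ProteinGroup("demo", c(p1 = "WTFE", p2 = "AARNDV"))
#' groupName(pg)
#' @export
ProteinGroup <- function(name, sequences,
                         classLabels = character(),
                         policy = c("strict", "mask", "drop")) {
    policy <- match.arg(policy)
    if (is.character(sequences))
        sequences <- AAStringSet(sequences)
    if (!is(sequences, "AAStringSet"))
        stop("sequences must be a character vector or AAStringSet")
    if (is.null(names(sequences)))
        stop("sequences must be named by record id")
    desc <- mcols(sequences)$description
    up <- toupper(as.character(sequences))
    if (any(!nzchar(up))) {
        stop("empty sequence record(s): ",
             paste(sQuote(names(sequences)[!nzchar(up)]), collapse = ", "))
    }
    if (policy == "drop") {
        keepPattern <- paste0("[^", paste(.RESIDUE_ORDER, collapse = ""), "]")
        up <- gsub(keepPattern, "", up)
        if (any(!nzchar(up)))
            stop("record(s) empty after dropping non-canonical residues: ",
                 paste(sQuote(names(sequences)[!nzchar(up)]), collapse = ", "))
    }
    out <- AAStringSet(up)
    names(out) <- names(sequences)
    if (!is.null(desc)) mcols(out)$description <- desc
    if (policy == "strict") {
        bad <- .nonCanonicalPositions(out)
        if (nrow(bad))
            stop(sprintf(
                "non-canonical residue '%s' in record '%s' at position %d (policy = strict); use policy = 'mask' or 'drop' to admit it",
                bad$char[1L], bad$id[1L], bad$pos[1L]))
    }
    new("ProteinGroup", groupName = name, sequences = out,
        classLabels = classLabels, policy = policy)
}

#' Read a protein family from a FASTA file
#'
#' Parses a FASTA file of amino-acid sequences into a [ProteinGroup],
#' preserving file order. The record id is the first whitespace-delimited
#' token of the header; the full header is kept as the description. Residues
#' are upper-cased and validated under the chosen policy (see
#' [ProteinGroup()]).
#'
#' @param path Path to a FASTA file.
#' @param name Group label; defaults to the file name without extension.
#' @param policy Residue-validation policy (see [ProteinGroup()]).
#' @param classLabels Optional named character vector, id to class label.
#' @return A [ProteinGroup] with records in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "WTFE"), fa)
#' readProteinGroup(fa, name = "demo")
#' @export
readProteinGroup <- function(path, name = NULL,
                             policy = c("strict", "mask", "drop"),
                             classLabels = character()) {
    policy <- match.arg(policy)
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (is.null(name))
        name <- tools::file_path_sans_ext(basename(path))
    seqs <- tryCatch(
        readAAStringSet(path, format = "fasta"),
        error = function(e) stop("malformed FASTA in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (!length(seqs))
        stop("no FASTA records found in ", path)
    headers <- names(seqs)
    ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1L), 1L)
    names(seqs) <- ids
    mcols(seqs)$description <- headers
    ProteinGroup(name, seqs, classLabels = classLabels, policy = policy)
}

#' Write a protein family to a FASTA file
#'
#' @param x A [ProteinGroup].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
writeProteinGroup <- function(x, path) {
    stopifnot(is(x, "ProteinGroup"))
    seqs <- x@sequences
    writeXStringSet(seqs, filepath = path, format = "fasta")
    invisible(path)
}

#' Read a group map
#'
#' Reads a tab-separated table with columns `id`, `group` and optionally
#' `class_label`, used to assign the records of a single FASTA file to
#' several families.
#'
#' @param path Path to a TSV file.
#' @return `data.frame` with columns `id`, `group` and, if present,
#'   `class_label`.
#' @export
readGroupMap <- function(path) {
    map <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "group")
    if (!all(need %in% colnames(map)))
        stop("group map must have columns 'id' and 'group'")
    map
}

#' Split a FASTA file into families using a group map
#'
#' @param path FASTA file containing records of several families.
#' @param map A group map `data.frame` (see [readGroupMap()]) or a path to
#'   one.
#' @inheritParams readProteinGroup
#' @return Named list of [ProteinGroup] objects, one per group in the map.
#' @export
readProteinGroups <- function(path, map,
                              policy = c("strict", "mask", "drop")) {
    policy <- match.arg(policy)
    if (is.character(map) && length(map) == 1L)
        map <- readGroupMap(map)
    all <- readProteinGroup(path, name = "all", policy = policy)
    seqs <- all@sequences
    missing <- setdiff(map$id, names(seqs))
    if (length(missing))
        stop("group map ids absent from FASTA: ",
             paste(missing, collapse = ", "))
    groups <- unique(map$group)
    out <- lapply(groups, function(g) {
        ids <- map$id[map$group == g]
        cls <- character()
        if ("class_label" %in% colnames(map)) {
            cls <- map$class_label[map$group == g]
            names(cls) <- ids
            cls <- cls[!is.na(cls) & nzchar(cls)]
        }
        ProteinGroup(g, seqs[ids], classLabels = cls, policy = policy)
    })
    names(out) <- groups
    out
}

# shared fixed-precision rendering for tabular output
.renderNum <- function(x, precision) {
    ifelse(is.na(x), NA_character_,
           formatC(x, format = "f", digits = precision))
}

#' Write a similarity table
#'
#' Writes a [SimilarityResult] (or any data frame of keyed rows) to TSV or
#' JSON with a deterministic column order and fixed-precision floats
#' (default 4 decimals).
#'
#' @param x A [SimilarityResult] or `data.frame`.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param precision Number of decimals for floating-point columns.
#' @return Invisibly, `path`.
#' @export
writeSimilarityTable <- function(x, path, format = c("tsv", "json"),
                                 precision = 4L) {
    format <- match.arg(format)
    if (precision < 1L) stop("precision must be >= 1")
    df <- if (is(x, "SimilarityResult")) as.data.frame(x) else
        as.data.frame(x)
    isNum <- vapply(df, is.numeric, logical(1L)) &
        !vapply(df, is.integer, logical(1L))
    if (format == "tsv") {
        out <- df
        out[isNum] <- lapply(df[isNum], .renderNum, precision = precision)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    } else {
        out <- df
        out[isNum] <- lapply(df[isNum], function(v) round(v, precision))
        jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                             auto_unbox = TRUE, pretty = TRUE)
    }
    invisible(path)
}

#' Read back a similarity table written by [writeSimilarityTable()]
#'
#' @param path Path to a TSV or JSON table.
#' @param format `"tsv"` or `"json"`; guessed from the extension by default.
#' @return `data.frame`.
#' @export
readSimilarityTable <- function(path, format = NULL) {
    if (is.null(format))
        format <- if (grepl("\\.json$", path)) "json" else "tsv"
    if (format == "json")
        as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    else
        utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Export adjacency vectors as a labelled TSV
#'
#' One row per sequence: `id`, `length`, `skipped_pairs`, then the 400 pair
#' counts in canonical layout order under their two-letter labels.
#'
#' @param x An [AdjacencySet].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeAdjacencyTable <- function(x, path) {
    stopifnot(is(x, "AdjacencySet"))
    cnt <- t(adjacencyCounts(x))
    df <- data.frame(id = colnames(x),
                     length = seqLengths(x),
                     skipped_pairs = skippedPairs(x),
                     cnt, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Export / import a group representative
#'
#' A representative written once can be reused for cross-group runs. The TSV
#' has one row with `group_name`, `n_sequences` and the 400 labelled values
#' (exact: integers or half-integers, so nothing is lost in the round trip).
#'
#' @param gr A [GroupRepresentative].
#' @param path Output (or input) path.
#' @return `writeRepresentative()` invisibly returns `path`;
#'   `readRepresentative()` returns a [GroupRepresentative] (member ids are
#'   not stored in the file and come back as `NA`).
#' @export
writeRepresentative <- function(gr, path) {
    stopifnot(is(gr, "GroupRepresentative"))
    df <- data.frame(group_name = gr@groupName,
                     n_sequences = gr@nSequences,
                     t(gr@values), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeRepresentative
#' @export
readRepresentative <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!all(c("group_name", "n_sequences", .PAIR_LABELS) %in% colnames(df)))
        stop("not a representative table: ", path)
    vals <- as.numeric(df[1L, .PAIR_LABELS])
    names(vals) <- .PAIR_LABELS
    n <- as.integer(df$n_sequences[1L])
    new("GroupRepresentative", groupName = as.character(df$group_name[1L]),
        values = vals, nSequences = n,
        memberIds = rep(NA_character_, n))
}
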