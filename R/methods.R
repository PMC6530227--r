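# accessors and show methods

#' @describeIn ProteinGroup-class Group label.
#' @export
setMethod("groupName", "ProteinGroup", function(x) x@groupName)

#' @describeIn ProteinGroup-class Named class-label vector (length 0 when
#'   unlabelled).
#' @export
setMethod("classLabels", "ProteinGroup", function(x) x@classLabels)

#' @describeIn ProteinGroup-class Attach or replace class labels.
#' @export
setMethod("classLabels<-", "ProteinGroup", function(x, value) {
    x@classLabels <- value
    validObject(x)
    x
})

#' @describeIn ProteinGroup-class Residue-validation policy the records
#'   were admitted under.
#' @export
setMethod("residuePolicy", "ProteinGroup", function(x) x@policy)

#' @describeIn ProteinGroup-class The member sequences as an
#'   [Biostrings::AAStringSet] named by record id.
#' @export
setMethod("sequences", "ProteinGroup", function(x) x@sequences)

#' @describeIn ProteinGroup-class Number of records.
#' @export
setMethod("length", "ProteinGroup", function(x) length(x@sequences))

#' @describeIn ProteinGroup-class Record ids.
#' @export
setMethod("names", "ProteinGroup", function(x) names(x@sequences))

setMethod("show", "ProteinGroup", function(object) {
    w <- Biostrings::width(object@sequences)
    cat("ProteinGroup '", object@groupName, "': ",
        length(object@sequences), " sequence(s), lengths ",
        min(w), "..", max(w), ", policy = ", object@policy, "\n", sep = "")
    if (length(object@classLabels))
        cat("  classes: ",
            paste(sort(unique(object@classLabels)), collapse = ", "),
            "\n", sep = "")
})

setMethod("show", "AdjacencySet", function(object) {
    cat("AdjacencySet of group '", groupName(object), "': ",
        ncol(object), " sequence(s) x 400 ordered residue pairs\n",
        sep = "")
    cat("  policy: ", metadata(object)$policy,
        "; total pairs counted: ",
        sum(SummarizedExperiment::colData(object)$nPairs), "\n", sep = "")
})

setMethod("show", "GroupRepresentative", function(object) {
    nz <- sum(object@values > 0)
    cat("GroupRepresentative of '", object@groupName, "' (elementwise ",
        "median over ", object@nSequences, " member(s))\n", sep = "")
    cat("  ", nz, " of 400 elements non-zero; norm = ",
        format(sqrt(sum(object@values^2)), digits = 6), "\n", sep = "")
})

setMethod("show", "SimilarityResult", function(object) {
    cross <- !identical(object@sampleGroup, object@grGroup)
    cat("SimilarityResult: sample '", object@sampleGroup,
        "' vs representative of '", object@grGroup, "'",
        if (cross) "  [cross-group]", "\n", sep = "")
    cat("  ", nrow(object@table), " entries; ", object@nEvaluations,
        " evaluations per metric; D normalisation: ", object@normalize,
        "\n", sep = "")
    df <- as.data.frame(object)
    df$D <- round(df$D, 4)
    df$theta <- round(df$theta, 4)
    print(utils::head(df[, c("id", "D", "theta")], 10L),
          row.names = FALSE)
    if (nrow(df) > 10L) cat("  ... ", nrow(df) - 10L, " more\n", sep = "")
})
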