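# Embedded worked-example sequences and a seeded synthetic family
# generator, so every stage is exercisable without any download.

# run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

#' The two worked-example yeast protein segments
#'
#' Two 30-residue segments of a yeast *Saccharomyces cerevisiae* protein,
#' classically used to demonstrate pair-count descriptors. Protein I is
#' `WTFESRNDPAKDPVILWLNGGPGCSSLTGL`; Protein II differs at a handful of
#' sites. Each yields 29 adjacent ordered pairs; e.g. the pair `ND` occurs
#' once in Protein I and twice in Protein II, `DP` twice in both, and `SL`
#' and `LT` once in Protein I but never in Protein II.
#'
#' @return A [ProteinGroup] named `"worked_example"` with records
#'   `ProteinI` and `ProteinII`.
#' @examples
#' we <- workedExample()
#' adjacencyVector(as.character(sequences(we)[["ProteinI"]]))[["ND"]]
#' @export
workedExample <- function() {
    ProteinGroup("worked_example", c(
        ProteinI  = "WTFESRNDPAKDPVILWLNGGPGCSSLTGL",
        ProteinII = "WFFESRNDPANDPIILWLNGGPGCSSFTGL"))
}

#' The canonical human beta globin protein sequence
#'
#' The 147-residue human beta globin chain (HBB, including the initiator
#' methionine), embedded as a reference fixture: its adjacency vector's
#' first 20 elements (the "A row") are a standard worked check for
#' dipeptide-count descriptors.
#'
#' @return A [ProteinGroup] named `"beta_globin"` with the single record
#'   `Human_HBB`.
#' @examples
#' hb <- humanBetaGlobin()
#' Biostrings::width(sequences(hb))
#' @export
humanBetaGlobin <- function() {
    ProteinGroup("beta_globin", c(Human_HBB = paste0(
        "MVHLTPEEKSAVTALWGKVNVDEVGGEALGRLLVVYPWTQRFFESFGDLSTPDAVMGNPK",
        "VKAHGKKVLGAFSDGLAHLDNLKGTFATLSELHCDKLHVDPENFRLLGNVLVCVLAHHFG",
        "KEFTPPVQAAYQKVVAGVANALAHKYH")))
}

#' Generate a seeded synthetic protein family
#'
#' Draws a uniform-random ancestor sequence over the 20 canonical residues,
#' then derives each further member by substituting every site
#' independently with probability `substitutionRate` to a uniformly chosen
#' *different* residue. The ancestor itself is included as the first member
#' (`ancestor`); mutated copies are `member1`, `member2`, ... The generator
#' is deterministic given `seed` and leaves the caller's RNG state
#' untouched. No evolutionary substitution model is applied: the fixture
#' emulates the group structure of a sequence family (shared composition
#' plus per-copy noise), not realistic protein evolution.
#'
#' @param ancestorLength Number of residues in the ancestor (>= 2).
#' @param nMembers Total number of records, ancestor included (>= 1).
#' @param substitutionRate Per-site substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param name Group label.
#' @return A [ProteinGroup] of `nMembers` records.
#' @examples
#' fam <- makeFamily(60, 5, 0.1, seed = 1)
#' length(sequences(fam))
#' @export
makeFamily <- function(ancestorLength, nMembers, substitutionRate, seed,
                       name = "synthetic") {
    if (ancestorLength < 2L) stop("ancestorLength must be >= 2")
    if (nMembers < 1L) stop("nMembers must be >= 1")
    if (substitutionRate < 0 || substitutionRate >= 1)
        stop("substitutionRate must be in [0, 1)")
    seqs <- .withSeed(seed, {
        anc <- sample(.RESIDUE_ORDER, ancestorLength, replace = TRUE)
        members <- list(anc)
        if (nMembers > 1L) for (k in seq_len(nMembers - 1L)) {
            s <- anc
            hit <- stats::runif(ancestorLength) < substitutionRate
            if (any(hit)) {
                # uniformly among the 19 residues different from the current
                s[hit] <- vapply(s[hit], function(r)
                    sample(setdiff(.RESIDUE_ORDER, r), 1L), character(1L))
            }
            members[[k + 1L]] <- s
        }
        vapply(members, paste, character(1L), collapse = "")
    })
    names(seqs) <- c("ancestor",
                     if (nMembers > 1L) paste0("member", seq_len(nMembers - 1L)))
    ProteinGroup(name, seqs)
}
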