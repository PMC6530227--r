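#' The canonical residue ordering
#'
#' The 20 standard amino acids in the fixed order that defines the layout of
#' every adjacency vector in this package: alphabetical by the residues' full
#' names, which yields `A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T, W,
#' Y, V`. The ordered pair (i-th residue, j-th residue) occupies layout index
#' `20*(i-1) + (j-1)` (zero-based), so the first 20 elements are the "A row"
#' (`AA`, `AR`, ..., `AV`), the next 20 the "R row", and the last element
#' (index 399) is `VV`.
#'
#' @return Character vector of the 20 one-letter codes, in canonical order.
#' @examples
#' residueOrder()
#' @export
residueOrder <- function() .RESIDUE_ORDER

.RESIDUE_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# layout labels "AA","AR",...,"VV" in vector order
.PAIR_LABELS <- as.vector(t(outer(.RESIDUE_ORDER, .RESIDUE_ORDER, paste0)))

#' Labels of the 400 adjacency-vector elements
#'
#' @return Character vector of length 400: `"AA", "AR", ..., "VV"` in layout
#'   order.
#' @examples
#' head(pairLabels())
#' @export
pairLabels <- function() .PAIR_LABELS

#' Map an ordered residue pair to its layout index
#'
#' Returns the zero-based position of the ordered pair `(first, second)` in
#' the 400-element adjacency-vector layout: `20 * index(first) +
#' index(second)` with residue indices `0..19` in canonical order. The first
#' element of the vector (label `AA`) has index 0 and the last (`VV`) index
#' 399.
#'
#' @param first,second Single canonical one-letter residue codes (vectorised;
#'   recycled to a common length).
#' @return Integer vector of zero-based layout indices in `0..399`.
#' @seealso [pairLabel()] for the inverse, [pairLabels()] for the full layout.
#' @examples
#' pairIndex("A", "A")  # 0
#' pairIndex("A", "H")  # 8
#' pairIndex("V", "V")  # 399
#' @export
pairIndex <- function(first, second) {
    i <- match(first, .RESIDUE_ORDER)
    j <- match(second, .RESIDUE_ORDER)
    bad <- is.na(i) | is.na(j)
    if (any(bad)) {
        offending <- unique(c(first[is.na(i)], second[is.na(j)]))
        stop("non-canonical residue symbol(s): ",
             paste(sQuote(offending), collapse = ", "),
             "; canonical symbols are ",
             paste(.RESIDUE_ORDER, collapse = ""))
    }
    as.integer(20L * (i - 1L) + (j - 1L))
}

#' Map a layout index back to its residue-pair label
#'
#' Inverse of [pairIndex()]: `pairLabel(0)` is `"AA"`, `pairLabel(399)` is
#' `"VV"`.
#'
#' @param index Integer vector of zero-based layout indices in `0..399`.
#' @return Character vector of two-letter pair labels.
#' @examples
#' pairLabel(c(0, 8, 399))
#' @export
pairLabel <- function(index) {
    index <- as.integer(index)
    if (any(is.na(index) | index < 0L | index > 399L))
        stop("layout index must be in 0..399")
    .PAIR_LABELS[index + 1L]
}
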