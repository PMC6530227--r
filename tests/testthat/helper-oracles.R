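# Independent oracles and frozen reference data used across the suite.
# Every oracle here deliberately avoids the package's own counting /
# median / angle code paths.

# Brute-force 2-mer oracle: for each of the 400 ordered pair labels,
# count overlapping occurrences by scanning every position of the
# sequence. O(400 * L), independent of the sliding-window tabulation.
bruteForcePairCounts <- function(seq) {
    ord <- residueOrder()
    labels <- as.vector(t(outer(ord, ord, paste0)))
    L <- nchar(seq)
    starts <- if (L >= 2L) substring(seq, 1:(L - 1L), 2:L) else character()
    out <- vapply(labels, function(lab) sum(starts == lab), integer(1L))
    names(out) <- labels
    out
}

# Sort-and-pick median oracle (does not call stats::median):
# middle order statistic for odd n, mean of the two central ones for even.
sortPickMedian <- function(v) {
    s <- sort(v)
    n <- length(s)
    if (n %% 2L == 1L) s[(n + 1L) %/% 2L]
    else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

# Direct-definition angle oracle.
dotProductAngle <- function(a, b) {
    acos(pmin(1, pmax(-1, sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b))))))
}

randomProtein <- function(n) {
    paste(sample(residueOrder(), n, replace = TRUE), collapse = "")
}

# Published similarity-vector angle columns (radians, 4 decimals) used as
# frozen reference data. The spike entries carry the virus class labels
# (I, II, III, SARS).
BETA_GLOBIN_THETA <- c(Human = 0.3657, Chimpanzee = 0.4098,
                       Gorilla = 0.4185, Mouse = 0.6047, Rat = 0.6251,
                       Gallus = 0.7480, Opossum = 0.7955)

ND5_THETA <- c(PigmyChimpanzee = 0.2218, CommonChimpanzee = 0.2357,
               Human = 0.2517, Gorilla = 0.2547, FinWhale = 0.3006,
               BlueWhale = 0.3003, Mouse = 0.3873, Rat = 0.4130,
               Opossum = 0.4659)

SPIKE_THETA <- data.frame(
    id = c("TGEVG", "TGEV", "PEDVC", "PEDV", "HCoVOC43", "BCoVE", "BCoVL",
           "BCoVM", "BCoVQ", "MHVA", "MHVJHM", "MHVP", "MHVM", "IBVBJ",
           "IBVC", "IBV", "GD03T0013", "PC4127", "PC4137", "PC4205",
           "civet007", "civet010", "A022", "GD01", "GZ02", "BJ01", "FRA",
           "TOR2", "TaiwanTC1"),
    class = c(rep("I", 4), rep("II", 9), rep("III", 3), rep("SARS", 13)),
    theta = c(0.4793, 0.4793, 0.4473, 0.4473, 0.4299, 0.4203, 0.4233,
              0.4198, 0.4203, 0.4395, 0.4728, 0.4240, 0.4406, 0.5002,
              0.4863, 0.5188, 0.2439, 0.2473, 0.2491, 0.2476, 0.2519,
              0.2478, 0.2526, 0.2445, 0.2433, 0.2413, 0.2481, 0.2458,
              0.2449),
    stringsAsFactors = FALSE)

# First 20 elements (the "A row") of the published human beta globin
# adjacency vector.
HUMAN_HBB_A_ROW <- c(AA = 1, AR = 0, AN = 1, AD = 0, AC = 0, AQ = 0,
                     AE = 0, AG = 1, AH = 4, AI = 0, AL = 3, AK = 0,
                     AM = 0, AF = 1, AP = 0, AS = 0, AT = 1, AW = 0,
                     AY = 1, AV = 2)

# Paths where the NCBI accession FASTAs are expected once fetched with
# inst/scripts/fetch-ncbi.R (network-dependent; not shipped).
ncbiFixturePath <- function(file) {
    dir <- system.file("extdata", "ncbi", package = "ProtAdjacency")
    if (!nzchar(dir)) return(file.path("__missing__", file))
    file.path(dir, file)
}
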