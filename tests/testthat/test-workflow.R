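test_that("a full group analysis writes the four artifacts, deterministically", {
    fam <- makeFamily(80, 5, 0.2, seed = 77, name = "famW")
    fa <- tempfile(fileext = ".fasta")
    writeProteinGroup(fam, fa)
    out1 <- file.path(tempdir(), "runA")
    out2 <- file.path(tempdir(), "runB")
    res <- runGroupAnalysis(fa, out1, name = "famW")
    runGroupAnalysis(fa, out2, name = "famW")

    files <- c("adjacency.tsv", "representative.tsv", "similarity.tsv",
               "run_log.json")
    expect_true(all(file.exists(file.path(out1, files))))
    # byte-identical reruns (the log includes no timestamps)
    for (f in files)
        expect_identical(readLines(file.path(out1, f)),
                         readLines(file.path(out2, f)))

    log <- jsonlite::read_json(file.path(out1, "run_log.json"))
    expect_identical(log$policy, "strict")
    expect_identical(log$n_sequences, 5L)
    expect_match(log$input_md5, "^[0-9a-f]{32}$")

    # written similarity table equals the in-memory result at 4 decimals
    tab <- readSimilarityTable(file.path(out1, "similarity.tsv"))
    expect_equal(tab$theta,
                 round(similarityTable(res$similarity)$theta, 4))
    # the representative on disk can be reused for a cross-group run
    gr <- readRepresentative(file.path(out1, "representative.tsv"))
    expect_equal(grValues(gr), grValues(res$representative))
})

test_that("the worked-example group run is hand-checkable", {
    out <- file.path(tempdir(), "runWE")
    res <- runGroupAnalysis(workedExample(), out)
    gr <- res$representative
    aset <- adjacencyVectors(workedExample())
    expect_equal(unname(grValues(gr)),
                 unname(rowMeans(adjacencyCounts(aset))))  # n = 2 median
    D <- similarityTable(res$similarity)$D
    expect_equal(D[1], D[2])
})

test_that("a single-sequence group yields a (0, 0) entry and a warning", {
    pg <- ProteinGroup("solo", c(only = "WTFESRND"))
    out <- file.path(tempdir(), "runSolo")
    expect_warning(res <- runGroupAnalysis(pg, out), "single-sequence")
    tab <- similarityTable(res$similarity)
    expect_equal(nrow(tab), 1L)
    expect_equal(tab$D, 0)
    expect_equal(tab$theta, 0)
})

test_that("a failing stage aborts with its name and removes partial output", {
    out <- file.path(tempdir(), "runFail")
    expect_error(runGroupAnalysis(tempfile(fileext = ".fasta"), out),
                 "stage 'read'")
    expect_length(list.files(out), 0L)
})

test_that("the class-coherence rule flags exactly the planted outlier", {
    # disjoint synthetic theta ranges: zero flags
    rep0 <- classCoherence(c(0.10, 0.12, 0.11, 0.30, 0.32, 0.31),
                           rep(c("a", "b"), each = 3))
    expect_equal(nrow(rep0$flagged), 0L)
    expect_equal(sort(rep0$classRanges$class), c("a", "b"))

    # one member of class a sits inside class b's range: exactly one flag
    # (b's extremes are duplicated so they stay inside their own
    # leave-one-out ranges, as ties do in real families)
    rep1 <- classCoherence(c(0.10, 0.12, 0.31, 0.30, 0.30, 0.33, 0.33),
                           c("a", "a", "a", "b", "b", "b", "b"),
                           ids = paste0("s", 1:7))
    expect_identical(rep1$flagged$id, "s3")
    expect_identical(rep1$flagged$overlaps, "b")

    # outside its own range but inside no other: not flagged
    rep2 <- classCoherence(c(0.10, 0.12, 0.20, 0.40, 0.42, 0.41),
                           rep(c("a", "b"), each = 3))
    expect_equal(nrow(rep2$flagged), 0L)

    # singleton classes are never flagged
    rep3 <- classCoherence(c(0.10, 0.12, 0.11), c("a", "a", "b"))
    expect_equal(nrow(rep3$flagged), 0L)
})

test_that("published spike angles feed the rule: one class-II outlier, SARS lowest", {
    # frozen published angle column as input data to the coherence rule
    rep <- classCoherence(SPIKE_THETA$theta, SPIKE_THETA$class,
                          ids = SPIKE_THETA$id)
    expect_identical(rep$flagged$id, "MHVJHM")
    expect_identical(rep$flagged$class, "II")
    sars <- SPIKE_THETA$theta[SPIKE_THETA$class == "SARS"]
    rest <- SPIKE_THETA$theta[SPIKE_THETA$class != "SARS"]
    expect_lt(max(sars), min(rest))
})

test_that("an end-to-end class report flags a planted synthetic outlier", {
    fam <- makeFamily(120, 8, 0.05, seed = 404, name = "tight")
    far <- makeFamily(120, 3, 0.05, seed = 405, name = "far")
    seqs <- c(as.character(sequences(fam)),
              outlier = as.character(sequences(far))[[1]])
    names(seqs) <- c(names(fam), "outlier")
    labels <- c(stats::setNames(rep("core", length(fam)), names(fam)),
                outlier = "core")
    # a second, self-consistent class built around the foreign family
    seqs2 <- as.character(sequences(far))[2:3]
    names(seqs2) <- c("f1", "f2")
    all <- ProteinGroup("mix", c(seqs, seqs2),
                        classLabels = c(labels,
                                        f1 = "other", f2 = "other"))
    rep <- runClassReport(all)
    expect_true("outlier" %in% rep$flagged$id)
    expect_false(any(grepl("^member", rep$flagged$id)))
    expect_error(runClassReport(ProteinGroup("x", c(a = "WTFE", b = "WTFD"))),
                 "missing class labels")
})
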