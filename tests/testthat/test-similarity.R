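test_that("magnitude D satisfies its elementary identities", {
    gr <- rep(0, 400)
    a <- gr; a[5] <- 3
    expect_equal(magnitudeD(a, gr), 3)           # single-coordinate norm
    expect_equal(magnitudeD(a, a), 0)            # identical vectors
    set.seed(21)
    x <- sample(0:9, 400, replace = TRUE)
    y <- sample(0:9, 400, replace = TRUE) + 0.5  # half-integer representative
    expect_equal(magnitudeD(x, y), sqrt(sum((x - y)^2)))
    expect_equal(magnitudeD(x, y), magnitudeD(y, x))
})

test_that("D obeys the metric axioms on random descriptor triples", {
    set.seed(31)
    for (rep in 1:25) {
        x <- sample(0:6, 400, replace = TRUE)
        y <- sample(0:6, 400, replace = TRUE)
        z <- sample(0:6, 400, replace = TRUE)
        dxy <- magnitudeD(x, y); dyz <- magnitudeD(y, z)
        dxz <- magnitudeD(x, z)
        expect_gte(dxy, 0)
        expect_lte(dxz, dxy + dyz + 1e-12)       # triangle inequality
        expect_equal(dxy, magnitudeD(y, x))      # symmetry
        if (dxy == 0) expect_identical(x, y)     # identity of indiscernibles
    }
})

test_that("theta matches the definition, is clamped, and is scale-free", {
    a <- c(1, 2, rep(0, 398))
    expect_equal(angleTheta(a, 7 * a), 0)        # parallel
    b <- c(0, 0, 5, rep(0, 397))
    expect_equal(angleTheta(a, b), pi / 2)       # disjoint supports
    # antiparallel direction reaches acos(-1) without NaN
    expect_equal(angleTheta(a, -a), pi)
    set.seed(41)
    for (rep in 1:20) {
        x <- sample(0:9, 400, replace = TRUE)
        y <- sample(0:9, 400, replace = TRUE) / 2
        expect_equal(angleTheta(x, y), dotProductAngle(x, y))
        c1 <- stats::runif(1, 0.01, 50)
        expect_equal(angleTheta(c1 * x, y), angleTheta(x, y))
        expect_equal(angleTheta(x, c1 * y), angleTheta(x, y))
        # D is not scale invariant (unless c1 == 1)
        if (abs(c1 - 1) > 1e-6 && sum(x) > 0)
            expect_false(isTRUE(all.equal(magnitudeD(c1 * x, y),
                                          magnitudeD(x, y))))
    }
    expect_error(angleTheta(rep(0, 400), a), "zero norm")
    expect_equal(angleTheta(a, b, degrees = TRUE), 90)
})

test_that("the similarity vector has one entry per member, in input order", {
    fam <- makeFamily(90, 6, 0.2, seed = 8, name = "famS")
    aset <- adjacencyVectors(fam)
    sv <- similarityVector(aset)
    tab <- similarityTable(sv)
    expect_equal(nrow(tab), 6)
    expect_identical(tab$id, colnames(aset))
    expect_identical(sv@nEvaluations, 6L)
    expect_identical(sv@sampleGroup, "famS")
    expect_identical(sv@grGroup, "famS")
    df <- as.data.frame(sv)
    expect_identical(colnames(df), c("id", "group", "gr_group", "D", "theta"))

    # identical sequences: every entry is (0, 0)
    same <- adjacencyVectors(c(a = "WTFESR", b = "WTFESR", c = "WTFESR"))
    sv0 <- similarityVector(same)
    expect_equal(similarityTable(sv0)$D, rep(0, 3))
    expect_equal(similarityTable(sv0)$theta, rep(0, 3))
})

test_that("zero-norm members are rejected by name in the angle stage", {
    suppressWarnings({
        aset <- adjacencyVectors(c(ok = "WTFESR", tiny = "W"))
        expect_error(similarityVector(aset), "tiny")
    })
})

test_that("the worked-example two-member group is equidistant from its representative", {
    we <- workedExample()
    aset <- adjacencyVectors(we)
    gr <- groupRepresentative(aset)
    # even-n median of two vectors is their midpoint, so D must be equal
    sv <- similarityVector(aset, gr)
    D <- similarityTable(sv)$D
    expect_equal(D[1], D[2])
    expect_equal(D[1],
                 magnitudeD(adjacencyCounts(aset)[, 1],
                            adjacencyCounts(aset)[, 2]) / 2)
})

test_that("the pairwise matrix is symmetric, zero-diagonal, and costs n(n-1)/2", {
    fam <- makeFamily(70, 7, 0.25, seed = 17)
    aset <- adjacencyVectors(fam)
    for (metric in c("D", "theta")) {
        m <- pairwiseMatrix(aset, metric = metric)
        expect_equal(m, t(m))
        expect_equal(unname(diag(m)), rep(0, 7))
        expect_identical(attr(m, "nEvaluations"), 21L)   # 7 * 6 / 2
    }
    # D-mode agrees with stats::dist as an independent route
    m <- pairwiseMatrix(aset, metric = "D")
    ref <- as.matrix(stats::dist(t(adjacencyCounts(aset))))
    expect_equal(unname(m[1:7, 1:7]), unname(ref), tolerance = 1e-12)

    two <- adjacencyVectors(c(a = "WTFE", b = "WTFE"))
    expect_equal(unname(pairwiseMatrix(two, "D")[1:2, 1:2]),
                 matrix(0, 2, 2))
    expect_error(pairwiseMatrix(two[, 1]), "at least 2")
})

test_that("cross-group scoring degenerates to the own-group vector and is label-only", {
    famA <- makeFamily(90, 5, 0.15, seed = 23, name = "A")
    asetA <- adjacencyVectors(famA)
    grA <- groupRepresentative(asetA)
    own <- similarityVector(asetA, grA)
    cross <- crossGroup(asetA, grA)
    expect_equal(similarityTable(cross)$theta, similarityTable(own)$theta)
    expect_equal(similarityTable(cross)$D, similarityTable(own)$D)

    famB <- makeFamily(90, 5, 0.15, seed = 24, name = "B")
    grB <- groupRepresentative(adjacencyVectors(famB))
    crossAB <- crossGroup(asetA, grB)
    expect_identical(crossAB@sampleGroup, "A")
    expect_identical(crossAB@grGroup, "B")
    # the statistics depend only on the two vectors, not on the labelling
    for (k in 1:5)
        expect_equal(similarityTable(crossAB)$theta[k],
                     angleTheta(adjacencyCounts(asetA)[, k], grValues(grB)))
})

test_that("PHYLIP export writes a square matrix readable by ape", {
    fam <- makeFamily(60, 4, 0.2, seed = 29)
    m <- pairwiseMatrix(adjacencyVectors(fam), "theta")
    f <- tempfile(fileext = ".dist")
    writePhylipMatrix(m, f)
    lines <- readLines(f)
    expect_equal(as.integer(trimws(lines[1])), 4L)
    expect_length(lines, 5L)
})
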