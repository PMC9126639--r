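test_that("moments match hand evaluation", {
    m <- biclusterMoments(matrix(c(1, 3, 2, 5), 2, 2))
    expect_equal(unname(m$rowMeans), c(1.5, 4))
    expect_equal(unname(m$colMeans), c(2, 3.5))
    expect_equal(m$overallMean, 2.75)

    m5 <- biclusterMoments(matrix(5, 3, 4))
    expect_equal(unname(m5$rowMeans), rep(5, 3))
    expect_equal(m5$overallMean, 5)

    m1 <- biclusterMoments(matrix(c(1, 2, 6), 1, 3))
    expect_equal(unname(m1$rowMeans), m1$overallMean)
})

test_that("worked micro-examples of the four indices", {
    expect_equal(biclusterVariance(matrix(c(1, 3, 2, 4), 2, 2)), 1.25)
    expect_equal(biclusterMSR(matrix(c(1, 3, 2, 5), 2, 2)), 0.0625)
    expect_equal(biclusterSMSR(matrix(c(1, 2, 2, 2), 2, 2)),
                 mean(c(0.049382716, 0.027777778, 0.027777778, 0.015625)),
                 tolerance = 1e-7)
    expect_equal(virtualError(matrix(c(1, 2, 2, 1), 2, 2)), 1)
})

test_that("zero cases: each index vanishes on its pattern family", {
    expect_equal(biclusterVariance(matrix(5, 2, 2)), 0)
    # additive block pi=(0,1), beta=(0,2)
    expect_equal(biclusterMSR(outer(c(0, 1), c(0, 2), `+`)), 0)
    # multiplicative block pi=(1,2), beta=(1,3)
    expect_equal(biclusterSMSR(outer(c(1, 2), c(1, 3))), 0)
    # shifting and positive-scaling rows are affine families: VE = 0
    expect_equal(virtualError(outer(c(0, 1, 5), c(0, 2, 7), `+`)), 0)
    expect_equal(virtualError(matrix(c(1, 2, 2, 4, 3, 6), 2, 3)), 0)
    # constant bicluster: degenerate rows standardise to zero, VE = 0
    expect_equal(virtualError(matrix(3, 4, 5)), 0)
})

test_that("SMSR is undefined for zero row/column means and excluded downstream", {
    withZeroRow <- rbind(c(0, 0, 0), c(1, 2, 3))
    expect_true(is.na(biclusterSMSR(withZeroRow)))
    withZeroColMean <- cbind(c(-1, 1), c(2, 3))
    expect_true(is.na(biclusterSMSR(withZeroColMean)))
})

test_that("standardizeRows uses the population sd and flags degenerate rows", {
    s <- standardizeRows(matrix(c(1, 2, 3), 1, 3))
    expect_equal(unname(s$rowSdsUsed), sqrt(2 / 3))
    expect_equal(unname(s$values[1, ]),
                 c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)

    s2 <- standardizeRows(rbind(c(2, 2, 2), c(1, 2, 3)))
    expect_equal(s2$degenerateRows, 1L)
    expect_equal(unname(s2$values[1, ]), c(0, 0, 0))
    # non-degenerate rows: mean 0, population sd 1
    expect_equal(mean(s2$values[2, ]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(s2$values[2, ]^2)), 1, tolerance = 1e-9)
})

test_that("row standardisation is invariant under positive affine maps", {
    set.seed(11)
    for (i in 1:100) {
        x <- matrix(rnorm(24), 4, 6)
        a <- runif(4, 0.1, 3); c0 <- rnorm(4)
        y <- x * a + c0
        expect_equal(standardizeRows(y)$values, standardizeRows(x)$values,
                     tolerance = 1e-9)
    }
})

test_that("virtual pattern is the row mean of the standardised bicluster", {
    # opposite rows cancel
    expect_equal(unname(virtualPattern(rbind(c(-1, 1), c(1, -1)))), c(0, 0))
    # identical rows: pattern equals any standardised row
    x <- rbind(c(1, 2, 4), c(1, 2, 4))
    expect_equal(virtualPattern(x), standardizeRows(x)$values[1, ])
    # single row: pattern is that row
    y <- matrix(c(1, 5, 2), 1, 3)
    expect_equal(virtualPattern(y), standardizeRows(y)$values[1, ])
})

test_that("vectorised metrics agree with per-element loop oracles", {
    set.seed(12)
    for (i in 1:200) {
        n <- sample(2:10, 1); p <- sample(2:10, 1)
        v <- matrix(rnorm(n * p, sd = runif(1, 0.1, 5)), n, p)
        expect_equal(biclusterVariance(v), loopVariance(v),
                     tolerance = 1e-12)
        expect_equal(biclusterMSR(v), loopMSR(v), tolerance = 1e-12)
        expect_equal(biclusterSMSR(v), loopSMSR(v), tolerance = 1e-12)
        expect_equal(virtualError(v), loopVE(v), tolerance = 1e-12)
    }
})

test_that("shift/affine invariances hold on random biclusters", {
    set.seed(13)
    for (i in 1:100) {
        v <- matrix(rnorm(30), 5, 6)
        c0 <- rnorm(1)
        expect_equal(biclusterVariance(v + c0), biclusterVariance(v),
                     tolerance = 1e-9)
        rshift <- rnorm(5); cshift <- rnorm(6)
        expect_equal(biclusterMSR(v + outer(rshift, cshift, `+`)),
                     biclusterMSR(v), tolerance = 1e-9)
        a <- runif(5, 0.1, 3)
        expect_equal(virtualError(v * a + rshift), virtualError(v),
                     tolerance = 1e-9)
    }
})

test_that("VAR supports matrix-global centring via globalMean", {
    v <- matrix(c(1, 3, 2, 4), 2, 2)
    expect_equal(biclusterVariance(v, globalMean = 0), mean(v^2))
})

test_that("computeMetrics composes per-bicluster indices with sizes", {
    sm <- ScanMatrix(rbind(c(1, 2, 9), c(3, 5, 9), c(0, 1, 2)),
                     matrixId = "toy")
    set <- BiclusterSet(list(
        materializeBicluster(sm, 1:2, 1:2,
                             provenance = list(algorithm = "a", run = 1L)),
        materializeBicluster(sm, 1:3, 1:3,
                             provenance = list(algorithm = "b", run = 2L))))
    rec <- computeMetrics(set)
    expect_equal(nrow(rec), 2L)
    expect_equal(rec$msr[1], 0.0625)
    expect_equal(rec$area, c(4L, 9L))
    expect_equal(rec$algorithm, c("a", "b"))
    expect_equal(rec$var[1], biclusterVariance(biclusterValues(set[[1]])))

    empty <- computeMetrics(BiclusterSet(list()))
    expect_equal(nrow(empty), 0L)
    expect_true(all(c("scan", "ve", "smsr") %in% names(empty)))
})

test_that("VE grows on average with additive noise on planted blocks", {
    set.seed(14)
    noise <- c(0.05, 0.2, 0.6)
    meanVE <- vapply(noise, function(ns) {
        ves <- vapply(1:50, function(i) {
            block <- outer(rnorm(5, sd = 2), rnorm(8), `+`)  # shifting
            virtualError(block + matrix(rnorm(40, sd = ns), 5, 8))
        }, numeric(1))
        mean(ves)
    }, numeric(1))
    expect_true(all(diff(meanVE) > 0))
})
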