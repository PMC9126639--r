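symDisc <- function(codes, k, off = FALSE) {
    new("DiscretizedMatrix", symbols = codes, alphabetSize = as.integer(k),
        scheme = if (off) "transitions" else "rowwise_bins",
        transitionOffset = off)
}

test_that("CCC reproduces the worked symbolic example", {
    # rows: AABB / AABC / CABB over 4 columns (A=0, B=1, C=2)
    codes <- rbind(c(0L, 0L, 1L, 1L),
                   c(0L, 0L, 1L, 2L),
                   c(2L, 0L, 1L, 1L))
    scan <- randomScan(3, 4, seed = 50)
    got <- cccBiclustering(scan, symDisc(codes, 3))
    expect_setequal(setKeys(got),
                    c(bcKey(1:3, 2:3), bcKey(c(1, 3), 2:4), bcKey(1:2, 1:3)))
})

test_that("identical rows give a single all-spanning bicluster", {
    codes <- matrix(rep(c(0L, 1L, 0L, 2L), each = 4), 4, 4)
    scan <- randomScan(4, 4, seed = 51)
    got <- cccBiclustering(scan, symDisc(codes, 3))
    expect_identical(setKeys(got), bcKey(1:4, 1:4))
})

test_that("CCC equals the brute-force maximal-interval oracle", {
    set.seed(52)
    for (i in 1:200) {
        n <- sample(2:6, 1); p <- sample(3:8, 1)
        scan <- ScanMatrix(matrix(rnorm(n * p), n, p))
        disc <- if (i %% 2 == 0) discretizeRowwise(scan, sample(2:3, 1))
                else discretizeTransitions(scan, 3L)
        got <- cccBiclustering(scan, disc)
        expect_identical(setKeys(got),
                         bruteCCC(symbolMatrix(disc),
                                  disc@transitionOffset))
    }
})

test_that("CCC output is contiguous in time, materialised and 2x2-filtered", {
    g <- generateScan(scanSpec(nRegions = 15, nTime = 60, seed = 53,
                               planted = plantedSpec(nBlocks = 1)))
    set <- cccBiclustering(g$scan, discretizeTransitions(g$scan, 3L))
    expect_gt(length(set), 0)
    for (b in biclusters(set)) {
        expect_true(all(diff(biclusterCols(b)) == 1L))  # contiguous time
        expect_gte(length(biclusterRows(b)), 2L)
        expect_gte(length(biclusterCols(b)), 2L)
        expect_identical(biclusterValues(b),
                         scanValues(g$scan)[biclusterRows(b),
                                            biclusterCols(b), drop = FALSE])
    }
})

test_that("CCC recovers a zero-noise planted block exactly", {
    g <- generateScan(scanSpec(noiseSd = 0, seed = 54,
                               planted = plantedSpec(nBlocks = 2)))
    set <- cccBiclustering(g$scan, discretizeTransitions(g$scan, 3L))
    expect_equal(unname(bestRecovery(set, g$planted)), c(1, 1))
})

test_that("bimax matches the worked 3x3 example and the brute-force oracle", {
    B <- rbind(c(1L, 1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 1L))
    scan <- randomScan(3, 3, seed = 55)
    got <- bimaxBiclustering(scan, new("DiscretizedMatrix", symbols = B,
                                       alphabetSize = 2L, scheme = "binary",
                                       transitionOffset = FALSE))
    expect_setequal(setKeys(got), c(bcKey(1:2, 1:2), bcKey(2:3, 2:3)))

    set.seed(56)
    for (i in 1:200) {
        n <- sample(3:8, 1); p <- sample(3:8, 1)
        B <- matrix(rbinom(n * p, 1L, runif(1, 0.2, 0.8)), n, p)
        scan <- ScanMatrix(matrix(rnorm(n * p), n, p))
        disc <- new("DiscretizedMatrix", symbols = B, alphabetSize = 2L,
                    scheme = "binary", transitionOffset = FALSE)
        expect_identical(setKeys(bimaxBiclustering(scan, disc)),
                         bruteBimax(B))
    }
})

test_that("bimax edge cases: all-ones and all-zeros matrices", {
    ones <- new("DiscretizedMatrix", symbols = matrix(1L, 4, 5),
                alphabetSize = 2L, scheme = "binary",
                transitionOffset = FALSE)
    scan <- randomScan(4, 5, seed = 57)
    expect_identical(setKeys(bimaxBiclustering(scan, ones)), bcKey(1:4, 1:5))

    zeros <- new("DiscretizedMatrix", symbols = matrix(0L, 4, 5),
                 alphabetSize = 2L, scheme = "binary",
                 transitionOffset = FALSE)
    expect_equal(length(bimaxBiclustering(scan, zeros)), 0L)
    expect_error(bimaxBiclustering(scan, discretizeRowwise(scan, 3)),
                 "binary")
})

test_that("bimax truncation keeps the largest-area biclusters first", {
    set.seed(58)
    scan <- ScanMatrix(matrix(rnorm(12 * 20), 12, 20))
    disc <- binarizeMatrix(scan)
    full <- bimaxBiclustering(scan, disc, maxBiclusters = 100000L)
    small <- bimaxBiclustering(scan, disc, maxBiclusters = 5L)
    expect_equal(length(small), min(5L, length(full)))
    areas <- function(s) sort(vapply(biclusters(s), function(b)
        prod(dim(b)), numeric(1)), decreasing = TRUE)
    expect_equal(areas(small), utils::head(areas(full), length(small)))
})

test_that("xmotifs finds fully conserved row groups and is seed-deterministic", {
    # two row groups with identical symbol profiles across all columns
    set.seed(59)
    profA <- sample(0:2, 12, replace = TRUE)
    profB <- sample(0:2, 12, replace = TRUE)
    codes <- rbind(matrix(profA, 3, 12, byrow = TRUE),
                   matrix(profB, 4, 12, byrow = TRUE))
    scan <- randomScan(7, 12, seed = 60)
    got <- xmotifsBiclustering(scan, symDisc(codes, 3), ns = 6, nd = 20,
                               sdSize = 4, seed = 1)
    expect_true(bcKey(1:3, 1:12) %in% setKeys(got) ||
                bcKey(4:7, 1:12) %in% setKeys(got))

    again <- xmotifsBiclustering(scan, symDisc(codes, 3), ns = 6, nd = 20,
                                 sdSize = 4, seed = 1)
    expect_identical(setKeys(got), setKeys(again))
    other <- xmotifsBiclustering(scan, symDisc(codes, 3), ns = 6, nd = 20,
                                 sdSize = 4, seed = 2)
    expect_s4_class(other, "BiclusterSet")
    expect_error(xmotifsBiclustering(scan, symDisc(codes, 3), sdSize = 12),
                 "smaller")
})

test_that("xmotifs recovers a planted conserved block over most seeds", {
    # conserved state spanning most of the recording, as xMotifs expects
    g <- generateScan(scanSpec(nRegions = 20, nTime = 60, noiseSd = 0,
                               seed = 61,
                               planted = plantedSpec(nBlocks = 1,
                                                     blockRows = 6,
                                                     blockCols = 50)))
    hits <- vapply(1:5, function(s) {
        set <- xmotifsBiclustering(g$scan, discretizeTransitions(g$scan, 2L),
                                   seed = s)
        max(bestRecovery(set, g$planted))
    }, numeric(1))
    expect_gte(sum(hits >= 0.9), 4)
})

test_that("runRepeated pools runs, dedupes, and keeps run provenance", {
    g <- generateScan(scanSpec(nRegions = 12, nTime = 40, seed = 62,
                               planted = plantedSpec(nBlocks = 1,
                                                     blockRows = 4,
                                                     blockCols = 10)))
    algo <- function(scan, seed, run)
        xmotifsBiclustering(scan, ns = 3, nd = 10, sdSize = 4,
                            seed = seed, run = run)
    pooled <- runRepeated(g$scan, algo, nRuns = 8, seed = 5)
    keys <- setKeys(pooled)
    expect_identical(keys, unique(keys))

    # brute-force distinct count over the individual runs
    perRun <- lapply(1:8, function(i)
        algo(g$scan, seed = fmribic:::.deriveSeed(5, i), run = i))
    allKeys <- unlist(lapply(perRun, setKeys))
    expect_equal(length(pooled), length(unique(allKeys)))
    runs <- vapply(biclusters(pooled), function(b)
        provenance(b)$run, integer(1))
    expect_true(all(runs >= 1L & runs <= 8L))

    # a deterministic algorithm pooled over runs collapses to a single run
    det <- function(scan, seed, run) cccBiclustering(scan)
    one <- det(g$scan, 1, 1)
    expect_equal(length(runRepeated(g$scan, det, nRuns = 3, seed = 1)),
                 length(one))
})
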