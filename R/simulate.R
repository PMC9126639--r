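.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

.deriveSeed <- function(master, i) {
    as.integer((as.numeric(master) %% 2147483647 * 48271 +
                i * 104729) %% 2147483647)
}

#' Construct a PlantedBicluster ground-truth description
#'
#' @param rows,cols 1-based index sets of the block.
#' @param patternType "constant", "shifting" or "scaling".
#' @param rowEffects,colEffects effect vectors pi_i and beta_j (ignored for
#'   constant patterns).
#' @param baseLevel constant level pi (constant patterns).
#' @return A \linkS4class{PlantedBicluster}.
#' @export
plantedBicluster <- function(rows, cols, patternType,
                             rowEffects = numeric(), colEffects = numeric(),
                             baseLevel = 0) {
    new("PlantedBicluster", rows = sort(as.integer(rows)),
        cols = sort(as.integer(cols)), patternType = patternType,
        rowEffects = as.numeric(rowEffects),
        colEffects = as.numeric(colEffects),
        baseLevel = as.numeric(baseLevel))
}

#' Pattern values of a planted block
#'
#' @param pb a \linkS4class{PlantedBicluster}.
#' @return Numeric matrix |I| x |J| with the noiseless pattern values.
#' @export
plantedValues <- function(pb) {
    switch(pb@patternType,
           constant = matrix(pb@baseLevel, length(pb@rows), length(pb@cols)),
           shifting = outer(pb@rowEffects, pb@colEffects, `+`),
           scaling  = outer(pb@rowEffects, pb@colEffects, `*`))
}

#' Parameters for sampling planted blocks
#'
#' Describes how many coherent blocks a scan hides and what they look like.
#' Column effects emulate an event-related response: an alternating
#' on/off waveform of amplitude \code{colEffectSize} with uniform jitter, so
#' consecutive time points inside a block move by a clearly visible step.
#' Shifting row effects mix signs (half the regions activate, half
#' deactivate); scaling row effects are strictly positive by default so a
#' noiseless scaling block has virtual error zero.
#'
#' @param nBlocks number of planted blocks per scan.
#' @param type pattern family: "constant", "shifting" or "scaling".
#' @param blockRows,blockCols block dimensions (columns are contiguous).
#' @param rowEffectSize magnitude of the per-region offsets/gains.
#' @param colEffectSize amplitude of the alternating temporal waveform.
#' @param baseLevel level of constant blocks.
#' @param allowNegativeScaling permit negative scaling factors (adversarial
#'   setting; breaks the VE = 0 identity on purpose).
#' @param overwrite if TRUE (default) planted values replace the baseline
#'   inside the block, making the zero-noise metric identities exact; if
#'   FALSE they are added on top of it.
#' @return A list of class parameters consumed by \code{\link{generateScan}}.
#' @export
plantedSpec <- function(nBlocks = 3L, type = "shifting",
                        blockRows = 8L, blockCols = 15L,
                        rowEffectSize = 2, colEffectSize = 0.6,
                        baseLevel = 1, allowNegativeScaling = FALSE,
                        overwrite = TRUE) {
    stopifnot(type %in% c("constant", "shifting", "scaling"))
    list(nBlocks = as.integer(nBlocks), type = type,
         blockRows = as.integer(blockRows), blockCols = as.integer(blockCols),
         rowEffectSize = rowEffectSize, colEffectSize = colEffectSize,
         baseLevel = baseLevel,
         allowNegativeScaling = allowNegativeScaling,
         overwrite = overwrite)
}

#' Specification of one synthetic scan
#'
#' Defaults mirror the artificial fMRI collection the generator emulates:
#' 30 regions observed over 150 time points, smooth unit-amplitude
#' baselines, planted coherent blocks, and Gaussian observation noise of
#' standard deviation 0.1.
#'
#' @param nRegions,nTime matrix dimensions (regions x time points).
#' @param noiseSd standard deviation of the i.i.d. Gaussian noise added to
#'   every cell (same units as the signal).
#' @param baselineMean mean intensity level of the baselines. Positive by
#'   default because parcellated BOLD intensities are positive-valued;
#'   this keeps row and column means of arbitrary submatrices away from
#'   zero, where the scaling mean squared residue degenerates.
#' @param baselineAmplitude population sd of each region's smooth baseline.
#' @param baselineSmoothness moving-average window (in time points) of the
#'   low-pass filter applied to each region's Gaussian walk.
#' @param planted either a \code{\link{plantedSpec}} (blocks sampled per
#'   scan) or an explicit list of \linkS4class{PlantedBicluster}.
#' @param seed integer RNG seed; every draw of the scan flows from it.
#' @return A list of generator settings for \code{\link{generateScan}}.
#' @export
scanSpec <- function(nRegions = 30L, nTime = 150L, noiseSd = 0.1,
                     baselineMean = 8, baselineAmplitude = 1,
                     baselineSmoothness = 9L,
                     planted = plantedSpec(), seed = 1L) {
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    stopifnot(nRegions >= 2L, nTime >= 2L)
    list(nRegions = as.integer(nRegions), nTime = as.integer(nTime),
         noiseSd = noiseSd, baselineMean = baselineMean,
         baselineAmplitude = baselineAmplitude,
         baselineSmoothness = as.integer(baselineSmoothness),
         planted = planted, seed = as.integer(seed))
}

.smoothBaseline <- function(n, p, amplitude, window) {
    raw <- matrix(rnorm(n * (p + 2L * window)), n)
    kernel <- rep(1 / window, window)
    sm <- t(apply(raw, 1L, function(x)
        stats::filter(x, kernel, sides = 2L)))
    sm <- sm[, window + seq_len(p), drop = FALSE]
    sdp <- sqrt(rowMeans((sm - rowMeans(sm))^2))
    sdp[sdp == 0] <- 1
    (sm - rowMeans(sm)) / sdp * amplitude
}

.sampleBlocks <- function(ps, n, p, center = 0) {
    nb <- ps$nBlocks
    if (nb == 0L) return(list())
    if (nb * ps$blockRows > n || ps$blockCols > p)
        stop("planted blocks do not fit inside the scan")
    rowPool <- sample.int(n)
    segment <- floor(p / nb)
    if (segment < ps$blockCols)
        stop("planted blocks do not fit along the time axis")
    alt <- function(k) rep_len(c(1, -1), k)
    lapply(seq_len(nb), function(b) {
        rows <- sort(rowPool[(b - 1L) * ps$blockRows + seq_len(ps$blockRows)])
        start <- (b - 1L) * segment +
            sample.int(segment - ps$blockCols + 1L, 1L)
        cols <- start:(start + ps$blockCols - 1L)
        nr <- ps$blockRows; nc <- ps$blockCols
        if (ps$type == "shifting") {
            signs <- alt(nr)[sample.int(nr)]
            # offsets ride on the scan's intensity level so block edges
            # step up for half the regions and down for the other half
            re <- center + signs * ps$rowEffectSize + rnorm(nr, 0, 0.2)
            ce <- alt(nc) * ps$colEffectSize + runif(nc, -0.1, 0.1)
            plantedBicluster(rows, cols, "shifting", re, ce)
        } else if (ps$type == "scaling") {
            re <- runif(nr, 0.3, 1.2) * ps$rowEffectSize
            if (ps$allowNegativeScaling)
                re <- re * sample(c(-1, 1), nr, replace = TRUE)
            ce <- 1 + (5 / 6) * ps$colEffectSize * alt(nc) +
                runif(nc, -0.08, 0.08)
            plantedBicluster(rows, cols, "scaling", re, ce)
        } else {
            plantedBicluster(rows, cols, "constant",
                             baseLevel = ps$baseLevel)
        }
    })
}

#' Generate one synthetic Region x Time scan
#'
#' Builds a smooth random baseline per region (a low-pass filtered Gaussian
#' walk scaled to \code{baselineAmplitude}), embeds the planted coherent
#' blocks (overwriting the baseline by default), and adds i.i.d. Gaussian
#' noise of sd \code{noiseSd} to every cell. Deterministic for a fixed
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{scanSpec}}.
#' @param matrixId identifier for the generated scan.
#' @return List with \code{scan} (a \linkS4class{ScanMatrix}) and
#'   \code{planted} (list of \linkS4class{PlantedBicluster}).
#' @examples
#' gs <- generateScan(scanSpec(nRegions = 10, nTime = 40, seed = 7,
#'                             planted = plantedSpec(nBlocks = 1,
#'                                                   blockRows = 4,
#'                                                   blockCols = 10)))
#' dim(gs$scan)
#' @export
generateScan <- function(spec, matrixId = paste0("scan", spec$seed)) {
    .withSeed(spec$seed, {
        n <- spec$nRegions; p <- spec$nTime
        m <- (spec$baselineMean %||% 0) +
            .smoothBaseline(n, p, spec$baselineAmplitude,
                            spec$baselineSmoothness)
        planted <- spec$planted
        if (!is.null(planted$nBlocks))          # parameters, not blocks
            planted <- .sampleBlocks(planted, n, p,
                                     center = spec$baselineMean %||% 0)
        overwrite <- if (!is.null(spec$planted$overwrite))
            spec$planted$overwrite else TRUE
        for (pb in planted) {
            if (max(pb@rows) > n || max(pb@cols) > p)
                stop("planted block exceeds the scan bounds")
            vals <- plantedValues(pb)
            if (overwrite) m[pb@rows, pb@cols] <- vals
            else m[pb@rows, pb@cols] <- m[pb@rows, pb@cols] + vals
        }
        m <- m + matrix(rnorm(n * p, 0, spec$noiseSd), n, p)
        list(scan = ScanMatrix(m, matrixId = matrixId), planted = planted)
    })
}

#' Generate a collection of synthetic scans
#'
#' Per-scan seeds are derived deterministically from the master seed, so a
#' fixed master seed reproduces all scans bit for bit. Defaults mirror the
#' artificial collection shape: 20 scans of 30 regions x 150 time points.
#'
#' @param nScans number of scans (default 20).
#' @param spec template \code{\link{scanSpec}}; its \code{seed} is replaced
#'   per scan.
#' @param seed master seed.
#' @param collectionId identifier stamped on the scan ids.
#' @return List with one element per scan, each a list \code{scan} /
#'   \code{planted} as in \code{\link{generateScan}}.
#' @export
generateCollection <- function(nScans = 20L, spec = scanSpec(), seed = 1L,
                               collectionId = "collection") {
    stopifnot(nScans >= 1L)
    lapply(seq_len(nScans), function(i) {
        s <- spec
        s$seed <- .deriveSeed(seed, i)
        generateScan(s, matrixId = paste0(collectionId, "-scan", i))
    })
}

#' Jaccard recovery score between a found and a planted bicluster
#'
#' Treats each bicluster as the set of cells I x J and returns
#' |intersection| / |union|: 1 for identical blocks, 0 for disjoint ones.
#'
#' @param found a \linkS4class{Bicluster} (or any object with
#'   \code{rows}/\code{cols} slots).
#' @param truth a \linkS4class{PlantedBicluster}.
#' @return Scalar in [0, 1].
#' @export
recoveryScore <- function(found, truth) {
    ri <- length(intersect(found@rows, truth@rows))
    ci <- length(intersect(found@cols, truth@cols))
    inter <- ri * ci
    a1 <- length(found@rows) * length(found@cols)
    a2 <- length(truth@rows) * length(truth@cols)
    inter / (a1 + a2 - inter)
}

#' Best recovery of each planted block by a bicluster set
#'
#' @param set a \linkS4class{BiclusterSet} found on one scan.
#' @param planted list of \linkS4class{PlantedBicluster} for that scan.
#' @return Numeric vector: for each planted block, the maximum
#'   \code{\link{recoveryScore}} over the set (0 when the set is empty).
#' @export
bestRecovery <- function(set, planted) {
    vapply(planted, function(pb) {
        if (length(set) == 0L) return(0)
        max(vapply(biclusters(set), recoveryScore, numeric(1), truth = pb))
    }, numeric(1))
}
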