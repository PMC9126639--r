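.metricCols <- c("var", "msr", "smsr", "ve")

#' Median/sd summary of the quality indices per algorithm
#'
#' For each group (algorithm by default) and each of the four indices,
#' reports the median and the sample standard deviation over the group's
#' biclusters. Undefined SMSR values are excluded from the SMSR summary and
#' counted separately.
#'
#' @param records metrics table from \code{\link{computeMetrics}}.
#' @param groupBy grouping column (default \code{"algorithm"}).
#' @return Long \code{data.frame} with columns \code{group}, \code{metric},
#'   \code{median}, \code{sd}, \code{n}, \code{n_undefined}.
#' @export
summarizeMetrics <- function(records, groupBy = "algorithm") {
    stopifnot(groupBy %in% names(records))
    groups <- split(records, records[[groupBy]])
    groups <- groups[lengths(groups) > 0L]
    rows <- lapply(names(groups), function(g) {
        df <- groups[[g]]
        do.call(rbind, lapply(.metricCols, function(m) {
            x <- df[[m]]
            nUndef <- sum(is.na(x))
            x <- x[!is.na(x)]
            data.frame(group = g, metric = m,
                       median = if (length(x)) stats::median(x) else NA_real_,
                       sd = if (length(x) > 1L) stats::sd(x) else 0,
                       n = length(x), n_undefined = nUndef,
                       stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Top-K bicluster selection with a virtual-error floor
#'
#' Implements the comparison protocol for solutions of very different sizes:
#' records with VE below \code{veMin} are removed as statistical artifacts
#' (near-duplicate trivial patterns), the remainder is sorted by ascending
#' VE (lower is better) with ties broken by larger area and then input
#' order, and the first \code{K} records are returned. \code{K} defaults to
#' 50 for artificial-shape collections; 500 is the convention for the larger
#' real-shape collections.
#'
#' @param records metrics table from \code{\link{computeMetrics}}.
#' @param K number of biclusters to keep.
#' @param veMin VE floor (default 0.01).
#' @return The selected rows of \code{records}, at most \code{K} of them,
#'   sorted by VE.
#' @export
topKFilter <- function(records, K = 50L, veMin = 0.01) {
    stopifnot(K >= 1L)
    keep <- records[records$ve >= veMin, , drop = FALSE]
    if (nrow(keep) == 0L) return(keep)
    ord <- order(keep$ve, -keep$area, seq_len(nrow(keep)))
    keep <- keep[ord, , drop = FALSE]
    utils::head(keep, K)
}

#' Size summary per algorithm
#'
#' Median and sample sd of the number of time points, the number of regions
#' and the area of the biclusters in each group. The area median is taken
#' over the area distribution itself (not the product of the two medians).
#'
#' @inheritParams summarizeMetrics
#' @return \code{data.frame} with one row per group and columns
#'   \code{time_median}, \code{time_sd}, \code{region_median},
#'   \code{region_sd}, \code{area_median}, \code{area_sd}, \code{n}.
#' @export
sizeSummary <- function(records, groupBy = "algorithm") {
    stopifnot(groupBy %in% names(records))
    groups <- split(records, records[[groupBy]])
    groups <- groups[lengths(groups) > 0L]
    sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    out <- do.call(rbind, lapply(names(groups), function(g) {
        df <- groups[[g]]
        data.frame(group = g,
                   time_median = stats::median(df$n_cols),
                   time_sd = sd0(df$n_cols),
                   region_median = stats::median(df$n_rows),
                   region_sd = sd0(df$n_rows),
                   area_median = stats::median(df$area),
                   area_sd = sd0(df$area),
                   n = nrow(df), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

.r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(0)
    stats::cor(x[ok], y[ok])^2
}

#' Infer the dominant bicluster pattern type
#'
#' Each specific coherence measure is diagnostic of one pattern family:
#' variance for constant, MSR for shifting, SMSR for scaling biclusters.
#' The virtual error captures all of them, so across a set of biclusters
#' the squared Pearson correlation of VE with each specific measure points
#' at the family actually present: the label is the argmax of the three
#' r-squared values. Pairs with undefined SMSR are dropped pairwise;
#' zero-variance metric vectors give r-squared 0; with fewer than 3 usable
#' pairs, or all r-squared below \code{floor}, the label is
#' \code{"undetermined"}.
#'
#' @param records metrics table from \code{\link{computeMetrics}}.
#' @param floor minimum r-squared needed to commit to a label.
#' @return List with \code{r2_var}, \code{r2_msr}, \code{r2_smsr} and
#'   \code{label} ("constant", "shifting", "scaling" or "undetermined").
#' @export
inferPatternType <- function(records, floor = 0.01) {
    r2 <- c(var = .r2(records$ve, records$var),
            msr = .r2(records$ve, records$msr),
            smsr = .r2(records$ve, records$smsr))
    labelMap <- c(var = "constant", msr = "shifting", smsr = "scaling")
    usable <- !is.na(r2)
    label <- if (!any(usable) || max(r2[usable]) < floor) "undetermined"
             else labelMap[[names(which.max(replace(r2, !usable, -Inf)))]]
    list(r2_var = unname(r2[["var"]]), r2_msr = unname(r2[["msr"]]),
         r2_smsr = unname(r2[["smsr"]]), label = label)
}

#' Pooled comparison of biclustering against clustering baselines
#'
#' Pools the metric records of every algorithm inside each super-group
#' (typically biclustering, region clustering and temporal clustering) and
#' compares the pooled medians — lower is better for every index. No
#' significance testing is attached.
#'
#' @param records metrics table from \code{\link{computeMetrics}}.
#' @param groups named list mapping super-group name to the algorithm names
#'   it pools.
#' @param metrics indices to compare (default all four).
#' @return List with \code{medians} (data.frame group x metric) and
#'   \code{ordering} (per metric, super-groups sorted best first).
#' @export
compareGroups <- function(records,
                          groups = list(
                              biclustering = c("ccc", "bimax", "xmotifs"),
                              region_clustering = c("kmeans-regions",
                                                    "ward-regions"),
                              temporal_clustering = c("kmeans-times",
                                                      "ward-times")),
                          metrics = .metricCols) {
    med <- do.call(rbind, lapply(names(groups), function(g) {
        df <- records[records$algorithm %in% groups[[g]], , drop = FALSE]
        if (nrow(df) == 0L)
            stop("super-group '", g, "' has no records")
        vals <- vapply(metrics, function(m)
            stats::median(df[[m]], na.rm = TRUE), numeric(1))
        cbind(data.frame(group = g, n = nrow(df),
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(vals)))
    }))
    rownames(med) <- NULL
    ordering <- lapply(metrics, function(m)
        med$group[order(med[[m]])])
    names(ordering) <- metrics
    list(medians = med, ordering = ordering)
}

#' Planted pattern-type identification experiment
#'
#' Runs the controlled experiment behind pattern-type inference: scans are
#' generated whose planted blocks all belong to one pattern family, over a
#' ladder of observation-noise levels and with heterogeneous block sizes
#' and amplitudes (emulating the size heterogeneity of real biclustering
#' output); the planted blocks are materialised, their quality indices
#' computed, and \code{\link{inferPatternType}} applied to the pooled
#' records.
#'
#' @param type planted family: "constant", "shifting" or "scaling".
#' @param seed master seed for the whole experiment.
#' @param noiseLevels observation-noise sds, low to high; includes 0 so the
#'   noise-free identity anchors the correlations.
#' @param scansPerLevel scans generated per noise level (2 blocks each).
#' @param nRegions,nTime scan dimensions.
#' @return List with \code{records} (the pooled metrics table) and the
#'   fields of \code{\link{inferPatternType}}'s report.
#' @export
patternRecoveryExperiment <- function(type, seed,
                                      noiseLevels = c(0, 0.02, 0.08, 0.15,
                                                      0.25, 0.4),
                                      scansPerLevel = 4L,
                                      nRegions = 30L, nTime = 60L) {
    recs <- list()
    i <- 0L
    for (ns in noiseLevels) {
        for (r in seq_len(scansPerLevel)) {
            i <- i + 1L
            sub <- .deriveSeed(seed, i)
            dims <- .withSeed(sub, list(
                rows = sample(3:10, 1L), cols = sample(6:20, 1L),
                amp = stats::runif(1L, 0.5, 2),
                base = stats::runif(1L, 0.5, 2)))
            sp <- scanSpec(nRegions = nRegions, nTime = nTime,
                           noiseSd = ns, seed = .deriveSeed(sub, 1L),
                           planted = plantedSpec(
                               nBlocks = 2L, type = type,
                               blockRows = dims$rows,
                               blockCols = dims$cols,
                               rowEffectSize = 2 * dims$amp,
                               baseLevel = dims$base))
            g <- generateScan(sp)
            for (pb in g$planted)
                recs[[length(recs) + 1L]] <- materializeBicluster(
                    g$scan, pb@rows, pb@cols,
                    provenance = list(algorithm = "planted"))
        }
    }
    records <- computeMetrics(BiclusterSet(recs))
    c(list(records = records), inferPatternType(records))
}

#' Run the full algorithm suite on a collection of scans
#'
#' Applies every reference algorithm to each scan of a collection — CCC on
#' the per-row 5-symbol discretisation, the Bimax-style search on an
#' activation-like binarisation (row mean + 1 sd), the greedy
#' conserved-state search pooled over repeated runs, and the four
#' clustering baselines — then pools each algorithm's biclusters across
#' scans (union + dedupe) and returns the combined metrics table.
#'
#' @param coll list of scans as returned by \code{\link{generateCollection}}
#'   (elements carry \code{$scan}), or a plain list of
#'   \linkS4class{ScanMatrix}.
#' @param seed master seed for the stochastic algorithms.
#' @param nRunsGreedy repetitions for the greedy search (default 30).
#' @param nRunsKmeans repetitions for the k-means baselines.
#' @return Metrics \code{data.frame} as from \code{\link{computeMetrics}}.
#' @export
runAlgorithmSuite <- function(coll, seed = 1L, nRunsGreedy = 30L,
                              nRunsKmeans = 5L) {
    sets <- list()
    add <- function(s) sets[[length(sets) + 1L]] <<- s
    for (i in seq_along(coll)) {
        scan <- coll[[i]]$scan %||% coll[[i]]
        add(cccBiclustering(scan, discretizeRowwise(scan, 5L)))
        add(bimaxBiclustering(scan, binarizeMatrix(scan,
                                                   "above_row_mean_plus",
                                                   c = 1)))
        add(runRepeated(scan, function(s2, seed, run)
            xmotifsBiclustering(s2, seed = seed, run = run),
            nRuns = nRunsGreedy, seed = .deriveSeed(seed, i)))
        add(runRepeated(scan, function(s2, seed, run)
            clusterRegions(s2, "kmeans", seed = seed, run = run),
            nRuns = nRunsKmeans, seed = .deriveSeed(seed, 1000L + i)))
        add(clusterRegions(scan, "ward"))
        add(runRepeated(scan, function(s2, seed, run)
            clusterTimes(s2, "kmeans", seed = seed, run = run),
            nRuns = nRunsKmeans, seed = .deriveSeed(seed, 2000L + i)))
        add(clusterTimes(scan, "ward"))
    }
    computeMetrics(unionCollection(sets, collectionId = "suite"))
}
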