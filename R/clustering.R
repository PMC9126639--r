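.partitionToSets <- function(labels) {
    split(seq_along(labels), labels)
}

.clusterProfiles <- function(profiles, method, k, seed) {
    if (method == "kmeans") {
        .withSeed(seed, stats::kmeans(profiles, centers = k,
                                      nstart = 5L, iter.max = 50L)$cluster)
    } else {
        hc <- stats::hclust(stats::dist(profiles), method = "ward.D2")
        stats::cutree(hc, k = k)
    }
}

#' Region clustering expressed as biclusters
#'
#' Partitions the regions (rows) by their full time profiles and wraps each
#' cluster as a bicluster spanning every time point — clustering viewed as a
#' degenerate biclustering. Supports k-means (stochastic; seeded) and
#' Ward's hierarchical method (ward.D2 on Euclidean distances).
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param method "kmeans" or "ward".
#' @param nClusters number of clusters; defaults to
#'   \code{floor(sqrt(n regions))}. Must lie in [2, n] unless
#'   \code{allowSingle} permits 1.
#' @param seed RNG seed (k-means only).
#' @param allowSingle allow \code{nClusters = 1} (whole matrix as one
#'   bicluster).
#' @param run run index recorded in provenance.
#' @return A \linkS4class{BiclusterSet}; the row sets partition the regions.
#' @export
clusterRegions <- function(scan, method = c("kmeans", "ward"),
                           nClusters = NULL, seed = 1L,
                           allowSingle = FALSE, run = NA_integer_) {
    method <- match.arg(method)
    v <- scanValues(scan)
    n <- nrow(v)
    if (is.null(nClusters)) nClusters <- max(2L, floor(sqrt(n)))
    lo <- if (allowSingle) 1L else 2L
    if (nClusters < lo || nClusters > n)
        stop("nClusters must be in [", lo, ", ", n, "]")
    labels <- .clusterProfiles(v, method, nClusters, seed)
    pairs <- lapply(.partitionToSets(labels), function(idx)
        list(rows = idx, cols = seq_len(ncol(v))))
    .asSet(scan, pairs, paste0(method, "-regions"), run = run)
}

#' Temporal clustering expressed as biclusters
#'
#' Symmetric to \code{\link{clusterRegions}}: time points (columns) are
#' clustered by their region profiles, and each cluster becomes a bicluster
#' spanning all regions.
#'
#' @inheritParams clusterRegions
#' @return A \linkS4class{BiclusterSet}; the column sets partition the time
#'   points.
#' @export
clusterTimes <- function(scan, method = c("kmeans", "ward"),
                         nClusters = NULL, seed = 1L,
                         allowSingle = FALSE, run = NA_integer_) {
    method <- match.arg(method)
    v <- scanValues(scan)
    p <- ncol(v)
    if (is.null(nClusters)) nClusters <- max(2L, floor(sqrt(p)))
    lo <- if (allowSingle) 1L else 2L
    if (nClusters < lo || nClusters > p)
        stop("nClusters must be in [", lo, ", ", p, "]")
    labels <- .clusterProfiles(t(v), method, nClusters, seed)
    pairs <- lapply(.partitionToSets(labels), function(idx)
        list(rows = seq_len(nrow(v)), cols = idx))
    .asSet(scan, pairs, paste0(method, "-times"), run = run)
}
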