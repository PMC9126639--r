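#' Materialise a bicluster from a scan
#'
#' Builds a \linkS4class{Bicluster} by slicing the \emph{original} scan
#' values at the given row and column index sets. Algorithms that search a
#' discretised or normalised view of the scan must pass their index sets
#' through this function so every bicluster is evaluated on the original
#' data. Indices are canonicalised: duplicates removed, sorted ascending.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param rows,cols 1-based index vectors into the scan.
#' @param provenance list with optional \code{algorithm}, \code{run},
#'   \code{scan} entries.
#' @return A \linkS4class{Bicluster} carrying the original values at
#'   rows x cols.
#' @examples
#' sm <- ScanMatrix(matrix(1:4, 2, 2, byrow = TRUE))
#' materializeBicluster(sm, rows = c(1, 2), cols = 2)
#' @export
materializeBicluster <- function(scan, rows, cols, provenance = list()) {
    stopifnot(is(scan, "ScanMatrix"))
    rows <- sort(unique(as.integer(rows)))
    cols <- sort(unique(as.integer(cols)))
    if (length(rows) == 0L || length(cols) == 0L)
        stop("invalid bicluster: empty row or column set")
    n <- nrow(scan@values); p <- ncol(scan@values)
    bad <- rows[rows < 1L | rows > n]
    if (length(bad))
        stop("row index out of range [1, ", n, "]: ", bad[1L])
    bad <- cols[cols < 1L | cols > p]
    if (length(bad))
        stop("column index out of range [1, ", p, "]: ", bad[1L])
    prov <- list(algorithm = provenance$algorithm %||% NA_character_,
                 run = provenance$run %||% NA_integer_,
                 scan = provenance$scan %||% scan@matrixId)
    new("Bicluster",
        rows = rows, cols = cols,
        values = scan@values[rows, cols, drop = FALSE],
        matrixId = scan@matrixId, provenance = prov)
}

#' Drop undersized biclusters
#'
#' Biclusters with fewer than \code{minRows} rows or \code{minCols} columns
#' carry no pattern worth evaluating (a single row or column is trivially
#' coherent) and are removed before any statistic is computed. Order is
#' preserved.
#'
#' @param set a \linkS4class{BiclusterSet}.
#' @param minRows,minCols minimum size thresholds (default 2 x 2).
#' @return A filtered \linkS4class{BiclusterSet}.
#' @export
filterMinSize <- function(set, minRows = 2L, minCols = 2L) {
    stopifnot(is(set, "BiclusterSet"))
    keep <- vapply(set@biclusters, function(b) {
        length(b@rows) >= minRows && length(b@cols) >= minCols
    }, logical(1))
    BiclusterSet(set@biclusters[keep], set@collectionId)
}

.biclusterKey <- function(b) {
    paste(b@provenance$scan %||% b@matrixId,
          paste(b@rows, collapse = ","),
          paste(b@cols, collapse = ","), sep = "|")
}

#' Collapse duplicate biclusters
#'
#' Two biclusters are duplicates when they share the same scan and identical
#' row and column index sets. The first occurrence wins (its provenance is
#' kept), so pooling repeated stochastic runs never multiply-counts the same
#' bicluster. Idempotent.
#'
#' @param set a \linkS4class{BiclusterSet}.
#' @return A \linkS4class{BiclusterSet} without duplicates.
#' @export
dedupe <- function(set) {
    stopifnot(is(set, "BiclusterSet"))
    keys <- vapply(set@biclusters, .biclusterKey, character(1))
    BiclusterSet(set@biclusters[!duplicated(keys)], set@collectionId)
}

#' Pool bicluster sets across the scans of a collection
#'
#' The result for a data collection is the union of the biclusters generated
#' on each of its scans: sets are concatenated in order and exact
#' (scan, rows, cols) duplicates collapsed.
#'
#' @param perScanSets list of \linkS4class{BiclusterSet}, one per scan.
#' @param collectionId identifier for the pooled collection; defaults to the
#'   (unique) id of the inputs.
#' @return A deduplicated \linkS4class{BiclusterSet}.
#' @export
unionCollection <- function(perScanSets, collectionId = NULL) {
    stopifnot(length(perScanSets) >= 1L)
    ids <- unique(vapply(perScanSets, function(s) s@collectionId,
                         character(1)))
    if (is.null(collectionId)) {
        if (length(ids) > 1L)
            stop("sets belong to different collections: ",
                 paste(ids, collapse = ", "))
        collectionId <- ids
    }
    all <- unlist(lapply(perScanSets, biclusters), recursive = FALSE)
    dedupe(BiclusterSet(all %||% list(), collectionId))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
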