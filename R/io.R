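#' Read a Region x Time matrix from TSV
#'
#' Expected dialect: tab-separated, UTF-8, a header row of time-point
#' labels, a first column of region labels, '.' as the decimal point.
#' Orientation is preserved exactly as stored.
#'
#' @param path file path.
#' @param matrixId identifier for the scan; defaults to the file name
#'   without extension.
#' @return A \linkS4class{ScanMatrix}.
#' @export
readScanMatrix <- function(path, matrixId = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    cells <- strsplit(lines, "\t", fixed = TRUE)
    header <- cells[[1L]]
    p <- length(header) - 1L
    if (p < 1L) stop("parse error: header has no time-point labels")
    body <- cells[-1L]
    vals <- matrix(NA_real_, length(body), p)
    rlab <- character(length(body))
    for (i in seq_along(body)) {
        row <- body[[i]]
        if (length(row) != p + 1L)
            stop("parse error at line ", i + 1L, ": expected ",
                 p + 1L, " fields, got ", length(row))
        rlab[i] <- row[1L]
        num <- suppressWarnings(as.numeric(row[-1L]))
        if (anyNA(num))
            stop("parse error at line ", i + 1L, ", column ",
                 which(is.na(num))[1L] + 1L, ": non-numeric cell")
        vals[i, ] <- num
    }
    if (anyDuplicated(rlab)) stop("duplicate region labels")
    if (anyDuplicated(header[-1L])) stop("duplicate time-point labels")
    if (is.null(matrixId))
        matrixId <- sub("\\.[^.]*$", "", basename(path))
    ScanMatrix(vals, matrixId = matrixId, regionLabels = rlab,
               timeLabels = header[-1L])
}

#' Write a ScanMatrix to TSV
#'
#' Inverse of \code{\link{readScanMatrix}}; the round trip is lossless on
#' values and labels. Output is newline-terminated for golden-file testing.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeScanMatrix <- function(scan, path) {
    v <- scanValues(scan)
    lines <- c(paste(c("region", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i],
                           format(v[i, ], digits = 17, trim = TRUE,
                                  scientific = FALSE)),
                         collapse = "\t"), character(1)))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Bicluster JSON interchange
#'
#' Reads/writes the interchange format used to score the output of external
#' biclustering tools:
#' \preformatted{{"collection": str, "matrix_id": str, "algorithm": str,
#'  "run": int, "biclusters": [{"rows": [int...], "cols": [int...]}]}}
#' Indices are 0-based ascending in the file and converted to this
#' package's 1-based indexing on load. When loading, biclusters are
#' materialised against \code{scan} and out-of-range indices are rejected.
#'
#' @param path JSON file path.
#' @param scan the \linkS4class{ScanMatrix} the indices refer to.
#' @return \code{readBiclusterJSON}: a \linkS4class{BiclusterSet}.
#' @export
readBiclusterJSON <- function(path, scan) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    run <- as.integer(obj$run %||% NA_integer_)
    bl <- obj$biclusters %||% list()
    bs <- lapply(bl, function(b) {
        rows <- as.integer(unlist(b$rows))
        cols <- as.integer(unlist(b$cols))
        if (any(rows < 0L) || any(cols < 0L))
            stop("negative index in ", path)
        materializeBicluster(scan, rows + 1L, cols + 1L,
                             provenance = list(
                                 algorithm = obj$algorithm %||% "imported",
                                 run = run,
                                 scan = obj$matrix_id %||% matrixId(scan)))
    })
    BiclusterSet(bs, collectionId = obj$collection %||% "collection")
}

#' @rdname readBiclusterJSON
#' @param set a \linkS4class{BiclusterSet} to serialise; provenance of the
#'   first member supplies \code{matrix_id}, \code{algorithm}, \code{run}.
#' @return \code{writeBiclusterJSON}: invisibly, \code{path}.
#' @export
writeBiclusterJSON <- function(set, path) {
    first <- if (length(set) > 0L) set[[1L]] else NULL
    obj <- list(
        collection = collectionId(set),
        matrix_id = if (is.null(first)) NA_character_ else first@matrixId,
        algorithm = if (is.null(first)) NA_character_
                    else first@provenance$algorithm,
        run = if (is.null(first)) NA_integer_ else first@provenance$run,
        biclusters = lapply(biclusters(set), function(b)
            list(rows = as.integer(b@rows - 1L),
                 cols = as.integer(b@cols - 1L))))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
    invisible(path)
}

#' Ground-truth JSON for synthetic scans
#'
#' One file per scan:
#' \preformatted{{"planted": [{"rows": [...], "cols": [...],
#'   "type": "shifting", "row_effects": [...], "col_effects": [...],
#'   "base_level": x}]}}
#' Indices 0-based in the file, converted on load.
#'
#' @param planted list of \linkS4class{PlantedBicluster}.
#' @param path file path.
#' @return \code{writeGroundTruthJSON}: invisibly \code{path};
#'   \code{readGroundTruthJSON}: list of \linkS4class{PlantedBicluster}.
#' @export
writeGroundTruthJSON <- function(planted, path) {
    obj <- list(planted = lapply(planted, function(pb)
        list(rows = as.integer(pb@rows - 1L),
             cols = as.integer(pb@cols - 1L),
             type = pb@patternType,
             row_effects = pb@rowEffects,
             col_effects = pb@colEffects,
             base_level = pb@baseLevel)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGroundTruthJSON
#' @export
readGroundTruthJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    lapply(obj$planted, function(b)
        plantedBicluster(as.integer(unlist(b$rows)) + 1L,
                         as.integer(unlist(b$cols)) + 1L,
                         patternType = b$type,
                         rowEffects = as.numeric(unlist(b$row_effects)),
                         colEffects = as.numeric(unlist(b$col_effects)),
                         baseLevel = as.numeric(b$base_level %||% 0)))
}

#' Write a metrics table as CSV
#'
#' Columns: scan, algorithm, run, n_rows, n_cols, area, var, msr, smsr, ve;
#' undefined SMSR as an empty field. Deterministic and newline-terminated.
#'
#' @param records metrics table from \code{\link{computeMetrics}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMetricsCSV <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE, na = "")
    invisible(path)
}

#' @rdname writeMetricsCSV
#' @export
readMetricsCSV <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
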