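#' @import methods
NULL

#' ScanMatrix: a Region x Time data matrix
#'
#' Container for one parcellated scan: a real-valued matrix with brain
#' regions as rows and time points as columns. Row and column names carry the
#' region and time-point labels and must be unique.
#'
#' @slot values numeric matrix, regions in rows, time points in columns.
#' @slot matrixId single character identifier for the scan.
#' @exportClass ScanMatrix
setClass("ScanMatrix",
         representation(values = "matrix", matrixId = "character"))

setValidity("ScanMatrix", function(object) {
    v <- object@values
    if (!is.numeric(v))
        return("'values' must be a numeric matrix")
    if (nrow(v) < 2L || ncol(v) < 2L)
        return("a scan needs at least 2 regions and 2 time points")
    if (!all(is.finite(v)))
        return("'values' must be finite (no NA/NaN/Inf)")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("'values' must carry region (row) and time (column) labels")
    if (anyDuplicated(rownames(v)))
        return("duplicate region labels")
    if (anyDuplicated(colnames(v)))
        return("duplicate time-point labels")
    if (length(object@matrixId) != 1L || is.na(object@matrixId))
        return("'matrixId' must be a single string")
    TRUE
})

#' Bicluster: a submatrix of a ScanMatrix
#'
#' A subset of rows I and columns J of one scan, together with the
#' materialised original values at I x J (never discretised or normalised
#' values) and the provenance of the discovery.
#'
#' @slot rows strictly increasing integer row indices (1-based).
#' @slot cols strictly increasing integer column indices (1-based).
#' @slot values numeric matrix: the original scan values at rows x cols.
#' @slot matrixId identifier of the scan the indices refer to.
#' @slot provenance list with elements \code{algorithm}, \code{run},
#'   \code{scan}.
#' @exportClass Bicluster
setClass("Bicluster",
         representation(rows = "integer", cols = "integer",
                        values = "matrix", matrixId = "character",
                        provenance = "list"))

setValidity("Bicluster", function(object) {
    if (length(object@rows) == 0L || length(object@cols) == 0L)
        return("row and column index sets must be non-empty")
    if (is.unsorted(object@rows, strictly = TRUE) ||
        is.unsorted(object@cols, strictly = TRUE))
        return("indices must be strictly increasing")
    if (any(object@rows < 1L) || any(object@cols < 1L))
        return("indices must be >= 1")
    if (!identical(dim(object@values),
                   c(length(object@rows), length(object@cols))))
        return("'values' shape must match the index sets")
    TRUE
})

#' BiclusterSet: an ordered collection of biclusters
#'
#' Holds the output of one algorithm run, or the pooled union over the scans
#' of a data collection.
#'
#' @slot biclusters list of \linkS4class{Bicluster}.
#' @slot collectionId single character identifier.
#' @exportClass BiclusterSet
setClass("BiclusterSet",
         representation(biclusters = "list", collectionId = "character"))

setValidity("BiclusterSet", function(object) {
    ok <- vapply(object@biclusters, is, logical(1), class2 = "Bicluster")
    if (!all(ok))
        return("all members must be Bicluster objects")
    if (length(object@collectionId) != 1L)
        return("'collectionId' must be a single string")
    TRUE
})

#' DiscretizedMatrix: a symbolic view of a scan
#'
#' Integer symbol codes (0..k-1) derived from a ScanMatrix by row-wise
#' binning, time-point transition coding, or binarisation. Under the
#' transition scheme columns represent gaps between consecutive time points,
#' so the symbol matrix has p-1 columns.
#'
#' @slot symbols integer matrix of codes in 0..alphabetSize-1.
#' @slot alphabetSize number of symbols k.
#' @slot scheme one of "rowwise_bins", "transitions", "binary".
#' @slot transitionOffset TRUE when columns are inter-time-point gaps.
#' @exportClass DiscretizedMatrix
setClass("DiscretizedMatrix",
         representation(symbols = "matrix", alphabetSize = "integer",
                        scheme = "character", transitionOffset = "logical"))

setValidity("DiscretizedMatrix", function(object) {
    if (!object@scheme %in% c("rowwise_bins", "transitions", "binary"))
        return("unknown discretisation scheme")
    s <- object@symbols
    if (any(s < 0L) || any(s >= object@alphabetSize))
        return("symbol codes out of range")
    if (object@scheme == "binary" && object@alphabetSize != 2L)
        return("binary scheme must have alphabet size 2")
    TRUE
})

#' PlantedBicluster: ground truth for a synthetic block
#'
#' Describes a coherent block embedded by the generator: constant
#' (b_ij = pi), shifting (b_ij = pi_i + beta_j) or scaling
#' (b_ij = pi_i * beta_j).
#'
#' @slot rows,cols 1-based index sets of the planted block.
#' @slot patternType "constant", "shifting" or "scaling".
#' @slot rowEffects per-row effects pi_i (empty for constant).
#' @slot colEffects per-column effects beta_j (empty for constant).
#' @slot baseLevel the constant level pi (constant patterns only).
#' @exportClass PlantedBicluster
setClass("PlantedBicluster",
         representation(rows = "integer", cols = "integer",
                        patternType = "character", rowEffects = "numeric",
                        colEffects = "numeric", baseLevel = "numeric"))

setValidity("PlantedBicluster", function(object) {
    if (!object@patternType %in% c("constant", "shifting", "scaling"))
        return("patternType must be constant, shifting or scaling")
    if (length(object@rows) == 0L || length(object@cols) == 0L)
        return("planted block must be non-empty")
    if (object@patternType != "constant") {
        if (length(object@rowEffects) != length(object@rows) ||
            length(object@colEffects) != length(object@cols))
            return("effect vectors must match the block dimensions")
    }
    TRUE
})
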