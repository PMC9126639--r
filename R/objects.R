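#' Construct a ScanMatrix
#'
#' @param values numeric matrix (regions x time points). If it has no
#'   dimnames, labels \code{R1..Rn} and \code{T1..Tp} are attached.
#' @param matrixId scan identifier.
#' @param regionLabels,timeLabels optional label vectors overriding the
#'   dimnames of \code{values}.
#' @return A \linkS4class{ScanMatrix}.
#' @examples
#' sm <- ScanMatrix(matrix(rnorm(12), 3, 4), matrixId = "demo")
#' dim(sm)
#' @export
ScanMatrix <- function(values, matrixId = "scan",
                       regionLabels = NULL, timeLabels = NULL) {
    values <- as.matrix(values)
    if (!is.null(regionLabels)) rownames(values) <- regionLabels
    if (!is.null(timeLabels)) colnames(values) <- timeLabels
    if (is.null(rownames(values)))
        rownames(values) <- paste0("R", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("T", seq_len(ncol(values)))
    new("ScanMatrix", values = values, matrixId = as.character(matrixId))
}

#' @describeIn ScanMatrix Numeric values of the scan.
#' @param x,object a ScanMatrix.
#' @export
scanValues <- function(x) x@values

#' Scan, bicluster and set accessors
#'
#' Small accessor family: \code{matrixId} returns the scan identifier a
#' ScanMatrix or Bicluster refers to; \code{regionLabels} and
#' \code{timeLabels} return the row/column labels of a scan;
#' \code{biclusterRows}, \code{biclusterCols} and \code{biclusterValues}
#' expose a Bicluster's index sets and materialised submatrix;
#' \code{provenance} its discovery metadata; \code{biclusters} the member
#' list of a BiclusterSet and \code{collectionId} its identifier.
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
matrixId <- function(x) x@matrixId

#' @rdname accessors
#' @export
regionLabels <- function(x) rownames(x@values)

#' @rdname accessors
#' @export
timeLabels <- function(x) colnames(x@values)

#' @rdname accessors
#' @export
biclusterRows <- function(x) x@rows

#' @rdname accessors
#' @export
biclusterCols <- function(x) x@cols

#' @rdname accessors
#' @export
biclusterValues <- function(x) x@values

#' @rdname accessors
#' @export
provenance <- function(x) x@provenance

#' @rdname accessors
#' @export
biclusters <- function(x) x@biclusters

#' @rdname accessors
#' @export
collectionId <- function(x) x@collectionId

#' @export
setMethod("dim", "ScanMatrix", function(x) dim(x@values))

#' @export
setMethod("dim", "Bicluster",
          function(x) c(length(x@rows), length(x@cols)))

#' @export
setMethod("length", "BiclusterSet", function(x) length(x@biclusters))

#' @export
setMethod("[[", "BiclusterSet", function(x, i) x@biclusters[[i]])

setMethod("show", "ScanMatrix", function(object) {
    cat("ScanMatrix '", object@matrixId, "': ",
        nrow(object@values), " regions x ",
        ncol(object@values), " time points\n", sep = "")
})

setMethod("show", "Bicluster", function(object) {
    pv <- object@provenance
    cat("Bicluster (", length(object@rows), " x ", length(object@cols),
        ") on '", object@matrixId, "'",
        if (!is.null(pv$algorithm)) paste0(" [", pv$algorithm, "]") else "",
        "\n", sep = "")
})

setMethod("show", "BiclusterSet", function(object) {
    cat("BiclusterSet '", object@collectionId, "' with ",
        length(object@biclusters), " biclusters\n", sep = "")
})

setMethod("show", "PlantedBicluster", function(object) {
    cat("PlantedBicluster [", object@patternType, "] ",
        length(object@rows), " x ", length(object@cols), "\n", sep = "")
})

#' Construct a BiclusterSet
#'
#' @param biclusters list of \linkS4class{Bicluster}.
#' @param collectionId identifier for the collection the members belong to.
#' @return A \linkS4class{BiclusterSet}.
#' @export
BiclusterSet <- function(biclusters = list(), collectionId = "collection") {
    new("BiclusterSet", biclusters = biclusters,
        collectionId = as.character(collectionId))
}
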