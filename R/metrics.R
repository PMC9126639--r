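.bvalues <- function(x) {
    if (is(x, "Bicluster")) x@values
    else if (is.matrix(x)) x
    else as.matrix(x)
}

#' Row, column and overall means of a bicluster
#'
#' @param x a \linkS4class{Bicluster} or numeric matrix.
#' @return List with \code{rowMeans} (b_iJ), \code{colMeans} (b_Ij) and
#'   \code{overallMean} (b_IJ).
#' @export
biclusterMoments <- function(x) {
    v <- .bvalues(x)
    list(rowMeans = rowMeans(v), colMeans = colMeans(v),
         overallMean = mean(v))
}

#' Bicluster variance (VAR)
#'
#' Mean squared deviation of the bicluster's cells from a reference mean:
#' \deqn{VAR(B) = \frac{1}{|I||J|}\sum_{i,j}(b_{ij} - b_{IJ})^2.}
#' Zero exactly for constant biclusters. By default \eqn{b_{IJ}} is the
#' bicluster's own mean (Hartigan's within-block variance); pass
#' \code{globalMean} to centre on the parent matrix's global mean instead.
#'
#' @param x a \linkS4class{Bicluster} or numeric matrix.
#' @param globalMean optional external centring value.
#' @return Non-negative scalar.
#' @examples
#' biclusterVariance(matrix(c(1, 3, 2, 4), 2, 2))  # 1.25
#' @export
biclusterVariance <- function(x, globalMean = NULL) {
    v <- .bvalues(x)
    m <- if (is.null(globalMean)) mean(v) else globalMean
    mean((v - m)^2)
}

#' Mean squared residue (MSR)
#'
#' Cheng & Church's additive coherence score:
#' \deqn{MSR(B) = \frac{1}{|I||J|}\sum_{i,j}
#'   (b_{ij} - b_{iJ} - b_{Ij} + b_{IJ})^2,}
#' where \eqn{b_{iJ}}, \eqn{b_{Ij}} are row/column means. Zero exactly for
#' shifting (additive) biclusters \eqn{b_{ij} = \pi_i + \beta_j}; blind to
#' scaling patterns.
#'
#' @inheritParams biclusterVariance
#' @return Non-negative scalar.
#' @export
biclusterMSR <- function(x) {
    v <- .bvalues(x)
    res <- v - outer(rowMeans(v), colMeans(v), `+`) + mean(v)
    mean(res^2)
}

#' Scaling mean squared residue (SMSR)
#'
#' Multiplicative counterpart of the MSR:
#' \deqn{SMSR(B) = \frac{1}{|I||J|}\sum_{i,j}
#'   \frac{(b_{iJ} b_{Ij} - b_{ij} b_{IJ})^2}{b_{iJ}^2 b_{Ij}^2}.}
#' Zero exactly for scaling biclusters \eqn{b_{ij} = \pi_i \beta_j} with
#' nonzero means. Undefined (returned as \code{NA}) when any row or column
#' mean is zero; such records are excluded pairwise from summaries rather
#' than epsilon-padded.
#'
#' @inheritParams biclusterVariance
#' @return Non-negative scalar, or \code{NA_real_} when undefined.
#' @export
biclusterSMSR <- function(x) {
    v <- .bvalues(x)
    rm <- rowMeans(v); cm <- colMeans(v)
    if (any(rm == 0) || any(cm == 0))
        return(NA_real_)
    denom <- outer(rm^2, cm^2)
    num <- (outer(rm, cm) - v * mean(v))^2
    mean(num / denom)
}

#' Row-standardise a bicluster
#'
#' Z-scores each row over the bicluster's columns,
#' \eqn{\hat b_{ij} = (b_{ij} - \mu_{g_i}) / \sigma_{g_i}}, using the
#' population standard deviation (divide by the column count) as the
#' descriptive normaliser. In the fMRI setting this puts every brain region
#' on a common amplitude. Constant rows (\eqn{\sigma_{g_i} = 0}) are mapped
#' to all-zero rows and flagged, so a constant bicluster standardises
#' cleanly instead of dividing by zero.
#'
#' @inheritParams biclusterVariance
#' @return List with \code{values} (standardised matrix),
#'   \code{rowMeansUsed}, \code{rowSdsUsed} and \code{degenerateRows}
#'   (indices of zero-sd rows).
#' @export
standardizeRows <- function(x) {
    v <- .bvalues(x)
    mu <- rowMeans(v)
    sdp <- sqrt(rowMeans((v - mu)^2))
    degenerate <- which(sdp == 0)
    sdsafe <- ifelse(sdp == 0, 1, sdp)
    z <- (v - mu) / sdsafe
    z[degenerate, ] <- 0
    list(values = z, rowMeansUsed = mu, rowSdsUsed = sdp,
         degenerateRows = degenerate)
}

#' Virtual pattern of a standardised bicluster
#'
#' The column-wise mean of the standardised rows,
#' \eqn{\hat\rho_j = \frac{1}{|I|}\sum_i \hat b_{ij}}: the average region
#' behaviour over the bicluster's time points.
#'
#' @param s output of \code{\link{standardizeRows}}, or a
#'   \linkS4class{Bicluster}/matrix (standardised first).
#' @return Numeric vector of length |J|.
#' @export
virtualPattern <- function(s) {
    if (!is.list(s) || is.null(s$values)) s <- standardizeRows(s)
    colMeans(s$values)
}

#' Virtual error (VE)
#'
#' Mean absolute deviation of the standardised rows from the virtual
#' pattern:
#' \deqn{VE(B) = \frac{1}{|I||J|}\sum_{i,j}
#'   |\hat b_{ij} - \hat\rho_j|.}
#' Because row standardisation removes each row's offset and (positive)
#' scale, VE is zero for every bicluster whose rows are positive affine
#' transforms of one another — both shifting and positive-scaling patterns —
#' and grows with the induced noise. Degenerate (constant) rows contribute
#' their zeros-vs-pattern differences to the average.
#'
#' @inheritParams biclusterVariance
#' @return Non-negative scalar.
#' @examples
#' virtualError(matrix(c(1, 2, 2, 1), 2, 2))  # 1
#' @export
virtualError <- function(x) {
    s <- standardizeRows(x)
    rho <- colMeans(s$values)
    mean(abs(sweep(s$values, 2L, rho)))
}

#' Compute all internal quality indices for a set of biclusters
#'
#' One row per bicluster, in input order, with the four internal quality
#' indices (VAR, MSR, SMSR, VE) and the size descriptors used by the
#' evaluation pipeline. Undefined SMSR values propagate as \code{NA}.
#'
#' @param set a \linkS4class{BiclusterSet}.
#' @return A \code{data.frame} with columns \code{scan}, \code{algorithm},
#'   \code{run}, \code{n_rows}, \code{n_cols}, \code{area}, \code{var},
#'   \code{msr}, \code{smsr}, \code{ve}.
#' @export
computeMetrics <- function(set) {
    stopifnot(is(set, "BiclusterSet"))
    bs <- set@biclusters
    if (length(bs) == 0L)
        return(data.frame(scan = character(), algorithm = character(),
                          run = integer(), n_rows = integer(),
                          n_cols = integer(), area = integer(),
                          var = numeric(), msr = numeric(),
                          smsr = numeric(), ve = numeric(),
                          stringsAsFactors = FALSE))
    nr <- vapply(bs, function(b) length(b@rows), integer(1))
    nc <- vapply(bs, function(b) length(b@cols), integer(1))
    data.frame(
        scan = vapply(bs, function(b)
            as.character(b@provenance$scan %||% b@matrixId), character(1)),
        algorithm = vapply(bs, function(b)
            as.character(b@provenance$algorithm %||% NA), character(1)),
        run = vapply(bs, function(b)
            as.integer(b@provenance$run %||% NA), integer(1)),
        n_rows = nr, n_cols = nc, area = nr * nc,
        var = vapply(bs, biclusterVariance, numeric(1)),
        msr = vapply(bs, biclusterMSR, numeric(1)),
        smsr = vapply(bs, biclusterSMSR, numeric(1)),
        ve = vapply(bs, virtualError, numeric(1)),
        stringsAsFactors = FALSE)
}
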