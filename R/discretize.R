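.rowPopSd <- function(v) sqrt(rowMeans((v - rowMeans(v))^2))

#' Row-wise equal-width discretisation
#'
#' The "traditional" per-row discretisation: each region's values are binned
#' into \code{k} equal-width bins spanning [row min, row max], with the top
#' bin right-closed. Constant rows map to code 0.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param k alphabet size (default 5 symbols).
#' @return A \linkS4class{DiscretizedMatrix} with scheme
#'   \code{"rowwise_bins"}.
#' @export
discretizeRowwise <- function(scan, k = 5L) {
    if (k < 2L) stop("k must be at least 2")
    v <- scanValues(scan)
    lo <- apply(v, 1L, min); hi <- apply(v, 1L, max)
    width <- hi - lo
    codes <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
    ok <- width > 0
    if (any(ok)) {
        z <- (v[ok, , drop = FALSE] - lo[ok]) / width[ok]
        codes[ok, ] <- pmin(as.integer(floor(z * k)), k - 1L)
    }
    new("DiscretizedMatrix", symbols = codes, alphabetSize = as.integer(k),
        scheme = "rowwise_bins", transitionOffset = FALSE)
}

#' Transition (variation between time points) discretisation
#'
#' Codes the gap between consecutive time points,
#' \eqn{\Delta_{ij} = b_{i,j+1} - b_{ij}}, so the symbol matrix has p-1
#' columns and \code{transitionOffset} is TRUE. With 2 symbols the codes are
#' Down (0) / Up (1), splitting at \eqn{\Delta \ge 0}. With 3 symbols a
#' NoChange band of half-width \code{t} times the row's population sd
#' separates Down (0), NoChange (1) and Up (2).
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param nSymbols 2 or 3.
#' @param t NoChange half-width, in units of row standard deviations
#'   (3-symbol scheme only; default 0.2).
#' @return A \linkS4class{DiscretizedMatrix} with scheme
#'   \code{"transitions"}.
#' @export
discretizeTransitions <- function(scan, nSymbols = 3L, t = 0.2) {
    stopifnot(nSymbols %in% c(2L, 3L))
    v <- scanValues(scan)
    if (ncol(v) < 2L) stop("need at least two time points")
    d <- v[, -1L, drop = FALSE] - v[, -ncol(v), drop = FALSE]
    if (nSymbols == 2L) {
        codes <- matrix(as.integer(d >= 0), nrow(d), ncol(d))
    } else {
        band <- t * .rowPopSd(v)
        codes <- matrix(1L, nrow(d), ncol(d))
        codes[d > band] <- 2L
        codes[d < -band] <- 0L
    }
    rownames(codes) <- rownames(v)
    new("DiscretizedMatrix", symbols = codes,
        alphabetSize = as.integer(nSymbols),
        scheme = "transitions", transitionOffset = TRUE)
}

#' Binarise a scan row-wise
#'
#' Produces the binary view a Bimax-style search requires. Two rules, both
#' applied per row with a strict inequality: \code{"above_row_median"}
#' (1 when the value exceeds the row median) and
#' \code{"above_row_mean_plus"} (1 when it exceeds the row mean plus
#' \code{c} row standard deviations — a sparser, activation-like coding).
#' Constant rows map to all zeros.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param rule binarisation rule.
#' @param c threshold offset in row sds (mean-plus rule only).
#' @return A \linkS4class{DiscretizedMatrix} with scheme \code{"binary"}.
#' @export
binarizeMatrix <- function(scan,
                           rule = c("above_row_median",
                                    "above_row_mean_plus"),
                           c = 1) {
    rule <- match.arg(rule)
    v <- scanValues(scan)
    thr <- if (rule == "above_row_median") apply(v, 1L, stats::median)
           else rowMeans(v) + c * .rowPopSd(v)
    codes <- matrix(as.integer(v > thr), nrow(v), ncol(v),
                    dimnames = dimnames(v))
    new("DiscretizedMatrix", symbols = codes, alphabetSize = 2L,
        scheme = "binary", transitionOffset = FALSE)
}

#' @rdname accessors
#' @export
symbolMatrix <- function(x) x@symbols
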