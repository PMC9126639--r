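.checkDisc <- function(scan, disc) {
    v <- scanValues(scan)
    expCols <- if (disc@transitionOffset) ncol(v) - 1L else ncol(v)
    if (nrow(disc@symbols) != nrow(v) || ncol(disc@symbols) != expCols)
        stop("discretised matrix shape does not match the scan")
}

.asSet <- function(scan, pairs, algorithm, run = NA_integer_) {
    bs <- lapply(pairs, function(pr)
        materializeBicluster(scan, pr$rows, pr$cols,
                             provenance = list(algorithm = algorithm,
                                               run = run,
                                               scan = matrixId(scan))))
    filterMinSize(dedupe(BiclusterSet(bs, collectionId = matrixId(scan))))
}

#' CCC biclustering: maximal contiguous-column coherent biclusters
#'
#' Exhaustively discovers every maximal bicluster whose columns form a
#' contiguous time interval and whose rows carry an identical symbol string
#' over that interval in the discretised view. Row-maximal (the row set is
#' all rows sharing the string) and column-maximal (the interval cannot be
#' extended while keeping the same row set). Implemented by interval
#' enumeration with incremental row-string hashing, O(p^2 n) strings;
#' equivalent output to suffix-tree formulations at the matrix sizes this
#' package targets.
#'
#' When the discretisation codes transitions between time points, the symbol
#' interval [j1, j2] maps back to time points [j1, j2+1]. Results are
#' materialised on the original scan values and filtered to at least 2 x 2.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param disc a \linkS4class{DiscretizedMatrix} derived from \code{scan};
#'   defaults to the per-row 5-symbol discretisation.
#' @return A \linkS4class{BiclusterSet}.
#' @export
cccBiclustering <- function(scan, disc = discretizeRowwise(scan, 5L)) {
    .checkDisc(scan, disc)
    sym <- disc@symbols
    n <- nrow(sym); m <- ncol(sym)
    off <- disc@transitionOffset
    found <- vector("list", 256L); nf <- 0L
    for (j1 in seq_len(m)) {
        id <- rep(1L, n)                    # one group: the empty string
        for (j2 in j1:m) {
            # refine row groups by the symbol at j2 (incremental hashing)
            code <- id * disc@alphabetSize + sym[, j2]
            id <- match(code, unique(code))
            cnt <- tabulate(id)
            if (max(cnt) < 2L) break        # all rows diverged; no
                                            # longer interval can regroup
            if (!off && j2 == j1) next      # single time column
            for (gid in which(cnt >= 2L)) {
                I <- which(id == gid)
                if (j1 > 1L && length(unique(sym[I, j1 - 1L])) == 1L)
                    next                    # extensible left
                if (j2 < m && length(unique(sym[I, j2 + 1L])) == 1L)
                    next                    # extensible right
                cols <- if (off) j1:(j2 + 1L) else j1:j2
                nf <- nf + 1L
                if (nf > length(found))
                    length(found) <- 2L * length(found)
                found[[nf]] <- list(rows = I, cols = cols)
            }
        }
    }
    .asSet(scan, found[seq_len(nf)], "ccc")
}

#' Bimax-style enumeration of maximal all-ones submatrices
#'
#' Enumerates the inclusion-maximal all-ones submatrices of a binary
#' discretised matrix (the formal concepts with at least 2 rows and 2
#' columns) by a close-by-one depth-first search over rows with canonicity
#' pruning, then keeps the \code{maxBiclusters} largest by area (largest
#' first, so raising the cap only ever adds biclusters). Results are
#' materialised on the original values and 2 x 2 filtered.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param disc binary \linkS4class{DiscretizedMatrix} (see
#'   \code{\link{binarizeMatrix}}).
#' @param maxBiclusters truncation cap (default 10000).
#' @param enumerationBudget safety bound on the number of concepts explored.
#' @return A \linkS4class{BiclusterSet}.
#' @export
bimaxBiclustering <- function(scan, disc = binarizeMatrix(scan),
                              maxBiclusters = 10000L,
                              enumerationBudget = 200000L) {
    if (disc@scheme != "binary")
        stop("bimaxBiclustering requires a binary discretisation")
    .checkDisc(scan, disc)
    B <- disc@symbols == 1L
    n <- nrow(B); p <- ncol(B)
    rowCols <- lapply(seq_len(n), function(i) which(B[i, ]))
    env <- new.env()
    env$out <- vector("list", 256L); env$k <- 0L; env$visited <- 0L
    colsOf <- function(R) Reduce(intersect, rowCols[R])
    rowsOf <- function(C) which(rowSums(B[, C, drop = FALSE]) == length(C))
    step <- function(R, C, minRow) {
        if (env$visited > enumerationBudget) return(invisible())
        if (length(R) >= 2L && length(C) >= 2L) {
            env$k <- env$k + 1L
            if (env$k > length(env$out)) length(env$out) <- 2L * length(env$out)
            env$out[[env$k]] <- list(rows = R, cols = C)
        }
        cand <- setdiff(seq_len(n), R)
        cand <- cand[cand >= minRow]
        for (i in cand) {
            newC <- intersect(C, rowCols[[i]])
            if (length(newC) < 2L) next
            newR <- rowsOf(newC)
            if (any(newR < i & !(newR %in% R))) next   # canonicity
            env$visited <- env$visited + 1L
            step(newR, newC, i + 1L)
        }
    }
    step(integer(0), seq_len(p), 1L)
    res <- env$out[seq_len(env$k)]
    if (length(res) > maxBiclusters) {
        areas <- vapply(res, function(x)
            length(x$rows) * length(x$cols), numeric(1))
        res <- res[order(-areas)][seq_len(maxBiclusters)]
    }
    .asSet(scan, res, "bimax")
}

.conservedCols <- function(sym, R) {
    sub <- sym[R, , drop = FALSE]
    which(colSums(sub == rep(sub[1L, ], each = length(R))) == length(R))
}

#' Greedy conserved-state (xMotifs-style) biclustering
#'
#' A simplified conserved-state search over a discretised matrix, faithful
#' to the xMotifs idea but not claiming byte-identical output to the
#' original tool. For each of \code{ns} randomly chosen seed columns and
#' \code{nd} random column subsets of size \code{sdSize}, the rows sharing
#' an identical symbol tuple on the subset (plus the seed column) are
#' collected — the largest agreeing group — and then extended to every
#' column on which those rows remain conserved. Per seed column the
#' largest-area candidate with row fraction at least \code{alpha} is kept.
#' Deterministic for a fixed \code{seed}; pool runs with
#' \code{\link{runRepeated}}.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param disc a \linkS4class{DiscretizedMatrix}; defaults to the 5-symbol
#'   row-wise discretisation.
#' @param ns number of seed columns.
#' @param nd number of random column subsets per seed.
#' @param sdSize size of each random column subset.
#' @param alpha minimum fraction of rows a motif must cover.
#' @param seed RNG seed.
#' @param run run index recorded in provenance.
#' @return A \linkS4class{BiclusterSet}.
#' @export
xmotifsBiclustering <- function(scan, disc = discretizeRowwise(scan, 5L),
                                ns = 10L, nd = 50L, sdSize = 5L,
                                alpha = 0.05, seed = 1L,
                                run = NA_integer_) {
    .checkDisc(scan, disc)
    sym <- disc@symbols
    n <- nrow(sym); m <- ncol(sym)
    if (sdSize >= m) stop("sdSize must be smaller than the column count")
    off <- disc@transitionOffset
    .withSeed(seed, {
        cands <- list()
        for (s in seq_len(ns)) {
            c0 <- sample.int(m, 1L)
            best <- NULL; bestArea <- 0
            for (d in seq_len(nd)) {
                S <- unique(c(c0, sample.int(m, sdSize)))
                # radix key over the subset's symbols (k^|S| stays well
                # inside double precision at practical subset sizes)
                keys <- drop(sym[, S, drop = FALSE] %*%
                             as.numeric(disc@alphabetSize)^(seq_along(S) - 1))
                grp <- split(seq_len(n), keys)
                R <- grp[[which.max(lengths(grp))]]
                if (length(R) < 2L || length(R) / n < alpha) next
                if (length(R) * m <= bestArea) next   # cannot beat best
                J <- .conservedCols(sym, R)
                area <- length(R) * length(J)
                if (area > bestArea) {
                    best <- list(rows = R, cols = J)
                    bestArea <- area
                }
            }
            if (!is.null(best)) cands[[length(cands) + 1L]] <- best
        }
        if (off)                       # transition cols -> time cols
            cands <- lapply(cands, function(x)
                list(rows = x$rows,
                     cols = sort(unique(c(x$cols, x$cols + 1L)))))
        .asSet(scan, cands, "xmotifs", run = run)
    })
}

#' Pool repeated stochastic runs of an algorithm
#'
#' Greedy searches depend on their starting seed; they are therefore
#' executed \code{nRuns} times with seeds derived from the master seed, and
#' the per-run outputs pooled by union plus deduplication. The run index of
#' the first occurrence of each bicluster is kept in provenance.
#'
#' @param scan a \linkS4class{ScanMatrix}.
#' @param algorithm function \code{(scan, seed, run)} returning a
#'   \linkS4class{BiclusterSet}, e.g. a wrapper around
#'   \code{\link{xmotifsBiclustering}} or a k-means baseline.
#' @param nRuns number of repetitions (default 30).
#' @param seed master seed.
#' @return Deduplicated pooled \linkS4class{BiclusterSet}.
#' @export
runRepeated <- function(scan, algorithm, nRuns = 30L, seed = 1L) {
    sets <- lapply(seq_len(nRuns), function(i)
        algorithm(scan, seed = .deriveSeed(seed, i), run = i))
    dedupe(BiclusterSet(unlist(lapply(sets, biclusters),
                               recursive = FALSE) %||% list(),
                        collectionId = matrixId(scan)))
}
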