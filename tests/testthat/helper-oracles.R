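# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately use naive per-element loops or
# exhaustive enumeration so they stay independent of the package's
# vectorised implementations.

randomScan <- function(n, p, seed) {
    set.seed(seed)
    ScanMatrix(matrix(rnorm(n * p), n, p), matrixId = paste0("rs", seed))
}

bcKey <- function(rows, cols) {
    paste(paste(rows, collapse = ","), paste(cols, collapse = ","),
          sep = "|")
}

setKeys <- function(set) {
    ks <- vapply(biclusters(set), function(b)
        bcKey(b@rows, b@cols), character(1))
    sort(ks)
}

# ---- metric loop oracles (per-element translations of the definitions) ----

loopVariance <- function(v) {
    m <- mean(v); acc <- 0
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        acc <- acc + (v[i, j] - m)^2
    acc / (nrow(v) * ncol(v))
}

loopMSR <- function(v) {
    rm <- rowMeans(v); cm <- colMeans(v); m <- mean(v); acc <- 0
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        acc <- acc + (v[i, j] - rm[i] - cm[j] + m)^2
    acc / (nrow(v) * ncol(v))
}

loopSMSR <- function(v) {
    rm <- rowMeans(v); cm <- colMeans(v); m <- mean(v)
    if (any(rm == 0) || any(cm == 0)) return(NA_real_)
    acc <- 0
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        acc <- acc + (rm[i] * cm[j] - v[i, j] * m)^2 / (rm[i]^2 * cm[j]^2)
    acc / (nrow(v) * ncol(v))
}

loopVE <- function(v) {
    z <- v
    for (i in seq_len(nrow(v))) {
        mu <- mean(v[i, ])
        sd <- sqrt(mean((v[i, ] - mu)^2))
        z[i, ] <- if (sd == 0) 0 else (v[i, ] - mu) / sd
    }
    rho <- colMeans(z)
    acc <- 0
    for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v)))
        acc <- acc + abs(z[i, j] - rho[j])
    acc / (nrow(v) * ncol(v))
}

# ---- exhaustive algorithm oracles (tiny matrices only) ----

allRowSubsets <- function(n, minSize = 2L) {
    out <- list()
    for (x in seq_len(2^n - 1L)) {
        I <- which(bitwAnd(x, 2^(seq_len(n) - 1L)) > 0L)
        if (length(I) >= minSize) out[[length(out) + 1L]] <- I
    }
    out
}

# maximal coherent contiguous-interval biclusters by containment pruning
bruteCCC <- function(sym, off) {
    n <- nrow(sym); m <- ncol(sym)
    cand <- list()
    for (j1 in seq_len(m)) for (j2 in j1:m) {
        if (!off && j2 == j1) next
        for (I in allRowSubsets(n)) {
            sub <- sym[I, j1:j2, drop = FALSE]
            if (all(apply(sub, 2L, function(x) all(x == x[1L]))))
                cand[[length(cand) + 1L]] <-
                    list(rows = I, j1 = j1, j2 = j2)
        }
    }
    keep <- rep(TRUE, length(cand))
    for (a in seq_along(cand)) for (b in seq_along(cand)) {
        if (a == b || !keep[a]) next
        A <- cand[[a]]; B <- cand[[b]]
        nested <- all(A$rows %in% B$rows) && B$j1 <= A$j1 && B$j2 >= A$j2
        same <- identical(A$rows, B$rows) && A$j1 == B$j1 && A$j2 == B$j2
        if (nested && !same) keep[a] <- FALSE
    }
    ks <- lapply(cand[keep], function(x)
        bcKey(x$rows, if (off) x$j1:(x$j2 + 1L) else x$j1:x$j2))
    sort(unique(unlist(ks, use.names = FALSE)) %||% character(0))
}

# inclusion-maximal all-ones submatrices by row-subset enumeration
bruteBimax <- function(B) {
    n <- nrow(B)
    ks <- character(0)
    for (I in allRowSubsets(n)) {
        J <- which(colSums(B[I, , drop = FALSE]) == length(I))
        if (length(J) < 2L) next
        I2 <- which(rowSums(B[, J, drop = FALSE]) == length(J))
        if (identical(I, I2)) ks <- c(ks, bcKey(I, J))
    }
    sort(unique(ks))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
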