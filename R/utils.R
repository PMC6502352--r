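# Internal helpers shared across modules.

# Evaluate `code` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    force(code)
}

# Symmetric eigendecomposition with descending eigenvalues and the sign of
# each eigenvector fixed so its largest-magnitude component is positive.
symmetricEigen <- function(A, matrixKind, source = list()) {
    if (max(abs(A - t(A))) > 1e-8 * max(1, max(abs(A))))
        stop("matrix is not symmetric within tolerance")
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    V <- e$vectors
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    new("SpectralResult", values = e$values, vectors = V,
        matrixKind = matrixKind, source = source)
}

stopifnotScalar <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a finite numeric scalar", name))
    invisible(x)
}
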