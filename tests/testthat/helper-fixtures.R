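# Shared fixtures and small independent oracles used across test files.

# Canonical L = 3 worked example: effects (-1, 1, 0) with a zero-width
# selection window at T* = 0 keeps exactly the four sequences orthogonal to
# the effect vector.
workedExampleDelta <- function() mutationalEffects(c(-1, 1, 0))

workedExampleEnsemble <- function() {
    enumerateEnsemble(workedExampleDelta(),
                      selectionModel("rectangular", tStar = 0, halfWidth = 0))
}

# Brute-force weighted covariance straight from the definition (independent
# of the package's vectorized implementation).
bruteCovariance <- function(X, w) {
    w <- w / sum(w)
    L <- ncol(X)
    mu <- sapply(seq_len(L), function(l) sum(w * X[, l]))
    C <- matrix(0, L, L)
    for (a in seq_len(L)) for (b in seq_len(L))
        C[a, b] <- sum(w * (X[, a] - mu[a]) * (X[, b] - mu[b]))
    C
}

# Exact sphere marginal: E|nu_1| for nu uniform on the unit (L-1)-sphere.
sphereAbsMarginal <- function(L) {
    exp(lgamma(L / 2) - lgamma((L + 1) / 2)) / sqrt(pi)
}

randomPSD <- function(n, seed) {
    set.seed(seed)
    A <- matrix(rnorm(n * n), n, n)
    crossprod(A) / n
}
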