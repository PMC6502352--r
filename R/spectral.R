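asCovMatrix <- function(cov) {
    if (is(cov, "CovarianceResult")) cov@Cmat
    else if (is(cov, "MultistateCovariance")) cov@Cmat
    else as.matrix(cov)
}

#' Principal component analysis of a covariance matrix
#'
#' Full eigendecomposition of the symmetric covariance matrix, eigenvalues
#' in decreasing order. Under a narrow selection window the highly weighted
#' sequences are confined near a plane perpendicular to the
#' mutational-effect vector, so the LAST principal component (smallest
#' eigenvalue) carries the sector signal.
#'
#' @param cov a \linkS4class{CovarianceResult} or symmetric matrix.
#' @return a \linkS4class{SpectralResult} with \code{matrixKind}
#'   "covariance".
#' @export
pcaSpectrum <- function(cov) {
    symmetricEigen(asCovMatrix(cov), "covariance",
                   source = list(analysis = "pca"))
}

#' ICOD: Inverse Covariance Off-Diagonal spectrum
#'
#' Inverts the covariance matrix, zeroes the diagonal (which is dominated by
#' single-site conservation), and eigendecomposes the result. Under
#' selection on an additive trait the off-diagonal of the inverse covariance
#' is approximately \eqn{\kappa \Delta_l \Delta_{l'}}, so the FIRST
#' eigenvector (largest eigenvalue) is the sector estimate.
#'
#' @param cov a \linkS4class{CovarianceResult} or symmetric matrix.
#' @param ridge optional nonnegative ridge added to the diagonal of C before
#'   inversion (default 0; prefer a frequency pseudocount in
#'   \code{\link{covariance}}).
#' @return a \linkS4class{SpectralResult} with \code{matrixKind} "icod".
#' @export
icodSpectrum <- function(cov, ridge = 0) {
    C <- asCovMatrix(cov)
    if (ridge > 0) C <- C + diag(ridge, nrow(C))
    Cinv <- tryCatch(solve(C), error = function(e)
        stop("covariance matrix is singular; re-estimate it with a ",
             "pseudocount (e.g. covariance(ens, lambda = 0.01)) or pass ",
             "ridge > 0", call. = FALSE))
    diag(Cinv) <- 0
    symmetricEigen(Cinv, "icod", source = list(analysis = "icod",
                                               ridge = ridge))
}

#' @rdname SpectralResult-class
#' @export
setMethod("eigenValues", "SpectralResult", function(x) x@values)

#' @rdname SpectralResult-class
#' @export
setMethod("eigenVectors", "SpectralResult", function(x) x@vectors)

setMethod("show", "SpectralResult", function(object) {
    k <- length(object@values)
    cat(sprintf("SpectralResult (%s): %d modes, eigenvalues [%.4g .. %.4g]\n",
                object@matrixKind, k, object@values[k], object@values[1L]))
})

#' Recovery of a mutational-effect vector by an inferred mode
#'
#' \deqn{\mathrm{Recovery} = \frac{\sum_l |\nu_l \Delta_l|}
#'   {\|\nu\|\,\|\Delta\|},}
#' which is nonnegative, saturates at 1 (attained when \eqn{\nu \propto
#' \Delta}, including after arbitrary per-site sign flips), and is invariant
#' to rescaling of either vector.
#'
#' @param nu numeric vector (an eigenvector / inferred mode).
#' @param delta a \linkS4class{MutationalEffects} (binary), or a plain
#'   numeric vector of effects.
#' @return numeric in [0, 1].
#' @examples
#' recovery(c(1, 1, 0) / sqrt(2), mutationalEffects(c(-1, 1, 0)))  # 1
#' @export
recovery <- function(nu, delta) {
    d <- if (is(delta, "MutationalEffects")) {
        if (isBinary(delta)) deltaVector(delta)
        else as.vector(t(effectsMatrix(delta)))
    } else as.numeric(delta)
    nu <- as.numeric(nu)
    if (length(nu) != length(d))
        stop("mode and effect vector must have matching lengths")
    nn <- sqrt(sum(nu^2)); nd <- sqrt(sum(d^2))
    if (nn == 0 || nd == 0)
        stop("Recovery is undefined for a zero vector")
    sum(abs(nu * d)) / (nn * nd)
}

#' Random expectation of the Recovery statistic
#'
#' Monte-Carlo mean of \code{\link{recovery}} over unit vectors drawn
#' uniformly on the L-sphere, together with the large-L closed form
#' \eqn{\sqrt{2/(\pi L)}\, \sum_l |\Delta_l| / \|\Delta\|}.
#'
#' @param delta a \linkS4class{MutationalEffects} or numeric vector.
#' @param nDraws number of random unit vectors (default 10000).
#' @param seed RNG seed.
#' @return list with elements \code{estimate} (Monte Carlo),
#'   \code{closedForm} (large-L approximation) and \code{nDraws}.
#' @export
recoveryRandomExpectation <- function(delta, nDraws = 10000, seed = 1) {
    d <- if (is(delta, "MutationalEffects")) {
        if (isBinary(delta)) deltaVector(delta)
        else as.vector(t(effectsMatrix(delta)))
    } else as.numeric(delta)
    L <- length(d)
    if (L < 2L) stop("need at least two sites")
    absd <- abs(d) / sqrt(sum(d^2))
    mc <- withSeed(seed, {
        Z <- matrix(rnorm(nDraws * L), nDraws, L)
        Z <- abs(Z) / sqrt(rowSums(Z^2))
        mean(drop(Z %*% absd))
    })
    list(estimate = mc,
         closedForm = sqrt(2 / (pi * L)) * sum(absd),
         nDraws = nDraws)
}

#' Per-mode Recovery report for a spectral result
#'
#' @param spectral a \linkS4class{SpectralResult}.
#' @param delta a \linkS4class{MutationalEffects} or numeric vector.
#' @param nDraws,seed forwarded to
#'   \code{\link{recoveryRandomExpectation}}.
#' @return a \linkS4class{RecoveryReport}.
#' @export
recoveryReport <- function(spectral, delta, nDraws = 10000, seed = 1) {
    per <- apply(eigenVectors(spectral), 2L, recovery, delta = delta)
    re <- recoveryRandomExpectation(delta, nDraws = nDraws, seed = seed)
    new("RecoveryReport", perMode = per, randomExpectation = re$estimate,
        bestMode = which.max(per))
}

setMethod("show", "RecoveryReport", function(object) {
    cat(sprintf(
        "RecoveryReport: best mode %d (Recovery %.4f), random expectation %.4f\n",
        object@bestMode, object@perMode[object@bestMode],
        object@randomExpectation))
})

#' Site-specific conservation factor for SCA (binary alphabet)
#'
#' \eqn{\phi_l = |\ln[P_l (1 - \bar q) / ((1 - P_l)\bar q)]|} with
#' background mutant frequency \code{background} (0.5 for unbiased synthetic
#' data, where the factor vanishes for unconserved sites).
#'
#' @param p per-site mutant fractions in (0, 1).
#' @param background background mutant frequency.
#' @return numeric vector of nonnegative conservation weights.
#' @export
scaWeights <- function(p, background = 0.5) {
    if (any(p <= 0 | p >= 1))
        stop("mutant fractions at 0 or 1: re-estimate the covariance with ",
             "a pseudocount (lambda > 0)")
    abs(log(p * (1 - background) / ((1 - p) * background)))
}

#' Statistical Coupling Analysis matrix and spectrum
#'
#' Builds the conservation-reweighted absolute covariance matrix
#' \eqn{\tilde C^{(SCA)}_{ll'} = |\phi_l C_{ll'} \phi_{l'}|} and
#' eigendecomposes it. Sectors are read from the FIRST eigenvector; for
#' Recovery comparisons against a mutational-effect vector, use the square
#' root of the magnitudes of its components
#' (\code{scaSectorEstimate}).
#'
#' @param cov a \linkS4class{CovarianceResult} from a binary ensemble.
#' @param background background mutant frequency for the conservation
#'   factor.
#' @return a \linkS4class{SpectralResult} with \code{matrixKind} "sca".
#' @export
scaSpectrum <- function(cov, background = 0.5) {
    if (!is(cov, "CovarianceResult"))
        stop("scaSpectrum needs a binary CovarianceResult")
    phi <- scaWeights(cov@mutantFractions, background)
    Csca <- abs(outer(phi, phi) * cov@Cmat)
    symmetricEigen(Csca, "sca",
                   source = list(analysis = "sca", background = background))
}

#' @rdname scaSpectrum
#' @param spectral a \linkS4class{SpectralResult} of kind "sca".
#' @export
scaSectorEstimate <- function(spectral) {
    sqrt(abs(eigenVectors(spectral)[, 1L]))
}

#' Count outlier eigenvalues
#'
#' Declared outlier rule: eigenvalues exceeding
#' \code{median + 6 * mad} of the spectrum. Used to decide how many ICA
#' components to extract.
#'
#' @param values numeric eigenvalues.
#' @param nMad multiplier of the MAD (default 6).
#' @return integer count of upper outliers.
#' @export
countOutliers <- function(values, nMad = 6) {
    sum(values > median(values) + nMad * mad(values))
}

#' Disentangle multiple selected traits by ICA
#'
#' Applies fixed-point (FastICA-style, symmetric decorrelation, tanh
#' contrast) independent component analysis to the top eigenvectors of a
#' spectral result. When several traits are simultaneously under selection
#' the leading ICOD eigenvectors span the space of the mutational-effect
#' vectors but are rotated within it; ICA finds the rotation that maximizes
#' the non-Gaussianity (site-sparsity) of the components, aligning each with
#' one effect vector.
#'
#' @param spectral a \linkS4class{SpectralResult}.
#' @param nComponents number of leading eigenvectors to rotate; default the
#'   \code{\link{countOutliers}} count (at least 1).
#' @param seed RNG seed for the random orthogonal initialization.
#' @param maxit,tol iteration controls.
#' @return a list of normalized component vectors (each length L), sign-fixed
#'   like eigenvectors. \code{nComponents = 1} returns the top eigenvector
#'   unchanged.
#' @export
icaDisentangle <- function(spectral, nComponents = NULL, seed = 1,
                           maxit = 1000, tol = 1e-8) {
    V <- eigenVectors(spectral)
    if (is.null(nComponents))
        nComponents <- max(1L, countOutliers(eigenValues(spectral)))
    if (nComponents > ncol(V))
        stop("nComponents exceeds the number of available modes")
    if (nComponents == 1L) return(list(V[, 1L]))
    Vn <- V[, seq_len(nComponents), drop = FALSE]
    L <- nrow(Vn)
    Z <- t(Vn) * sqrt(L)            # rows orthonormal => already white
    n <- nComponents

    orth <- function(W) {           # symmetric decorrelation (W W^T)^-1/2 W
        e <- eigen(tcrossprod(W), symmetric = TRUE)
        if (any(e$values < 1e-12)) stop("degenerate ICA rotation")
        e$vectors %*% diag(1 / sqrt(e$values), n) %*% t(e$vectors) %*% W
    }
    W <- withSeed(seed, orth(matrix(rnorm(n * n), n, n)))
    for (it in seq_len(maxit)) {
        S <- W %*% Z
        G <- tanh(S)
        gp <- rowMeans(1 - G^2)
        Wn <- orth(G %*% t(Z) / L - diag(gp, n) %*% W)
        conv <- max(abs(abs(diag(Wn %*% t(W))) - 1))
        W <- Wn
        if (conv < tol) {
            comps <- W %*% t(Vn)    # components in site space
            out <- lapply(seq_len(n), function(k) {
                v <- comps[k, ]
                v <- v / sqrt(sum(v^2))
                i <- which.max(abs(v))
                if (v[i] < 0) -v else v
            })
            return(out)
        }
    }
    stop(sprintf("ICA did not converge within %d iterations", maxit))
}
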