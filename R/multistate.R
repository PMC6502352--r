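#' Standard 21-letter protein alphabet (20 amino acids plus the gap)
#'
#' Alphabetical amino-acid order; the gap "-" is the 21st state.
#' @export
aminoAcidStates <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                     "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")

#' Encode a multiple sequence alignment for q-state covariance analysis
#'
#' Maps an aligned set of sequences to integer state indices, removes
#' columns whose gap frequency exceeds \code{gapThreshold} (default 0.15),
#' and fixes a per-site gauge state: the consensus (most frequent non-gap
#' state, ties broken by alphabetical order) or a given reference sequence.
#' Unrecognized characters are treated as gaps. Optional 80%-identity
#' sequence reweighting assigns each sequence weight 1/(number of neighbors
#' at >= 80% identity); it is off by default.
#'
#' @param msa a \code{Biostrings::AAStringSet}, character vector of aligned
#'   sequences, or character matrix.
#' @param gauge "consensus" or "reference".
#' @param reference reference sequence (character string or state-index
#'   vector) when \code{gauge = "reference"}.
#' @param gapThreshold maximum tolerated gap fraction per column.
#' @param states state alphabet; default \code{\link{aminoAcidStates}}.
#' @param reweightIdentity if non-NULL, identity level (e.g. 0.8) above
#'   which sequences share weight.
#' @return an \linkS4class{EncodedAlignment}.
#' @export
encodeAlignment <- function(msa, gauge = c("consensus", "reference"),
                            reference = NULL, gapThreshold = 0.15,
                            states = aminoAcidStates,
                            reweightIdentity = NULL) {
    gauge <- match.arg(gauge)
    if (inherits(msa, "XStringSet")) msa <- as.character(msa)
    chars <- if (is.matrix(msa)) msa
             else {
                 if (length(msa) == 0L) stop("empty alignment")
                 if (length(unique(nchar(msa))) != 1L)
                     stop("aligned sequences must have equal length")
                 do.call(rbind, strsplit(toupper(msa), ""))
             }
    if (nrow(chars) == 0L || ncol(chars) == 0L) stop("empty alignment")
    X <- matrix(match(chars, states), nrow(chars), ncol(chars))
    gapState <- match("-", states)
    if (!is.na(gapState)) X[is.na(X)] <- gapState
    if (any(is.na(X))) stop("unrecognized states and no gap state defined")

    gapFreq <- if (is.na(gapState)) rep(0, ncol(X))
               else colMeans(X == gapState)
    keep <- which(gapFreq <= gapThreshold)
    if (length(keep) == 0L) stop("all columns exceed the gap threshold")
    Xk <- X[, keep, drop = FALSE]

    w <- rep(1, nrow(Xk))
    if (!is.null(reweightIdentity)) {
        for (i in seq_len(nrow(Xk))) {
            ident <- rowMeans(Xk == matrix(Xk[i, ], nrow(Xk), ncol(Xk),
                                           byrow = TRUE))
            w[i] <- 1 / sum(ident >= reweightIdentity)
        }
    }
    w <- w / sum(w)

    g <- if (gauge == "consensus") {
        vapply(seq_len(ncol(Xk)), function(l) {
            tab <- tabulate(Xk[, l], nbins = length(states))
            if (!is.na(gapState)) tab[gapState] <- 0
            if (all(tab == 0L)) gapState else which.max(tab)
        }, 1L)
    } else {
        if (is.null(reference)) stop("gauge = 'reference' needs 'reference'")
        ref <- if (is.character(reference) && length(reference) == 1L)
            match(strsplit(toupper(reference), "")[[1L]], states)
        else as.integer(reference)
        if (anyNA(ref)) stop("reference contains unrecognized states")
        if (length(ref) == ncol(X)) ref <- ref[keep]
        if (length(ref) != ncol(Xk))
            stop("reference length does not match the alignment")
        ref
    }
    if (all(vapply(seq_len(ncol(Xk)),
                   function(l) length(unique(Xk[, l])) == 1L, TRUE)))
        warning("alignment is fully conserved at every retained site")
    new("EncodedAlignment", sequences = Xk, states = states,
        retainedSites = as.integer(keep), gauge = as.integer(g),
        gapFrequency = gapFreq, weights = w)
}

# Weighted L x q state-frequency matrix.
stateFrequencies <- function(X, w, q) {
    f <- matrix(0, ncol(X), q)
    for (a in seq_len(q)) f[, a] <- drop(crossprod(w, X == a))
    f
}

#' q-state covariance matrix with pseudocount, in a declared gauge
#'
#' Computes weighted single-site and pairwise state frequencies, mixes them
#' with the uniform distribution at pseudocount ratio \code{lambda}
#' (\eqn{\tilde f_1 = (1-\Lambda) f_1 + \Lambda/q}; off-site pairs
#' \eqn{\tilde f_2 = (1-\Lambda) f_2 + \Lambda/q^2}), and forms the
#' covariance \eqn{C = \tilde f_2 - \tilde f_1 \tilde f_1} restricted to the
#' q-1 non-gauge states per site. With q = 2 this reduces exactly to the
#' binary \code{\link{covariance}}.
#'
#' @param x an \linkS4class{EncodedAlignment} or a q-state
#'   \linkS4class{WeightedEnsemble}.
#' @param lambda pseudocount ratio in [0, 1).
#' @param gauge optional per-site gauge-state indices (defaults: the
#'   alignment's stored gauge, or state 1 for an ensemble).
#' @return a \linkS4class{MultistateCovariance}.
#' @export
multistateCovariance <- function(x, lambda = 0, gauge = NULL) {
    if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
    if (is(x, "EncodedAlignment")) {
        X <- x@sequences; w <- x@weights; states <- x@states
        if (is.null(gauge)) gauge <- x@gauge
        retained <- x@retainedSites
    } else if (is(x, "WeightedEnsemble")) {
        X <- x@sequences; w <- x@weights
        states <- x@states
        if (isBinaryEnsemble(x)) {      # 0/1 -> state indices 1/2
            X <- X + 1L
        }
        if (is.null(gauge)) gauge <- rep(1L, ncol(X))
        retained <- seq_len(ncol(X))
    } else stop("x must be an EncodedAlignment or WeightedEnsemble")
    L <- ncol(X); q <- length(states)
    gauge <- as.integer(rep_len(gauge, L))

    f1 <- stateFrequencies(X, w, q)
    f1t <- (1 - lambda) * f1 + lambda / q

    # one-hot over non-gauge states, sparse
    keepState <- lapply(seq_len(L), function(l) setdiff(seq_len(q), gauge[l]))
    siteOf <- rep(seq_len(L), each = q - 1L)
    stateOf <- unlist(keepState)
    K <- length(siteOf)
    M <- nrow(X)
    colIndex <- matrix(0L, L, q)
    colIndex[cbind(siteOf, stateOf)] <- seq_len(K)
    j <- colIndex[cbind(rep(seq_len(L), each = M), as.vector(X))]
    i <- rep(seq_len(M), times = L)
    nz <- j > 0L
    A <- Matrix::sparseMatrix(i = i[nz], j = j[nz], x = 1, dims = c(M, K))
    f2 <- as.matrix(Matrix::crossprod(A, A * w))
    f2t <- (1 - lambda) * f2 + lambda / q^2
    # within-site blocks: same-site pair frequencies are diag(f1)
    for (l in seq_len(L)) {
        idx <- colIndex[l, keepState[[l]]]
        f2t[idx, idx] <- diag(f1t[l, keepState[[l]]], length(idx))
    }
    f1flat <- f1t[cbind(siteOf, stateOf)]
    C <- f2t - tcrossprod(f1flat)
    C <- (C + t(C)) / 2
    siteMap <- data.frame(site = retained[siteOf],
                          state = states[stateOf], row = seq_len(K))
    new("MultistateCovariance", Cmat = C, siteMap = siteMap,
        frequencies = f1t, pseudocount = lambda,
        retainedSites = as.integer(retained), gauge = gauge,
        states = states)
}

#' ICOD for q-state covariance matrices with Frobenius compression
#'
#' Inverts the q-state covariance matrix, zeroes its (q-1) x (q-1)
#' within-site diagonal blocks, and compresses each off-diagonal site-pair
#' block to its Frobenius norm, yielding a site-level matrix whose top
#' eigenvector scores overall (not residue-specific) mutational effects.
#'
#' @param mcov a \linkS4class{MultistateCovariance}.
#' @return a \linkS4class{MultistateICODResult}; \code{siteScores} are the
#'   magnitudes of the top compressed-matrix eigenvector components and
#'   \code{ranking} lists retained sites by decreasing score.
#' @export
icodMultistate <- function(mcov) {
    C <- mcov@Cmat
    Cinv <- tryCatch(solve(C), error = function(e)
        stop("q-state covariance matrix is singular; re-estimate with a ",
             "pseudocount (multistateCovariance(x, lambda = 0.01))",
             call. = FALSE))
    sites <- mcov@siteMap$site
    usite <- unique(sites)
    Lp <- length(usite)
    blockIdx <- lapply(usite, function(s) which(sites == s))
    for (b in blockIdx) Cinv[b, b] <- 0
    Cinv <- (Cinv + t(Cinv)) / 2
    icodSpec <- symmetricEigen(Cinv, "icod",
                               source = list(analysis = "icod-multistate"))
    Fm <- matrix(0, Lp, Lp)
    for (a in seq_len(Lp - 1L)) for (b in seq((a + 1L), Lp)) {
        blk <- Cinv[blockIdx[[a]], blockIdx[[b]], drop = FALSE]
        Fm[a, b] <- Fm[b, a] <- sqrt(sum(blk^2))
    }
    comp <- new("CompressedICOD", fmat = Fm, compression = "frobenius")
    spec <- symmetricEigen(Fm, "icod",
                           source = list(analysis = "icod-compressed"))
    scores <- abs(eigenVectors(spec)[, 1L])
    new("MultistateICODResult", compressed = comp, spectrum = spec,
        icodMatrix = Cinv, icodSpectrum = icodSpec, siteScores = scores,
        ranking = as.integer(usite[order(scores, decreasing = TRUE)]))
}

setMethod("show", "MultistateICODResult", function(object) {
    v <- eigenValues(object@spectrum)
    cat(sprintf(
        "MultistateICODResult: %d sites, top eigenvalue %.4g (next %.4g)\n",
        length(object@siteScores), v[1L], v[2L]))
    cat("  top sites:", paste(head(object@ranking, 10L), collapse = " "),
        "\n")
})

#' Per-site conservation score (Kullback-Leibler divergence)
#'
#' \eqn{D_l = \sum_\alpha P_l(\alpha)\ln[P_l(\alpha)/b(\alpha)]} of the
#' observed state frequencies from a background distribution (default
#' uniform over the alphabet). A fully conserved site under a uniform
#' 21-state background scores \eqn{\ln 21 \approx 3.045}.
#'
#' @param frequencies L x q row-stochastic frequency matrix (e.g. the
#'   \code{frequencies} slot of a \linkS4class{MultistateCovariance}).
#' @param background length-q background distribution; default uniform.
#' @return numeric per-site scores (nonnegative).
#' @export
conservationScore <- function(frequencies, background = NULL) {
    q <- ncol(frequencies)
    if (is.null(background)) background <- rep(1 / q, q)
    background <- background / sum(background)
    apply(frequencies, 1L, function(p) {
        nz <- p > 0
        sum(p[nz] * log(p[nz] / background[nz]))
    })
}

#' SCA for q-state covariance matrices
#'
#' Generalizes the conservation-reweighted absolute covariance to q states:
#' each (site, state) row/column of the covariance matrix is weighted by
#' \eqn{\phi_l(\alpha) = |\ln[f_l(\alpha)(1-b(\alpha)) /
#' ((1-f_l(\alpha)) b(\alpha))]|}, the absolute value is taken, each
#' site-pair block is compressed by its Frobenius norm, and the resulting
#' site matrix is eigendecomposed.
#'
#' @param mcov a \linkS4class{MultistateCovariance}.
#' @param background length-q background distribution (default uniform).
#' @return a \linkS4class{SpectralResult} with \code{matrixKind} "sca" over
#'   retained sites.
#' @export
scaSpectrumMultistate <- function(mcov, background = NULL) {
    q <- length(mcov@states)
    if (is.null(background)) background <- rep(1 / q, q)
    f <- mcov@frequencies
    if (any(f <= 0 | f >= 1))
        stop("state frequencies at 0 or 1: use a pseudocount (lambda > 0)")
    sm <- mcov@siteMap
    localSite <- match(sm$site, unique(sm$site))
    st <- match(sm$state, mcov@states)
    phi <- abs(log(f[cbind(localSite, st)] * (1 - background[st]) /
                   ((1 - f[cbind(localSite, st)]) * background[st])))
    W <- abs(outer(phi, phi) * mcov@Cmat)
    usite <- unique(sm$site)
    Lp <- length(usite)
    Fm <- matrix(0, Lp, Lp)
    for (a in seq_len(Lp)) for (b in seq(a, Lp)) {
        blk <- W[localSite == a, localSite == b, drop = FALSE]
        Fm[a, b] <- Fm[b, a] <- sqrt(sum(blk^2))
    }
    symmetricEigen(Fm, "sca", source = list(analysis = "sca-multistate"))
}
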