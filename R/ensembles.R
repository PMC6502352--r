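#' Construct a weighted sequence ensemble
#'
#' @param sequences integer M x L matrix (0/1 binary or 1..q state indices).
#' @param weights nonnegative weights; normalized to sum to 1.
#' @param states state labels (default binary \code{c("0","1")}).
#' @param provenance list of sampler metadata.
#' @return a \linkS4class{WeightedEnsemble}.
#' @export
weightedEnsemble <- function(sequences, weights = NULL,
                             states = c("0", "1"), provenance = list()) {
    sequences <- as.matrix(sequences)
    storage.mode(sequences) <- "integer"
    if (is.null(weights)) weights <- rep(1, nrow(sequences))
    s <- sum(weights)
    if (s <= 0) stop("total weight is zero: no sequence survives selection")
    weights <- weights / s
    provenance$ess <- 1 / sum(weights^2)
    new("WeightedEnsemble", sequences = sequences, weights = weights,
        states = states, provenance = provenance)
}

#' @rdname WeightedEnsemble-class
#' @export
setMethod("sequenceMatrix", "WeightedEnsemble", function(x) x@sequences)

#' @rdname WeightedEnsemble-class
#' @export
setMethod("ensembleWeights", "WeightedEnsemble", function(x) x@weights)

#' @rdname WeightedEnsemble-class
#' @export
setMethod("effectiveSampleSize", "WeightedEnsemble",
          function(x) 1 / sum(x@weights^2))

isBinaryEnsemble <- function(x) identical(x@states, c("0", "1"))

setMethod("show", "WeightedEnsemble", function(object) {
    cat(sprintf("WeightedEnsemble: %d sequences of length %d (%s), ESS %.1f\n",
                nrow(object@sequences), ncol(object@sequences),
                if (isBinaryEnsemble(object)) "binary"
                else sprintf("%d states", length(object@states)),
                effectiveSampleSize(object)))
    if (!is.null(object@provenance$sampler))
        cat(sprintf("  sampler: %s\n", object@provenance$sampler))
})

#' Exhaustively enumerate the Boltzmann ensemble of binary sequences
#'
#' Enumerates all \eqn{2^L} binary sequences and assigns each the exact
#' normalized Boltzmann weight \eqn{P \propto \exp(w)}. Intended as the
#' exact reference for small systems; refuses \eqn{L > 20}.
#'
#' @param delta binary \linkS4class{MutationalEffects}.
#' @param selection a \linkS4class{SelectionModel} (or
#'   \linkS4class{MultiTraitSelection}).
#' @return a \linkS4class{WeightedEnsemble} with M = 2^L rows.
#' @export
enumerateEnsemble <- function(delta, selection) {
    d0 <- if (is(selection, "MultiTraitSelection")) selection@deltas[[1L]]
          else delta
    if (!isBinary(d0)) stop("enumeration supports the binary alphabet only")
    L <- nSites(d0)
    if (L > 20L)
        stop("L > 20: exhaustive enumeration is infeasible, use ",
             "sampleEnsemble() instead")
    X <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
    colnames(X) <- NULL
    w <- if (is(selection, "MultiTraitSelection"))
        exp(multiTraitFitnessFromMatrix(X, selection))
    else exp(fitnessFromTrait(traitValues(X, delta), selection))
    weightedEnsemble(X, w, provenance = list(sampler = "enumerate"))
}

#' Sample a selected sequence ensemble
#'
#' \code{method = "importance"}: sequences are proposed uniformly at random
#' over states (0 and 1 equally likely at each site in the binary model) and
#' carry normalized weights proportional to \code{exp(fitness)}.
#' \code{method = "mcmc"}: Metropolis single-site moves targeting the
#' Boltzmann distribution; samples are recorded every L accepted-or-rejected
#' flips after a burn-in of 10 L sweeps and carry uniform weights.
#'
#' @param delta a \linkS4class{MutationalEffects} (binary or q-state).
#' @param selection a \linkS4class{SelectionModel} or
#'   \linkS4class{MultiTraitSelection}.
#' @param nSamples number of sequences to draw.
#' @param seed integer RNG seed (mandatory; recorded in provenance).
#' @param method "importance" or "mcmc".
#' @param burninSweeps,thinFlips MCMC schedule overrides; defaults 10*L
#'   sweeps and L flips.
#' @return a \linkS4class{WeightedEnsemble}; provenance records the sampler,
#'   seed, selection parameters, and for MCMC the acceptance rate. An
#'   effective sample size below 50 is flagged in the provenance (not an
#'   error).
#' @export
sampleEnsemble <- function(delta, selection, nSamples, seed,
                           method = c("importance", "mcmc"),
                           burninSweeps = NULL, thinFlips = NULL) {
    method <- match.arg(method)
    multi <- is(selection, "MultiTraitSelection")
    d0 <- if (multi) selection@deltas[[1L]] else delta
    L <- nSites(d0)
    q <- nStates(d0)
    binary <- isBinary(d0)
    states <- if (binary) c("0", "1") else d0@states
    if (nSamples < 1L) stop("nSamples must be >= 1")
    prov <- list(sampler = method, seed = seed,
                 selection = if (multi) "multi-trait"
                             else selection@form)

    if (method == "importance") {
        X <- withSeed(seed, {
            if (binary)
                matrix(sample.int(2L, nSamples * L, replace = TRUE) - 1L,
                       nSamples, L)
            else
                matrix(sample.int(q, nSamples * L, replace = TRUE),
                       nSamples, L)
        })
        logw <- if (multi) multiTraitFitnessFromMatrix(X, selection)
                else fitnessFromTrait(traitValues(X, delta), selection)
        logw[!is.finite(logw)] <- -Inf
        w <- exp(logw - max(logw[is.finite(logw)], -Inf))
        ens <- weightedEnsemble(X, w, states = states, provenance = prov)
        if (effectiveSampleSize(ens) < 50)
            ens@provenance$lowESS <- TRUE
        return(ens)
    }

    # Metropolis MCMC with incremental trait updates
    if (is.null(burninSweeps)) burninSweeps <- 10L * L
    if (is.null(thinFlips)) thinFlips <- L
    ef <- lapply(if (multi) selection@deltas else list(delta), effectsMatrix)
    sels <- if (multi) selection@selections else list(selection)
    nTraits <- length(sels)
    withSeed(seed, {
        s <- if (binary) rep(0L, L) else rep(1L, L)
        tv <- vapply(ef, function(e) sum(e[cbind(seq_len(L), s + binary)]),
                     numeric(1L))
        # ensure a feasible start for hard selection windows
        w0 <- sum(vapply(seq_len(nTraits), function(i)
            fitnessFromTrait(tv[i], sels[[i]]), numeric(1L)))
        tries <- 0L
        while (!is.finite(w0) && tries < 10000L) {
            s <- if (binary) rbinom(L, 1L, 0.5) else sample.int(q, L, TRUE)
            tv <- vapply(ef, function(e) sum(e[cbind(seq_len(L), s + binary)]),
                         numeric(1L))
            w0 <- sum(vapply(seq_len(nTraits), function(i)
                fitnessFromTrait(tv[i], sels[[i]]), numeric(1L)))
            tries <- tries + 1L
        }
        if (!is.finite(w0))
            stop("could not find a feasible starting sequence for MCMC")
        X <- matrix(0L, nSamples, L)
        accepted <- 0L
        kept <- 0L
        flip <- 0L
        while (kept < nSamples) {
            flip <- flip + 1L
            l <- sample.int(L, 1L)
            if (binary) {
                newState <- 1L - s[l]
            } else {                   # uniform over the other q-1 states
                newState <- sample.int(q, 1L)
                while (newState == s[l]) newState <- sample.int(q, 1L)
            }
            dtv <- vapply(ef, function(e)
                e[l, newState + binary] - e[l, s[l] + binary], numeric(1L))
            wNew <- sum(vapply(seq_len(nTraits), function(i)
                fitnessFromTrait(tv[i] + dtv[i], sels[[i]]), numeric(1L)))
            if (is.finite(wNew) &&
                (wNew >= w0 || runif(1L) < exp(wNew - w0))) {
                s[l] <- newState
                tv <- tv + dtv
                w0 <- wNew
                accepted <- accepted + 1L
            }
            if (flip > burninSweeps * L &&
                (flip - burninSweeps * L) %% thinFlips == 0L) {
                kept <- kept + 1L
                X[kept, ] <- s
            }
        }
        prov$burninSweeps <- burninSweeps
        prov$thinFlips <- thinFlips
        prov$acceptanceRate <- accepted / flip
        weightedEnsemble(X, rep(1, nSamples), states = states,
                         provenance = prov)
    })
}

#' Weighted site covariance matrix of a binary ensemble
#'
#' Computes the weighted mutant fractions \eqn{\langle S_l\rangle_*} and the
#' covariance \eqn{C_{ll'} = \langle S_l S_{l'}\rangle_* -
#' \langle S_l\rangle_*\langle S_{l'}\rangle_*} (plain weighted second
#' central moment, no small-sample correction). A pseudocount ratio
#' \code{lambda} mixes the one- and two-site frequencies with those of the
#' uniform independent-site distribution before the covariance is formed
#' (binary case of the standard q-state mixture: \eqn{\tilde f_1 =
#' (1-\Lambda) f_1 + \Lambda/2}, \eqn{\tilde f_2 = (1-\Lambda) f_2 +
#' \Lambda/4} off-diagonal).
#'
#' For a q-state ensemble this dispatches to
#' \code{\link{multistateCovariance}}.
#'
#' @param ensemble a \linkS4class{WeightedEnsemble}.
#' @param lambda pseudocount ratio in [0, 1); default 0.
#' @return a \linkS4class{CovarianceResult} (binary) or
#'   \linkS4class{MultistateCovariance} (q-state).
#' @export
covariance <- function(ensemble, lambda = 0) {
    if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
    if (!isBinaryEnsemble(ensemble))
        return(multistateCovariance(ensemble, lambda = lambda))
    X <- ensemble@sequences
    w <- ensemble@weights
    f1 <- drop(crossprod(w, X))
    f2 <- crossprod(X * sqrt(w))
    f1t <- (1 - lambda) * f1 + lambda / 2
    f2t <- (1 - lambda) * f2 + lambda / 4
    diag(f2t) <- f1t
    C <- f2t - tcrossprod(f1t)
    C <- (C + t(C)) / 2
    new("CovarianceResult", Cmat = C, mutantFractions = f1t,
        pseudocount = lambda,
        provenance = c(ensemble@provenance, list(lambda = lambda)))
}

#' @rdname CovarianceResult-class
#' @export
setMethod("covarianceMatrix", "CovarianceResult", function(x) x@Cmat)

#' @rdname CovarianceResult-class
#' @export
setMethod("mutantFractions", "CovarianceResult", function(x)
    x@mutantFractions)

setMethod("show", "CovarianceResult", function(object) {
    cat(sprintf("CovarianceResult: %d x %d, pseudocount %.3g, trace %.4g\n",
                nrow(object@Cmat), ncol(object@Cmat), object@pseudocount,
                sum(diag(object@Cmat))))
})

#' Write / read an ensemble as FASTA with a weights sidecar
#'
#' Binary sequences are written over the two-letter alphabet A (state 0) and
#' M (state 1); q-state sequences use their state labels directly (single
#' characters required, e.g. amino acids plus "-"). Weights go to
#' \code{<path>.weights.tsv}.
#'
#' @param ensemble a \linkS4class{WeightedEnsemble}.
#' @param path FASTA file path.
#' @return \code{writeEnsembleFasta} returns \code{path} invisibly;
#'   \code{readEnsembleFasta} returns a \linkS4class{WeightedEnsemble}.
#' @export
writeEnsembleFasta <- function(ensemble, path) {
    X <- ensemble@sequences
    if (isBinaryEnsemble(ensemble)) {
        alphabet <- c("A", "M")
        chars <- matrix(alphabet[X + 1L], nrow(X), ncol(X))
    } else {
        if (any(nchar(ensemble@states) != 1L))
            stop("FASTA export needs single-character state labels")
        chars <- matrix(ensemble@states[X], nrow(X), ncol(X))
    }
    seqs <- apply(chars, 1L, paste0, collapse = "")
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
    if (isBinaryEnsemble(ensemble))
        names(seqs)[1L] <- "seq1 mapping:A=0,M=1"
    aa <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(aa, path)
    write.table(data.frame(sequence = sprintf("seq%d", seq_len(nrow(X))),
                           weight = ensemble@weights),
                paste0(path, ".weights.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeEnsembleFasta
#' @param binary logical; interpret A/M as binary states 0/1.
#' @param states state alphabet for q-state input.
#' @export
readEnsembleFasta <- function(path, binary = TRUE, states = NULL) {
    ss <- Biostrings::readBStringSet(path)
    chars <- do.call(rbind, strsplit(as.character(ss), ""))
    if (binary) {
        X <- matrix(match(chars, c("A", "M")) - 1L, nrow(chars), ncol(chars))
        states <- c("0", "1")
    } else {
        if (is.null(states)) states <- sort(unique(as.vector(chars)))
        X <- matrix(match(chars, states), nrow(chars), ncol(chars))
    }
    wpath <- paste0(path, ".weights.tsv")
    w <- if (file.exists(wpath)) read.delim(wpath)$weight
         else rep(1, nrow(X))
    weightedEnsemble(X, w, states = states,
                     provenance = list(sampler = "fasta", file = path))
}
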