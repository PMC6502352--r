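#' @import methods
#' @importFrom stats rnorm runif rbinom mad median cor sd setNames
#' @importFrom utils read.delim write.table head
NULL

#' MutationalEffects: per-site effects of mutations on an additive trait
#'
#' Container for a mutational-effect vector \eqn{\Delta}. Effects are stored
#' as an L x q matrix (sites x states) with a designated reference state per
#' site whose effect is exactly zero (the gauge). The binary model is the
#' special case q = 2 with states "0" (reference) and "1" (mutant).
#'
#' @slot effects numeric L x q matrix of per-site, per-state trait effects.
#' @slot states character vector of state labels (columns of \code{effects}).
#' @slot reference integer vector, per-site column index of the gauge state.
#' @slot sectorSites integer vector of designated large-effect sites
#'   (may be empty; populated by the synthetic generators).
#' @slot traitName free-text name of the trait.
#' @slot units free-text units of the trait.
#' @export
setClass("MutationalEffects",
    representation(effects = "matrix", states = "character",
                   reference = "integer", sectorSites = "integer",
                   traitName = "character", units = "character"))

setValidity("MutationalEffects", function(object) {
    ef <- object@effects
    L <- nrow(ef)
    if (L < 1L) return("need at least one site")
    if (!all(is.finite(ef))) return("all effects must be finite")
    if (ncol(ef) != length(object@states) || ncol(ef) < 2L)
        return("ncol(effects) must equal length(states) and be >= 2")
    if (length(object@reference) != L ||
        any(object@reference < 1L | object@reference > ncol(ef)))
        return("reference must give one valid state column per site")
    if (any(ef[cbind(seq_len(L), object@reference)] != 0))
        return("the reference state must have effect exactly 0 at every site")
    if (length(object@sectorSites) &&
        any(object@sectorSites < 1L | object@sectorSites > L))
        return("sectorSites out of range")
    TRUE
})

#' SelectionModel: a fitness functional form acting on an additive trait
#'
#' Describes how a scalar trait T maps to fitness w and hence to an
#' unnormalized Boltzmann weight exp(w). Supported forms: \code{"gaussian"}
#' (w = -kappa/2 (T - T*)^2), \code{"quartic"} (w = -kappa4/2 (T - T*)^4),
#' \code{"rectangular"} (w = 0 inside an inclusive window of half-width
#' around the center, -Inf outside) and \code{"threshold"} (w = 0 for
#' T >= threshold, -Inf below).
#'
#' @slot form character, one of gaussian/quartic/rectangular/threshold.
#' @slot kappa Gaussian selection strength (1/trait^2 units).
#' @slot kappa4 quartic selection strength (1/trait^4 units).
#' @slot tStar favored trait value (gaussian/quartic) or window center
#'   (rectangular).
#' @slot halfWidth rectangular window half-width (inclusive bounds).
#' @slot threshold minimum trait value under threshold selection.
#' @slot gamma relative selection bias (T* - <T>)/sd(T) under the unselected
#'   ensemble; NA when constructed without a MutationalEffects object.
#' @export
setClass("SelectionModel",
    representation(form = "character", kappa = "numeric", kappa4 = "numeric",
                   tStar = "numeric", halfWidth = "numeric",
                   threshold = "numeric", gamma = "numeric"))

setValidity("SelectionModel", function(object) {
    forms <- c("gaussian", "quartic", "rectangular", "threshold")
    if (length(object@form) != 1L || !object@form %in% forms)
        return(sprintf("form must be one of %s", paste(forms, collapse = ", ")))
    if (object@form == "gaussian" &&
        (!is.finite(object@kappa) || object@kappa <= 0))
        return("gaussian selection needs kappa > 0")
    if (object@form == "quartic" &&
        (!is.finite(object@kappa4) || object@kappa4 <= 0))
        return("quartic selection needs kappa4 > 0")
    if (object@form == "rectangular" &&
        (!is.finite(object@halfWidth) || object@halfWidth < 0))
        return("rectangular selection needs halfWidth >= 0")
    if (object@form == "threshold" && !is.finite(object@threshold))
        return("threshold selection needs a finite threshold")
    TRUE
})

#' MultiTraitSelection: independent Gaussian selection on several traits
#'
#' @slot deltas list of \linkS4class{MutationalEffects}, all with the same
#'   number of sites and the same alphabet.
#' @slot selections list of \linkS4class{SelectionModel}, one per trait.
#' @export
setClass("MultiTraitSelection",
    representation(deltas = "list", selections = "list"))

setValidity("MultiTraitSelection", function(object) {
    n <- length(object@deltas)
    if (n < 1L || length(object@selections) != n)
        return("need one SelectionModel per MutationalEffects, N >= 1")
    if (!all(vapply(object@deltas, is, TRUE, class2 = "MutationalEffects")))
        return("deltas must be MutationalEffects objects")
    if (!all(vapply(object@selections, is, TRUE, class2 = "SelectionModel")))
        return("selections must be SelectionModel objects")
    Ls <- vapply(object@deltas, function(d) nrow(d@effects), 1L)
    qs <- vapply(object@deltas, function(d) ncol(d@effects), 1L)
    if (length(unique(Ls)) != 1L || length(unique(qs)) != 1L)
        return("all traits must share sequence length and alphabet")
    TRUE
})

#' WeightedEnsemble: sequences with normalized statistical weights
#'
#' @slot sequences integer M x L matrix; 0/1 for the binary alphabet,
#'   1..q state indices otherwise.
#' @slot weights numeric length-M vector of nonnegative weights summing to 1.
#' @slot states character vector of state labels.
#' @slot provenance list recording sampler, seed and selection parameters.
#' @export
setClass("WeightedEnsemble",
    representation(sequences = "matrix", weights = "numeric",
                   states = "character", provenance = "list"))

setValidity("WeightedEnsemble", function(object) {
    M <- nrow(object@sequences)
    if (M < 1L) return("need at least one sequence")
    if (length(object@weights) != M) return("one weight per sequence")
    if (any(object@weights < 0)) return("weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-12)
        return("weights must sum to 1 within 1e-12")
    TRUE
})

#' CovarianceResult: weighted site covariance of a binary ensemble
#'
#' @slot Cmat numeric L x L symmetric covariance matrix (weighted
#'   second central moment).
#' @slot mutantFractions per-site weighted mutant fractions after pseudocount.
#' @slot pseudocount pseudocount ratio Lambda in [0, 1).
#' @slot provenance list.
#' @export
setClass("CovarianceResult",
    representation(Cmat = "matrix", mutantFractions = "numeric",
                   pseudocount = "numeric", provenance = "list"))

setValidity("CovarianceResult", function(object) {
    C <- object@Cmat
    if (nrow(C) != ncol(C)) return("C must be square")
    if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
        return("C must be symmetric")
    if (length(object@mutantFractions) != nrow(C))
        return("one mutant fraction per site")
    if (object@pseudocount < 0 || object@pseudocount >= 1)
        return("pseudocount must lie in [0, 1)")
    TRUE
})

#' SpectralResult: eigendecomposition of a symmetric site matrix
#'
#' @slot values eigenvalues sorted in decreasing order.
#' @slot vectors orthonormal eigenvectors (columns), sign-fixed so that each
#'   vector's largest-magnitude component is positive.
#' @slot matrixKind one of "covariance", "icod", "sca".
#' @slot source list of provenance metadata.
#' @export
setClass("SpectralResult",
    representation(values = "numeric", vectors = "matrix",
                   matrixKind = "character", source = "list"))

setValidity("SpectralResult", function(object) {
    K <- length(object@values)
    if (ncol(object@vectors) != K) return("one eigenvector per eigenvalue")
    if (is.unsorted(rev(object@values), strictly = FALSE))
        return("eigenvalues must be sorted in decreasing order")
    G <- crossprod(object@vectors)
    if (max(abs(G - diag(K))) > 1e-8)
        return("eigenvectors must be orthonormal within 1e-8")
    TRUE
})

#' RecoveryReport: Recovery of a mutational-effect vector per spectral mode
#'
#' @slot perMode Recovery value for each eigenvector, each in [0, 1].
#' @slot randomExpectation expected Recovery of a uniformly random unit
#'   vector against the same effects.
#' @slot bestMode index of the mode with maximal Recovery.
#' @export
setClass("RecoveryReport",
    representation(perMode = "numeric", randomExpectation = "numeric",
                   bestMode = "integer"))

setValidity("RecoveryReport", function(object) {
    if (any(object@perMode < -1e-12 | object@perMode > 1 + 1e-12))
        return("Recovery values must lie in [0, 1]")
    if (object@randomExpectation <= 0 || object@randomExpectation >= 1)
        return("random expectation must lie in (0, 1)")
    TRUE
})

#' ElasticNetwork: Calpha/Cbeta spring network of a protein structure
#'
#' @slot nodes data.frame with columns residue, role ("CA"/"CB"), x, y, z
#'   (Angstrom).
#' @slot springs data.frame with columns i, j (node row indices), restLength
#'   (Angstrom) and k (spring constant).
#' @slot L number of residues.
#' @export
setClass("ElasticNetwork",
    representation(nodes = "data.frame", springs = "data.frame",
                   L = "integer"))

setValidity("ElasticNetwork", function(object) {
    if (nrow(object@springs) < 1L) return("network has no springs")
    if (any(object@springs$i == object@springs$j))
        return("springs must connect distinct nodes")
    if (!all(object@springs$k > 0)) return("spring constants must be positive")
    if (!all(c("residue", "role", "x", "y", "z") %in% colnames(object@nodes)))
        return("nodes need residue, role, x, y, z columns")
    TRUE
})

#' Deformation: displacement field over the nodes of an elastic network
#'
#' @slot dr numeric 3N displacement vector (Angstrom), ordered as
#'   (x1, y1, z1, x2, ...) over network nodes.
#' @slot source free-text provenance, e.g. "ligand-free -> ligand-bound".
#' @export
setClass("Deformation",
    representation(dr = "numeric", source = "character"))

setValidity("Deformation", function(object) {
    if (!all(is.finite(object@dr))) return("displacements must be finite")
    if (length(object@dr) %% 3L != 0L) return("dr length must be 3N")
    TRUE
})

#' PerturbationResult: first-order mutational effects of an elastic network
#'
#' @slot delta \linkS4class{MutationalEffects} of length L (binary alphabet).
#' @slot epsilon spring-weakening fraction used.
#' @slot baselineEnergy deformation energy of the reference sequence.
#' @slot exactSingleMutant exact single-mutant deformation-energy changes at
#'   the given epsilon, for validation against the first-order delta.
#' @export
setClass("PerturbationResult",
    representation(delta = "MutationalEffects", epsilon = "numeric",
                   baselineEnergy = "numeric", exactSingleMutant = "numeric"))

#' EncodedAlignment: gap-filtered, state-indexed multiple sequence alignment
#'
#' @slot sequences integer M x L' matrix of state indices over retained sites.
#' @slot states state alphabet (20 amino acids plus "-" by default).
#' @slot retainedSites 1-based original column indices kept after gap
#'   filtering.
#' @slot gauge per-retained-site index of the gauge (reference) state.
#' @slot gapFrequency gap frequency of every original column.
#' @slot weights per-sequence weights (uniform unless reweighting requested).
#' @export
setClass("EncodedAlignment",
    representation(sequences = "matrix", states = "character",
                   retainedSites = "integer", gauge = "integer",
                   gapFrequency = "numeric", weights = "numeric"))

#' MultistateCovariance: q-state covariance matrix in a declared gauge
#'
#' @slot Cmat L'(q-1) x L'(q-1) symmetric covariance matrix over non-gauge
#'   states.
#' @slot siteMap data.frame mapping (site, state) to matrix row.
#' @slot frequencies L' x q row-stochastic state frequencies (pseudocounted).
#' @slot pseudocount pseudocount ratio Lambda.
#' @slot retainedSites original site indices.
#' @slot gauge per-site gauge state index.
#' @slot states state alphabet.
#' @export
setClass("MultistateCovariance",
    representation(Cmat = "matrix", siteMap = "data.frame",
                   frequencies = "matrix", pseudocount = "numeric",
                   retainedSites = "integer", gauge = "integer",
                   states = "character"))

setValidity("MultistateCovariance", function(object) {
    if (max(abs(rowSums(object@frequencies) - 1)) > 1e-12)
        return("frequency rows must sum to 1 within 1e-12")
    if (nrow(object@Cmat) != ncol(object@Cmat)) return("C must be square")
    if (max(abs(object@Cmat - t(object@Cmat))) > 1e-10 * max(1, max(abs(object@Cmat))))
        return("C must be symmetric")
    TRUE
})

#' CompressedICOD: Frobenius-compressed ICOD matrix over sites
#'
#' @slot fmat L' x L' symmetric nonnegative matrix; entry (l, l') is the
#'   Frobenius norm of the corresponding off-diagonal block of the
#'   diagonal-zeroed inverse covariance matrix; the diagonal is zero.
#' @slot compression compression scheme, currently "frobenius".
#' @export
setClass("CompressedICOD",
    representation(fmat = "matrix", compression = "character"))

setValidity("CompressedICOD", function(object) {
    Fm <- object@fmat
    if (any(diag(Fm) != 0)) return("diagonal must be zero")
    if (any(Fm < 0)) return("entries must be nonnegative")
    if (max(abs(Fm - t(Fm))) > 1e-10 * max(1, max(Fm)))
        return("matrix must be symmetric")
    TRUE
})

#' MultistateICODResult: ICOD analysis of a q-state covariance matrix
#'
#' @slot compressed \linkS4class{CompressedICOD} site-level matrix.
#' @slot spectrum \linkS4class{SpectralResult} of the compressed matrix.
#' @slot icodMatrix the uncompressed diagonal-block-zeroed inverse covariance.
#' @slot icodSpectrum \linkS4class{SpectralResult} of \code{icodMatrix}.
#' @slot siteScores per-site magnitude of the top compressed eigenvector.
#' @slot ranking retained-site indices ordered by decreasing score.
#' @export
setClass("MultistateICODResult",
    representation(compressed = "CompressedICOD", spectrum = "SpectralResult",
                   icodMatrix = "matrix", icodSpectrum = "SpectralResult",
                   siteScores = "numeric", ranking = "integer"))
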