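#' @rdname MutationalEffects-class
#' @param x,object an object.
#' @export
setGeneric("effectsMatrix", function(x) standardGeneric("effectsMatrix"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("deltaVector", function(x) standardGeneric("deltaVector"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("isBinary", function(x) standardGeneric("isBinary"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("sectorSites", function(x) standardGeneric("sectorSites"))

#' @rdname MutationalEffects-class
#' @export
setGeneric("referenceStates", function(x) standardGeneric("referenceStates"))

#' @rdname WeightedEnsemble-class
#' @export
setGeneric("sequenceMatrix", function(x) standardGeneric("sequenceMatrix"))

#' @rdname WeightedEnsemble-class
#' @export
setGeneric("ensembleWeights", function(x) standardGeneric("ensembleWeights"))

#' @rdname WeightedEnsemble-class
#' @export
setGeneric("effectiveSampleSize",
    function(x) standardGeneric("effectiveSampleSize"))

#' @rdname SpectralResult-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname SpectralResult-class
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname CovarianceResult-class
#' @export
setGeneric("covarianceMatrix", function(x) standardGeneric("covarianceMatrix"))

#' @rdname CovarianceResult-class
#' @export
setGeneric("mutantFractions", function(x) standardGeneric("mutantFractions"))
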