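#' Construct a mutational-effect vector
#'
#' Builds a \linkS4class{MutationalEffects} object from either a length-L
#' numeric vector (binary model: effect of mutating each site away from the
#' reference state) or an L x q matrix of per-site, per-state effects in
#' which the designated reference state has effect zero at every site.
#'
#' @param effects numeric vector (binary) or L x q matrix (q-state).
#' @param states optional state labels; defaults to \code{c("0", "1")} for a
#'   vector and \code{as.character(seq_len(q) - 1)} for a matrix.
#' @param reference integer vector of per-site reference-state columns
#'   (default: state 1 everywhere).
#' @param sectorSites optional integer vector of designated sector sites.
#' @param traitName,units free-text metadata.
#' @return a \linkS4class{MutationalEffects} object.
#' @examples
#' d <- mutationalEffects(c(-1, 1, 0))
#' deltaVector(d)
#' @export
mutationalEffects <- function(effects, states = NULL, reference = NULL,
                              sectorSites = integer(0),
                              traitName = "trait", units = "") {
    if (is.numeric(effects) && is.null(dim(effects))) {
        effects <- cbind(0, as.numeric(effects))
        if (is.null(states)) states <- c("0", "1")
    } else {
        effects <- as.matrix(effects)
        if (is.null(states)) states <- as.character(seq_len(ncol(effects)) - 1L)
    }
    if (is.null(reference)) reference <- rep(1L, nrow(effects))
    dimnames(effects) <- NULL
    new("MutationalEffects", effects = effects, states = states,
        reference = as.integer(reference),
        sectorSites = as.integer(sectorSites),
        traitName = traitName, units = units)
}

#' @rdname MutationalEffects-class
#' @export
setMethod("effectsMatrix", "MutationalEffects", function(x) x@effects)

#' @rdname MutationalEffects-class
#' @export
setMethod("nSites", "MutationalEffects", function(x) nrow(x@effects))

#' @rdname MutationalEffects-class
#' @export
setMethod("nStates", "MutationalEffects", function(x) ncol(x@effects))

#' @rdname MutationalEffects-class
#' @export
setMethod("isBinary", "MutationalEffects", function(x) {
    ncol(x@effects) == 2L && all(x@reference == 1L)
})

#' @rdname MutationalEffects-class
#' @export
setMethod("deltaVector", "MutationalEffects", function(x) {
    if (!isBinary(x))
        stop("deltaVector() is defined for binary MutationalEffects only")
    x@effects[, 2L]
})

#' @rdname MutationalEffects-class
#' @export
setMethod("sectorSites", "MutationalEffects", function(x) x@sectorSites)

#' @rdname MutationalEffects-class
#' @export
setMethod("referenceStates", "MutationalEffects", function(x) x@reference)

setMethod("show", "MutationalEffects", function(object) {
    cat(sprintf("MutationalEffects \"%s\": %d sites, %d states (%s)\n",
                object@traitName, nSites(object), nStates(object),
                if (isBinary(object)) "binary" else "q-state"))
    if (length(object@sectorSites))
        cat(sprintf("  %d designated sector sites\n",
                    length(object@sectorSites)))
    if (isBinary(object)) {
        d <- deltaVector(object)
        cat(sprintf("  delta range [%.4g, %.4g], sum(delta^2) = %.4g\n",
                    min(d), max(d), sum(d^2)))
    }
})

#' Change the gauge (reference state) of a q-state effect vector
#'
#' Re-expresses the effects relative to a new per-site reference state by
#' subtracting, at each site, the effect of the new reference. Trait
#' differences between any two sequences are unchanged.
#'
#' @param delta a \linkS4class{MutationalEffects} object.
#' @param newReference integer vector of new per-site reference-state columns.
#' @return a re-gauged \linkS4class{MutationalEffects} object.
#' @export
regauge <- function(delta, newReference) {
    ef <- delta@effects
    newReference <- as.integer(rep_len(newReference, nrow(ef)))
    shift <- ef[cbind(seq_len(nrow(ef)), newReference)]
    ef <- ef - shift
    new("MutationalEffects", effects = ef, states = delta@states,
        reference = newReference, sectorSites = delta@sectorSites,
        traitName = delta@traitName, units = delta@units)
}

#' Read / write mutational-effect vectors as TSV
#'
#' The on-disk format has a header line and columns \code{site} (1-based),
#' \code{state} (omitted for the binary model) and \code{delta}.
#'
#' @param delta a \linkS4class{MutationalEffects} object.
#' @param path file path.
#' @return \code{readDeltaTsv} returns a \linkS4class{MutationalEffects};
#'   \code{writeDeltaTsv} returns \code{path} invisibly.
#' @export
writeDeltaTsv <- function(delta, path) {
    if (isBinary(delta)) {
        df <- data.frame(site = seq_len(nSites(delta)),
                         delta = deltaVector(delta))
    } else {
        L <- nSites(delta); q <- nStates(delta)
        df <- data.frame(site = rep(seq_len(L), each = q),
                         state = rep(delta@states, times = L),
                         delta = as.vector(t(delta@effects)))
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeDeltaTsv
#' @export
readDeltaTsv <- function(path) {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    if (!"state" %in% colnames(df)) {
        df <- df[order(df$site), ]
        return(mutationalEffects(df$delta))
    }
    sites <- sort(unique(df$site))
    states <- unique(df$state[df$site == sites[1L]])
    ef <- matrix(0, length(sites), length(states))
    for (i in seq_along(sites)) {
        sub <- df[df$site == sites[i], ]
        ef[i, match(sub$state, states)] <- sub$delta
    }
    ref <- apply(ef, 1L, function(r) which(r == 0)[1L])
    mutationalEffects(ef, states = as.character(states),
                      reference = as.integer(ref))
}
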