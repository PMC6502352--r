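#' Moments of an additive trait under the unselected ensemble
#'
#' Mean and standard deviation of the trait \eqn{T = \sum_l \Delta_l(\alpha_l)}
#' when every site independently takes each state with equal probability
#' (0/1 equally likely in the binary model, uniform over q states otherwise).
#'
#' @param delta a \linkS4class{MutationalEffects} object.
#' @return list with elements \code{mean} and \code{sd}.
#' @export
unselectedTraitMoments <- function(delta) {
    ef <- effectsMatrix(delta)
    m <- rowMeans(ef)
    v <- rowMeans(ef^2) - m^2      # population variance over states
    list(mean = sum(m), sd = sqrt(sum(v)))
}

#' Construct a selection model
#'
#' Builds a \linkS4class{SelectionModel}. For Gaussian and quartic selection
#' the window center may be given either directly (\code{tStar}) or as the
#' relative bias \code{gamma} in units of the unselected trait's standard
#' deviation, in which case a \code{delta} is required to resolve it. The
#' default Gaussian strength is \code{kappa = 10 / sum(delta^2)} so the
#' selection window scales with the unselected trait distribution; the
#' default quartic strength is \code{kappa4 = kappa^2 / 2}, which places the
#' one-e-fold point of the quartic window at the same distance
#' \code{sqrt(2/kappa)} from the center as the default Gaussian window.
#'
#' @param form one of \code{"gaussian"}, \code{"quartic"},
#'   \code{"rectangular"}, \code{"threshold"}.
#' @param delta optional \linkS4class{MutationalEffects} used to resolve
#'   defaults (\code{kappa}) and \code{gamma}.
#' @param kappa Gaussian selection strength; default \code{10/sum(delta^2)}.
#' @param kappa4 quartic strength; default \code{kappa^2/2}.
#' @param tStar window center (gaussian, quartic, rectangular).
#' @param gamma relative selection bias; alternative to \code{tStar}.
#' @param halfWidth rectangular half-width (inclusive bounds; 0 selects
#'   \code{T == tStar} exactly).
#' @param threshold minimum trait value for threshold selection; may instead
#'   be supplied through \code{gamma} (relative threshold).
#' @return a \linkS4class{SelectionModel}.
#' @examples
#' d <- mutationalEffects(c(-1, 1, 0.5))
#' selectionModel("gaussian", d, gamma = 0)
#' @export
selectionModel <- function(form = c("gaussian", "quartic", "rectangular",
                                    "threshold"),
                           delta = NULL, kappa = NULL, kappa4 = NULL,
                           tStar = NULL, gamma = NULL, halfWidth = NULL,
                           threshold = NULL) {
    form <- match.arg(form)
    mom <- if (!is.null(delta)) unselectedTraitMoments(delta) else NULL

    resolveCenter <- function(center, what) {
        if (!is.null(center)) return(center)
        if (!is.null(gamma)) {
            if (is.null(mom))
                stop("'gamma' needs a 'delta' to resolve the trait moments")
            return(mom$mean + gamma * mom$sd)
        }
        stop(sprintf("%s selection needs '%s' or 'gamma' (with 'delta')",
                     form, what))
    }
    sumsq <- function() {
        if (is.null(delta))
            stop("default kappa = 10/sum(delta^2) needs a 'delta'")
        d2 <- sum(effectsMatrix(delta)^2)
        if (d2 <= 0) stop("delta has no nonzero effects")
        d2
    }

    kap <- NA_real_; kap4 <- NA_real_; ts <- NA_real_
    hw <- NA_real_; th <- NA_real_
    if (form %in% c("gaussian", "quartic")) {
        kap <- if (is.null(kappa)) 10 / sumsq() else kappa
        ts <- resolveCenter(tStar, "tStar")
        if (form == "quartic")
            kap4 <- if (is.null(kappa4)) kap^2 / 2 else kappa4
    } else if (form == "rectangular") {
        ts <- resolveCenter(tStar, "tStar")
        if (is.null(halfWidth)) stop("rectangular selection needs 'halfWidth'")
        hw <- halfWidth
    } else {
        th <- resolveCenter(threshold, "threshold")
    }
    g <- if (!is.null(mom) && mom$sd > 0) {
        center <- if (form == "threshold") th else ts
        (center - mom$mean) / mom$sd
    } else NA_real_
    new("SelectionModel", form = form, kappa = kap, kappa4 = kap4,
        tStar = ts, halfWidth = hw, threshold = th, gamma = g)
}

#' Relative selection bias of a selection model
#'
#' Recomputes \eqn{\gamma = (T^* - \langle T\rangle)/\mathrm{sd}(T)} under
#' the unselected ensemble of \code{delta} (for threshold selection the
#' threshold plays the role of the center).
#'
#' @param selection a \linkS4class{SelectionModel}.
#' @param delta a \linkS4class{MutationalEffects}.
#' @return numeric scalar.
#' @export
relativeBias <- function(selection, delta) {
    mom <- unselectedTraitMoments(delta)
    center <- if (selection@form == "threshold") selection@threshold
              else selection@tStar
    (center - mom$mean) / mom$sd
}

#' Additive trait value of a sequence
#'
#' Evaluates \eqn{T(\alpha) = \sum_l \Delta_l(\alpha_l)}. Binary sequences
#' are 0/1 vectors (\eqn{T = \sum_l S_l \Delta_l}); q-state sequences are
#' vectors of state indices in 1..q.
#'
#' @param sequence integer vector of length L.
#' @param delta a \linkS4class{MutationalEffects}.
#' @return numeric trait value; exactly additive over sites.
#' @examples
#' traitValue(c(1, 0, 1), mutationalEffects(c(2, -3, 0.5)))  # 2.5
#' @export
traitValue <- function(sequence, delta) {
    ef <- effectsMatrix(delta)
    if (length(sequence) != nrow(ef))
        stop(sprintf("sequence length %d does not match %d sites",
                     length(sequence), nrow(ef)))
    if (isBinary(delta)) {
        if (!all(sequence %in% c(0, 1)))
            stop("binary sequences must contain only 0 and 1")
        return(sum(ef[, 2L] * sequence))
    }
    if (any(sequence < 1L | sequence > ncol(ef)))
        stop("state indices out of range for this alphabet")
    sum(ef[cbind(seq_len(nrow(ef)), as.integer(sequence))])
}

# Vectorized: trait values of the rows of an M x L state matrix.
traitValues <- function(X, delta) {
    ef <- effectsMatrix(delta)
    if (ncol(X) != nrow(ef)) stop("sequence length mismatch")
    if (isBinary(delta)) return(drop(X %*% ef[, 2L]))
    tv <- numeric(nrow(X))
    for (l in seq_len(ncol(X))) tv <- tv + ef[l, X[, l]]
    tv
}

# Fitness as a function of the trait value alone (vectorized over tv).
fitnessFromTrait <- function(tv, selection) {
    switch(selection@form,
        gaussian = -(selection@kappa / 2) * (tv - selection@tStar)^2,
        quartic = -(selection@kappa4 / 2) * (tv - selection@tStar)^4,
        rectangular = ifelse(abs(tv - selection@tStar) <=
                                 selection@halfWidth, 0, -Inf),
        threshold = ifelse(tv >= selection@threshold, 0, -Inf),
        stop(sprintf("unknown selection form '%s'", selection@form)))
}

#' Fitness of a sequence under a selection model
#'
#' Gaussian: \eqn{w = -\kappa/2\,(T - T^*)^2}; quartic:
#' \eqn{w = -\kappa_4/2\,(T - T^*)^4}; rectangular and threshold selection
#' give fitness 0 inside the admissible region and \code{-Inf} outside
#' (weight exactly 0 after exponentiation, never NaN).
#'
#' @inheritParams traitValue
#' @param selection a \linkS4class{SelectionModel}.
#' @return numeric fitness (log-weight); may be \code{-Inf}.
#' @export
fitness <- function(sequence, selection, delta) {
    fitnessFromTrait(traitValue(sequence, delta), selection)
}

#' Unnormalized Boltzmann weight of a sequence
#'
#' \code{exp(fitness)}; normalization is performed by the ensemble module.
#'
#' @inheritParams fitness
#' @return nonnegative numeric weight (underflow clamps to 0).
#' @export
seqWeight <- function(sequence, selection, delta) {
    exp(fitness(sequence, selection, delta))
}

#' Construct a multi-trait selection model
#'
#' @param deltas list of \linkS4class{MutationalEffects} sharing length and
#'   alphabet.
#' @param selections list of \linkS4class{SelectionModel}, one per trait.
#' @return a \linkS4class{MultiTraitSelection}.
#' @export
multiTraitSelection <- function(deltas, selections) {
    new("MultiTraitSelection", deltas = deltas, selections = selections)
}

#' Fitness under independent selection on several additive traits
#'
#' Sum of the per-trait fitness terms
#' \eqn{w = -\sum_i \kappa_i/2\,(T_i - T_i^*)^2}.
#'
#' @param sequence integer vector of length L.
#' @param msel a \linkS4class{MultiTraitSelection}.
#' @return numeric fitness.
#' @export
multiTraitFitness <- function(sequence, msel) {
    sum(vapply(seq_along(msel@deltas), function(i)
        fitness(sequence, msel@selections[[i]], msel@deltas[[i]]),
        numeric(1L)))
}

multiTraitFitnessFromMatrix <- function(X, msel) {
    w <- numeric(nrow(X))
    for (i in seq_along(msel@deltas))
        w <- w + fitnessFromTrait(traitValues(X, msel@deltas[[i]]),
                                  msel@selections[[i]])
    w
}

setMethod("show", "SelectionModel", function(object) {
    cat(sprintf("SelectionModel: %s\n", object@form))
    fields <- c(kappa = object@kappa, kappa4 = object@kappa4,
                tStar = object@tStar, halfWidth = object@halfWidth,
                threshold = object@threshold, gamma = object@gamma)
    fields <- fields[is.finite(fields)]
    if (length(fields))
        cat(paste(sprintf("  %s = %.6g", names(fields), fields),
                  collapse = "\n"), "\n")
})

#' Serialize / deserialize a selection model as JSON
#'
#' @param selection a \linkS4class{SelectionModel}.
#' @param path optional file path; if \code{NULL} the JSON string is
#'   returned.
#' @return \code{selectionToJson}: the JSON string (invisibly if written to
#'   a file); \code{selectionFromJson}: a \linkS4class{SelectionModel}.
#' @export
selectionToJson <- function(selection, path = NULL) {
    x <- list(form = selection@form, kappa = selection@kappa,
              kappa4 = selection@kappa4, t_star = selection@tStar,
              half_width = selection@halfWidth,
              threshold = selection@threshold, gamma = selection@gamma,
              kappa4_default_rule = "kappa4 = kappa^2/2 (one-e-fold width matched to gaussian default)")
    x <- x[vapply(x, function(v) is.character(v) || is.finite(v), TRUE)]
    js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' @rdname selectionToJson
#' @param json JSON string or file path to parse.
#' @export
selectionFromJson <- function(json) {
    x <- jsonlite::fromJSON(json)
    num <- function(n) if (is.null(x[[n]])) NA_real_ else as.numeric(x[[n]])
    new("SelectionModel", form = x$form, kappa = num("kappa"),
        kappa4 = num("kappa4"), tStar = num("t_star"),
        halfWidth = num("half_width"), threshold = num("threshold"),
        gamma = num("gamma"))
}
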