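#' Generate a synthetic sector-structured mutational-effect vector
#'
#' Draws \code{nSectorSites} site positions at random and assigns them
#' large effects (\code{Normal(0, sectorScale^2)}, or a negative half-normal
#' under \code{signPolicy = "all_negative"}); the remaining sites get small
#' background effects (\code{Normal(0, backgroundScale^2)}). Deterministic
#' given \code{seed}. Default scale ratio 10.
#'
#' @param L sequence length.
#' @param nSectorSites number of large-effect (sector) sites, 1..L.
#' @param sectorScale,backgroundScale effect standard deviations; their
#'   ratio must be >= 1.
#' @param signPolicy "mixed" (default) or "all_negative".
#' @param seed integer RNG seed.
#' @return a binary \linkS4class{MutationalEffects} whose
#'   \code{sectorSites} slot records the drawn sector positions.
#' @export
makeDelta <- function(L, nSectorSites, sectorScale = 10,
                      backgroundScale = 1,
                      signPolicy = c("mixed", "all_negative"), seed = 1) {
    signPolicy <- match.arg(signPolicy)
    if (nSectorSites < 1L || nSectorSites > L)
        stop("need 1 <= nSectorSites <= L")
    if (sectorScale <= 0 || backgroundScale <= 0 ||
        sectorScale < backgroundScale)
        stop("scales must be positive with sectorScale >= backgroundScale")
    withSeed(seed, {
        sites <- sort(sample.int(L, nSectorSites))
        d <- rnorm(L, 0, backgroundScale)
        d[sites] <- rnorm(nSectorSites, 0, sectorScale)
        if (signPolicy == "all_negative") d <- -abs(d)
        mutationalEffects(d, sectorSites = sites, traitName = "synthetic")
    })
}

#' Generate a pair of synthetic effect vectors with overlapping sectors
#'
#' Builds two sector-structured vectors whose sector-site sets share a
#' fraction \code{overlapFraction} of their sites (rounded to the nearest
#' integer count). At fraction 0 the sets are disjoint, at 1 they coincide.
#' Effect values are drawn independently even on shared sites.
#'
#' @inheritParams makeDelta
#' @param size1,size2 sector sizes of the two vectors (default both 20).
#' @param overlapFraction requested overlap in [0, 1], as a fraction of the
#'   smaller sector.
#' @return list of two \linkS4class{MutationalEffects}.
#' @export
makeDeltaPair <- function(L, size1 = 20, size2 = size1, overlapFraction,
                          sectorScale = 10, backgroundScale = 1,
                          signPolicy = c("mixed", "all_negative"),
                          seed = 1) {
    signPolicy <- match.arg(signPolicy)
    if (overlapFraction < 0 || overlapFraction > 1)
        stop("overlapFraction must lie in [0, 1]")
    nShared <- round(overlapFraction * min(size1, size2))
    if (size1 + size2 - nShared > L)
        stop("requested overlap is infeasible: the union exceeds L sites")
    withSeed(seed, {
        sites1 <- sort(sample.int(L, size1))
        shared <- sort(sample(sites1, nShared))
        pool <- setdiff(seq_len(L), sites1)
        sites2 <- sort(c(shared, sample(pool, size2 - nShared)))
        drawOne <- function(sites) {
            d <- rnorm(L, 0, backgroundScale)
            d[sites] <- rnorm(length(sites), 0, sectorScale)
            if (signPolicy == "all_negative") d <- -abs(d)
            mutationalEffects(d, sectorSites = sites,
                              traitName = "synthetic")
        }
        list(drawOne(sites1), drawOne(sites2))
    })
}

#' Generate a synthetic q-state mutational-effect matrix
#'
#' Per-site, per-state effects with reference state 1 fixed at zero; the
#' sector structure lives in the per-site norm of the effects across the
#' q-1 non-reference states (each drawn \code{Normal(0, scale^2)} with the
#' site's scale). With q = 2 this reduces exactly to \code{\link{makeDelta}}.
#'
#' @inheritParams makeDelta
#' @param q number of states (>= 2).
#' @param states optional state labels.
#' @return a q-state \linkS4class{MutationalEffects}.
#' @export
makeMultistateDelta <- function(L, q, nSectorSites, sectorScale = 10,
                                backgroundScale = 1,
                                signPolicy = c("mixed", "all_negative"),
                                seed = 1, states = NULL) {
    signPolicy <- match.arg(signPolicy)
    if (q < 2L) stop("need q >= 2")
    if (q == 2L)
        return(makeDelta(L, nSectorSites, sectorScale, backgroundScale,
                         signPolicy, seed))
    withSeed(seed, {
        sites <- sort(sample.int(L, nSectorSites))
        scale <- rep(backgroundScale, L)
        scale[sites] <- sectorScale
        ef <- cbind(0, matrix(rnorm(L * (q - 1L)), L, q - 1L) * scale)
        if (signPolicy == "all_negative") ef <- -abs(ef)
        mutationalEffects(ef, states = states, sectorSites = sites,
                          traitName = "synthetic q-state")
    })
}

#' Generate a toy protein structure and a deformed copy
#'
#' Builds reproducible 3D CA/CB coordinates — an ideal alpha-helix (radius
#' 2.3 A, rise 1.5 A, 100 degrees per residue, CB displaced 1.6 A radially
#' outward) or a self-avoiding random coil with 3.8 A virtual bonds — plus
#' a copy in which a contiguous block of residues is coherently displaced,
#' mimicking a localized conformational change.
#'
#' @param nResidues number of residues (>= 3).
#' @param geometry "helix" or "random_coil".
#' @param seed RNG seed (used by the random coil and the displacement
#'   direction).
#' @param displacedResidues residue indices to displace (default: the
#'   central fifth, at least 3 residues).
#' @param displacement magnitude of the coherent displacement in Angstrom.
#' @return list with elements \code{reference} and \code{displaced}
#'   (structure data.frames) and \code{displacedResidues}.
#' @export
makeToyStructure <- function(nResidues, geometry = c("helix", "random_coil"),
                             seed = 1, displacedResidues = NULL,
                             displacement = 1.0) {
    geometry <- match.arg(geometry)
    if (nResidues < 3L) stop("need at least 3 residues")
    withSeed(seed, {
        if (geometry == "helix") {
            th <- (seq_len(nResidues) - 1L) * 100 * pi / 180
            ca <- cbind(2.3 * cos(th), 2.3 * sin(th),
                        1.5 * (seq_len(nResidues) - 1L))
            cb <- ca + cbind(1.6 * cos(th), 1.6 * sin(th), 0)
        } else {
            ca <- matrix(0, nResidues, 3L)
            for (i in seq(2L, nResidues)) {
                repeat {
                    step <- rnorm(3L)
                    step <- 3.8 * step / sqrt(sum(step^2))
                    cand <- ca[i - 1L, ] + step
                    dmin <- if (i > 2L)
                        min(sqrt(rowSums((ca[seq_len(i - 2L), , drop = FALSE] -
                            matrix(cand, i - 2L, 3L, byrow = TRUE))^2)))
                    else Inf
                    if (dmin > 3.0) break
                }
                ca[i, ] <- cand
            }
            off <- matrix(rnorm(nResidues * 3L), nResidues, 3L)
            off <- 1.6 * off / sqrt(rowSums(off^2))
            cb <- ca + off
        }
        st <- data.frame(
            residue = rep(seq_len(nResidues), each = 2L),
            role = rep(c("CA", "CB"), nResidues),
            x = as.vector(rbind(ca[, 1L], cb[, 1L])),
            y = as.vector(rbind(ca[, 2L], cb[, 2L])),
            z = as.vector(rbind(ca[, 3L], cb[, 3L])),
            stringsAsFactors = FALSE)
        if (is.null(displacedResidues)) {
            w <- max(3L, round(nResidues / 5))
            start <- floor((nResidues - w) / 2) + 1L
            displacedResidues <- start:(start + w - 1L)
        }
        dir <- rnorm(3L)
        dir <- displacement * dir / sqrt(sum(dir^2))
        displaced <- st
        rows <- displaced$residue %in% displacedResidues
        displaced[rows, c("x", "y", "z")] <-
            displaced[rows, c("x", "y", "z")] +
            matrix(dir, sum(rows), 3L, byrow = TRUE)
        list(reference = st, displaced = displaced,
             displacedResidues = displacedResidues)
    })
}

#' Write a toy CA/CB structure as a minimal PDB file
#'
#' Emits standard fixed-width ATOM records (alanine residues, chain A) so
#' toy structures round-trip through \code{\link{readStructurePDB}}.
#'
#' @param structure a structure data.frame (residue, role, x, y, z).
#' @param path output PDB path.
#' @return \code{path}, invisibly.
#' @export
writeToyPDB <- function(structure, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(structure))) {
        writeLines(sprintf(
            "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, structure$role[i], structure$residue[i],
            structure$x[i], structure$y[i], structure$z[i]), con)
    }
    writeLines("END", con)
    invisible(path)
}
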