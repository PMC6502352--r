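#' Read Calpha/Cbeta coordinates from a PDB file
#'
#' Parses ATOM records (via bio3d), keeping CA and CB atoms, selecting the
#' highest-occupancy alternate conformer and preserving insertion codes in
#' the residue identifier used for matching between structures.
#'
#' @param path PDB file path.
#' @param chain optional chain identifier(s) to keep.
#' @return data.frame with columns residue (sequential 1-based index),
#'   resid (author residue number + insertion code + chain, for matching),
#'   role ("CA"/"CB"), x, y, z.
#' @export
readStructurePDB <- function(path, chain = NULL) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    at <- at[at$type == "ATOM" & at$elety %in% c("CA", "CB"), ]
    if (!is.null(chain)) at <- at[at$chain %in% chain, ]
    if (nrow(at) == 0L) stop("no CA/CB ATOM records found")
    key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "",
                                            at$insert), at$elety)
    # highest-occupancy alternate conformer per atom
    at <- at[order(key, -replace(at$o, is.na(at$o), 1)), ]
    at <- at[!duplicated(paste(at$chain, at$resno,
                               ifelse(is.na(at$insert), "", at$insert),
                               at$elety)), ]
    resKey <- paste0(at$chain, ":", at$resno,
                     ifelse(is.na(at$insert), "", at$insert))
    ord <- order(match(resKey, unique(resKey)),
                 match(at$elety, c("CA", "CB")))
    at <- at[ord, ]
    resKey <- resKey[ord]
    df <- data.frame(residue = match(resKey, unique(resKey)),
                     resid = resKey, role = at$elety,
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
    missingCA <- setdiff(unique(df$residue),
                         df$residue[df$role == "CA"])
    if (length(missingCA))
        stop("residue(s) without a CA atom: ",
             paste(unique(df$resid)[missingCA], collapse = ", "))
    df
}

#' Build a Calpha/Cbeta elastic network
#'
#' Connects every pair of carbons within the cutoff distance \code{cutoff}
#' (default 7.5 Angstrom) in the reference structure with a harmonic spring.
#' Default spring constants: 2 for backbone-adjacent CA-CA pairs, 1 for
#' other CA-CA pairs, 1 for CA-CB pairs, 0.5 for CB-CB pairs.
#'
#' @param structure data.frame with columns residue (1-based integer),
#'   role ("CA"/"CB"), x, y, z — e.g. from \code{\link{readStructurePDB}}
#'   or \code{\link{makeToyStructure}}.
#' @param cutoff distance cutoff in Angstrom.
#' @param constants named list of constants: \code{caCaAdjacent}, \code{caCa},
#'   \code{caCb}, \code{cbCb}.
#' @return an \linkS4class{ElasticNetwork}.
#' @export
buildNetwork <- function(structure, cutoff = 7.5,
                         constants = list(caCaAdjacent = 2, caCa = 1,
                                          caCb = 1, cbCb = 0.5)) {
    st <- as.data.frame(structure)
    need <- c("residue", "role", "x", "y", "z")
    if (!all(need %in% colnames(st)))
        stop("structure needs columns ", paste(need, collapse = ", "))
    st <- st[order(st$residue, match(st$role, c("CA", "CB"))), ]
    res <- unique(st$residue)
    if (!all(res %in% st$residue[st$role == "CA"]))
        stop("every residue must have a CA atom")
    P <- as.matrix(st[, c("x", "y", "z")])
    n <- nrow(P)
    D <- as.matrix(stats::dist(P))
    pairs <- which(upper.tri(D) & D <= cutoff & D > 0, arr.ind = TRUE)
    if (nrow(pairs) == 0L) stop("no springs within the cutoff: empty network")
    i <- pairs[, 1L]; j <- pairs[, 2L]
    ri <- st$residue[i]; rj <- st$residue[j]
    roli <- st$role[i]; rolj <- st$role[j]
    k <- numeric(length(i))
    caca <- roli == "CA" & rolj == "CA"
    k[caca] <- ifelse(abs(ri[caca] - rj[caca]) == 1L,
                      constants$caCaAdjacent, constants$caCa)
    k[xor(roli == "CA", rolj == "CA")] <- constants$caCb
    k[roli == "CB" & rolj == "CB"] <- constants$cbCb
    springs <- data.frame(i = i, j = j, restLength = D[pairs], k = k)
    new("ElasticNetwork",
        nodes = data.frame(residue = st$residue, role = st$role,
                           x = st$x, y = st$y, z = st$z,
                           stringsAsFactors = FALSE),
        springs = springs, L = length(res))
}

setMethod("show", "ElasticNetwork", function(object) {
    cat(sprintf(
        "ElasticNetwork: %d residues, %d nodes (%d CB), %d springs\n",
        object@L, nrow(object@nodes), sum(object@nodes$role == "CB"),
        nrow(object@springs)))
})

# Per-spring multiplicative factor (1-eps)^(number of mutated CB endpoints).
springFactors <- function(network, sequence, epsilon) {
    nodes <- network@nodes
    sp <- network@springs
    mutCB <- nodes$role == "CB" &
        sequence[match(nodes$residue, sort(unique(nodes$residue)))] == 1
    nMut <- mutCB[sp$i] + mutCB[sp$j]
    (1 - epsilon)^nMut
}

#' Hessian matrix of an elastic network for a given mutant sequence
#'
#' Standard pairwise-spring Hessian: each spring of constant k contributes
#' the 3x3 block \eqn{k\,\hat d \hat d^T} on the unit bond direction, with
#' signs making the assembled 3N x 3N matrix positive semidefinite (six
#' rigid-body zero modes for a non-collinear 3D network). Mutating residue l
#' (\code{sequence[l] = 1}) multiplies the constant of every spring incident
#' on its CB by \code{(1 - epsilon)}; a spring joining two mutated CBs is
#' multiplied by \code{(1 - epsilon)^2}.
#'
#' @param network an \linkS4class{ElasticNetwork}.
#' @param sequence binary 0/1 vector of length L (default all reference).
#' @param epsilon spring-weakening fraction.
#' @return symmetric 3N x 3N Hessian matrix.
#' @export
enmHessian <- function(network, sequence = NULL, epsilon = 0.2) {
    nodes <- network@nodes
    n <- nrow(nodes)
    if (is.null(sequence)) sequence <- rep(0L, network@L)
    if (length(sequence) != network@L)
        stop("sequence length must equal the number of residues")
    fac <- springFactors(network, sequence, epsilon)
    P <- as.matrix(nodes[, c("x", "y", "z")])
    M <- matrix(0, 3L * n, 3L * n)
    sp <- network@springs
    for (s in seq_len(nrow(sp))) {
        i <- sp$i[s]; j <- sp$j[s]
        d <- P[j, ] - P[i, ]
        d <- d / sqrt(sum(d^2))
        B <- (sp$k[s] * fac[s]) * tcrossprod(d)
        ii <- (3L * (i - 1L) + 1L):(3L * i)
        jj <- (3L * (j - 1L) + 1L):(3L * j)
        M[ii, ii] <- M[ii, ii] + B
        M[jj, jj] <- M[jj, jj] + B
        M[ii, jj] <- M[ii, jj] - B
        M[jj, ii] <- M[jj, ii] - B
    }
    M
}

#' Deformation energy of a mutant elastic network
#'
#' \eqn{E = \frac12 \delta r^T M \delta r \ge 0} for the Hessian of the
#' given mutant sequence.
#'
#' @inheritParams enmHessian
#' @param deformation a \linkS4class{Deformation} (or numeric 3N vector).
#' @return nonnegative deformation energy.
#' @export
deformationEnergy <- function(network, sequence = NULL, epsilon = 0.2,
                              deformation) {
    dr <- if (is(deformation, "Deformation")) deformation@dr
          else as.numeric(deformation)
    if (length(dr) != 3L * nrow(network@nodes))
        stop("deformation dimension must be 3N")
    # per-spring form, equivalent to drT M dr / 2 but O(#springs)
    nodes <- network@nodes
    if (is.null(sequence)) sequence <- rep(0L, network@L)
    fac <- springFactors(network, sequence, epsilon)
    P <- as.matrix(nodes[, c("x", "y", "z")])
    sp <- network@springs
    dI <- matrix(dr, ncol = 3L, byrow = TRUE)
    dvec <- P[sp$j, , drop = FALSE] - P[sp$i, , drop = FALSE]
    dvec <- dvec / sqrt(rowSums(dvec^2))
    stretch <- rowSums((dI[sp$j, , drop = FALSE] -
                        dI[sp$i, , drop = FALSE]) * dvec)
    sum(0.5 * sp$k * fac * stretch^2)
}

#' First-order mutational effects of spring weakening on deformation energy
#'
#' Writes the mutant Hessian as \eqn{M = M^{(0)} + \epsilon M^{(1)} +
#' o(\epsilon)} and defines \eqn{\Delta_l} as the first-order energy change
#' \eqn{\epsilon\,\frac12 \delta r^T M^{(1,l)} \delta r} of a single
#' mutation at residue l (weakening all springs incident on its CB). For
#' this quadratic model the single-mutant energy is exactly linear in
#' epsilon, so the first-order effect coincides with the exact single-mutant
#' energy change, which is returned alongside for validation. A residue
#' without a CB (glycine) has no weakened springs and \eqn{\Delta_l = 0}
#' (flagged with a warning).
#'
#' @param network an \linkS4class{ElasticNetwork}.
#' @param deformation a \linkS4class{Deformation} or 3N vector.
#' @param epsilon spring-weakening fraction (default 0.2).
#' @return a \linkS4class{PerturbationResult}; its \code{delta} carries the
#'   length-L binary-model \linkS4class{MutationalEffects} (all
#'   \eqn{\Delta_l \le 0}).
#' @export
enmMutationalEffects <- function(network, deformation, epsilon = 0.2) {
    dr <- if (is(deformation, "Deformation")) deformation@dr
          else as.numeric(deformation)
    nodes <- network@nodes
    if (length(dr) != 3L * nrow(nodes))
        stop("deformation dimension must be 3N")
    sp <- network@springs
    P <- as.matrix(nodes[, c("x", "y", "z")])
    dI <- matrix(dr, ncol = 3L, byrow = TRUE)
    dvec <- P[sp$j, , drop = FALSE] - P[sp$i, , drop = FALSE]
    dvec <- dvec / sqrt(rowSums(dvec^2))
    stretch <- rowSums((dI[sp$j, , drop = FALSE] -
                        dI[sp$i, , drop = FALSE]) * dvec)
    eSpring <- 0.5 * sp$k * stretch^2     # unperturbed spring energies
    residues <- sort(unique(nodes$residue))
    L <- length(residues)
    cbNode <- match(paste0(residues, ":CB"),
                    paste0(nodes$residue, ":", nodes$role))
    delta <- numeric(L)
    for (l in seq_len(L)) {
        if (is.na(cbNode[l])) next
        touching <- sp$i == cbNode[l] | sp$j == cbNode[l]
        delta[l] <- -epsilon * sum(eSpring[touching])
    }
    if (anyNA(cbNode))
        warning(sprintf("%d residue(s) without CB: their effects are 0",
                        sum(is.na(cbNode))))
    e0 <- sum(eSpring)
    exact <- vapply(seq_len(L), function(l) {
        s <- rep(0L, L); s[l] <- 1L
        deformationEnergy(network, s, epsilon, dr) - e0
    }, numeric(1L))
    new("PerturbationResult",
        delta = mutationalEffects(delta, traitName = "deformation energy",
                                  units = "spring units"),
        epsilon = epsilon, baselineEnergy = e0, exactSingleMutant = exact)
}

#' Superpose two structures and extract the deformation field
#'
#' Least-squares rigid-body (Kabsch) superposition of structure B onto
#' structure A over their shared CA atoms, using bio3d. The deformation is
#' the per-node displacement (B superposed minus A) over all of A's network
#' nodes; nodes of residues missing from B get zero displacement with a
#' warning.
#'
#' @param structureA,structureB data.frames as returned by
#'   \code{\link{readStructurePDB}} or \code{\link{makeToyStructure}};
#'   matching uses the \code{resid} column when present, else
#'   \code{residue}.
#' @return a \linkS4class{Deformation} over the nodes of
#'   \code{structureA}.
#' @export
superposeStructures <- function(structureA, structureB) {
    keyOf <- function(st) {
        if ("resid" %in% colnames(st)) paste(st$resid, st$role)
        else paste(st$residue, st$role)
    }
    kA <- keyOf(structureA); kB <- keyOf(structureB)
    caA <- which(structureA$role == "CA" & kA %in% kB)
    if (length(caA) < 3L)
        stop("need at least 3 shared CA atoms for superposition")
    caB <- match(kA[caA], kB)
    fixed <- as.vector(t(as.matrix(structureA[, c("x", "y", "z")])))
    mobileMat <- as.matrix(structureB[, c("x", "y", "z")])
    mobile <- as.vector(t(mobileMat))
    xyzInd <- function(rows) as.vector(t(outer(3 * (rows - 1), 1:3, "+")))
    fitted <- bio3d::fit.xyz(fixed, mobile,
                             fixed.inds = xyzInd(caA),
                             mobile.inds = xyzInd(caB))
    fittedMat <- matrix(fitted, ncol = 3L, byrow = TRUE)
    shared <- match(kA, kB)
    if (anyNA(shared))
        warning(sprintf("%d node(s) of structure A missing from B: zero ",
                        sum(is.na(shared))), "displacement assigned")
    dr <- matrix(0, nrow(structureA), 3L)
    ok <- !is.na(shared)
    dr[ok, ] <- fittedMat[shared[ok], , drop = FALSE] -
        as.matrix(structureA[ok, c("x", "y", "z")])
    new("Deformation", dr = as.vector(t(dr)),
        source = "superposition B->A")
}

#' Write an elastic network as an edge-list TSV
#'
#' @param network an \linkS4class{ElasticNetwork}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeNetworkTsv <- function(network, path) {
    sp <- network@springs
    nodes <- network@nodes
    df <- data.frame(node_i = sp$i, node_j = sp$j,
                     residue_i = nodes$residue[sp$i],
                     residue_j = nodes$residue[sp$j],
                     role_i = nodes$role[sp$i], role_j = nodes$role[sp$j],
                     rest_length = sp$restLength, k = sp$k)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
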