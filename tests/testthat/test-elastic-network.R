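twoNodeStructure <- function(dist = 5, adjacent = TRUE) {
    data.frame(residue = c(1L, if (adjacent) 2L else 3L),
               role = c("CA", "CA"),
               x = c(0, dist), y = 0, z = 0, stringsAsFactors = FALSE)
}

test_that("network construction follows the cutoff and constant rules", {
    # adjacent backbone CA-CA pair within cutoff: one spring, constant 2
    net <- buildNetwork(twoNodeStructure(5, adjacent = TRUE))
    expect_equal(nrow(net@springs), 1L)
    expect_equal(net@springs$k, 2)
    expect_equal(net@springs$restLength, 5)
    # non-adjacent CA-CA: constant 1
    net2 <- buildNetwork(twoNodeStructure(5, adjacent = FALSE))
    expect_equal(net2@springs$k, 1)
    # beyond the 7.5 A cutoff: no spring at all
    expect_error(buildNetwork(twoNodeStructure(8)), "no springs")
    # three collinear CAs at 0/5/10: only the two 5 A pairs connect
    st3 <- data.frame(residue = c(1L, 5L, 9L), role = "CA",
                      x = c(0, 5, 10), y = 0, z = 0)
    net3 <- buildNetwork(st3)
    expect_equal(nrow(net3@springs), 2L)
    expect_true(all(net3@springs$k == 1))  # non-adjacent residue numbers
    # CA-CB and CB-CB constants
    st4 <- data.frame(residue = c(1L, 1L, 2L, 2L),
                      role = c("CA", "CB", "CA", "CB"),
                      x = c(0, 0, 4, 4), y = c(0, 1.5, 0, 1.5), z = 0)
    net4 <- buildNetwork(st4)
    getK <- function(ri, rj) {
        m <- net4@springs
        nodes <- net4@nodes
        key <- paste(pmin(paste(nodes$residue[m$i], nodes$role[m$i]),
                          paste(nodes$residue[m$j], nodes$role[m$j])),
                     pmax(paste(nodes$residue[m$i], nodes$role[m$i]),
                          paste(nodes$residue[m$j], nodes$role[m$j])))
        m$k[key == paste(pmin(ri, rj), pmax(ri, rj))]
    }
    expect_equal(getK("1 CA", "1 CB"), 1)
    expect_equal(getK("1 CB", "2 CB"), 0.5)
    expect_equal(getK("1 CA", "2 CA"), 2)
})

test_that("the Hessian is PSD with rigid-body zero modes and exact 2-node spectrum", {
    toy <- makeToyStructure(10, "helix", seed = 1)
    net <- buildNetwork(toy$reference)
    M0 <- enmHessian(net, epsilon = 0)
    expect_lt(max(abs(M0 - t(M0))), 1e-12)
    ev <- eigen(M0, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)                       # PSD
    expect_equal(sum(abs(ev) < 1e-8), 6L)           # 3 translations + 3 rotations
    # epsilon = 0: Hessian identical for all sequences
    s <- rep(0L, 10); s[3] <- 1L
    expect_equal(enmHessian(net, s, epsilon = 0), M0)
    # single spring k along x between two nodes: relative mode eigenvalue 2k
    net1 <- buildNetwork(twoNodeStructure(5))
    M1 <- enmHessian(net1)
    ev1 <- eigen(M1, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(ev1[1], 2 * 2)                     # k = 2 (adjacent CA-CA)
    expect_equal(sum(abs(ev1) < 1e-12), 5L)         # all other modes flat
})

test_that("deformation energy matches closed forms and the Hessian quadratic form", {
    net1 <- buildNetwork(twoNodeStructure(5))       # one spring, k = 2
    # stretching the bond by u costs k u^2 / 2
    u <- 0.3
    dr <- c(0, 0, 0, u, 0, 0)
    expect_equal(deformationEnergy(net1, deformation = dr), 2 * u^2 / 2)
    # rigid translation and zero displacement cost nothing
    expect_equal(deformationEnergy(net1, deformation = rep(c(1, 2, 3), 2)), 0)
    expect_equal(deformationEnergy(net1, deformation = rep(0, 6)), 0)
    # general case: per-spring accumulation equals dr' M dr / 2
    toy <- makeToyStructure(8, "helix", seed = 2)
    net <- buildNetwork(toy$reference)
    def <- superposeStructures(toy$reference, toy$displaced)
    s <- rep(0L, 8); s[c(2, 5)] <- 1L
    e1 <- deformationEnergy(net, s, 0.2, def)
    M <- enmHessian(net, s, 0.2)
    expect_equal(e1, 0.5 * sum(def@dr * (M %*% def@dr)), tolerance = 1e-12)
})

test_that("first-order mutational effects match exact single-mutant energetics", {
    toy <- makeToyStructure(15, "helix", seed = 3)
    net <- buildNetwork(toy$reference)
    def <- superposeStructures(toy$reference, toy$displaced)
    pr <- enmMutationalEffects(net, def, epsilon = 0.2)
    d <- deltaVector(pr@delta)
    # weakening springs cannot raise a fixed-deformation quadratic energy
    expect_true(all(d <= 0))
    # single-mutant energies are exactly linear in epsilon here
    expect_equal(d, pr@exactSingleMutant, tolerance = 1e-12)
    # finite-difference oracle at tiny epsilon
    eps <- 1e-6
    fd <- vapply(seq_len(15), function(l) {
        s <- rep(0L, 15); s[l] <- 1L
        (deformationEnergy(net, s, eps, def) - pr@baselineEnergy) / eps
    }, numeric(1))
    expect_equal(d / 0.2, fd, tolerance = 1e-6)
    # the largest effect sits in or immediately beside the displaced block
    # (boundary springs load the flanking residues too)
    nearDisplaced <- unique(pmax(1, pmin(15, c(toy$displacedResidues - 1,
                                               toy$displacedResidues,
                                               toy$displacedResidues + 1))))
    expect_true(which.min(d) %in% nearDisplaced)
})

test_that("double mutants are additive unless the mutated CBs share a spring", {
    toy <- makeToyStructure(20, "helix", seed = 4)
    net <- buildNetwork(toy$reference)
    def <- superposeStructures(toy$reference, toy$displaced)
    eps <- 0.2
    pr <- enmMutationalEffects(net, def, epsilon = eps)
    d <- deltaVector(pr@delta)
    nodes <- net@nodes
    cb <- match(paste0(1:20, ":CB"), paste0(nodes$residue, ":", nodes$role))
    sp <- net@springs
    sharedSpringEnergy <- function(l, m) {
        hit <- (sp$i == cb[l] & sp$j == cb[m]) |
               (sp$i == cb[m] & sp$j == cb[l])
        if (!any(hit)) return(NA_real_)
        # unperturbed energy of the shared spring
        P <- as.matrix(nodes[, c("x", "y", "z")])
        dI <- matrix(def@dr, ncol = 3, byrow = TRUE)
        dv <- P[sp$j[hit], ] - P[sp$i[hit], ]
        dv <- dv / sqrt(sum(dv^2))
        0.5 * sp$k[hit] * sum((dI[sp$j[hit], ] - dI[sp$i[hit], ]) * dv)^2
    }
    e0 <- pr@baselineEnergy
    nAdd <- 0L; nShared <- 0L
    for (l in 1:19) for (m in (l + 1):20) {
        s <- rep(0L, 20); s[c(l, m)] <- 1L
        exact <- deformationEnergy(net, s, eps, def) - e0
        eShared <- sharedSpringEnergy(l, m)
        if (is.na(eShared)) {
            # no shared CB-CB spring: exactly additive
            expect_lt(abs(exact - (d[l] + d[m])), 1e-10)
            nAdd <- nAdd + 1L
        } else {
            # deviation is exactly the (1-eps)^2 cross term of the shared
            # spring: eps^2 * its unperturbed energy
            expect_lt(abs(exact - (d[l] + d[m]) - eps^2 * eShared), 1e-12)
            nShared <- nShared + 1L
        }
    }
    expect_gt(nAdd, 0L); expect_gt(nShared, 0L)
})

test_that("superposition removes rigid motion and handles missing residues", {
    toy <- makeToyStructure(12, "helix", seed = 5)
    st <- toy$reference
    # rotated + translated copy superposes to zero deformation
    th <- 0.7
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    P <- as.matrix(st[, c("x", "y", "z")])
    stRot <- st
    stRot[, c("x", "y", "z")] <- P %*% t(R) +
        matrix(c(3, -1, 2), nrow(P), 3, byrow = TRUE)
    def <- superposeStructures(st, stRot)
    expect_lt(max(abs(def@dr)), 1e-9)
    # identical structures: zero deformation
    expect_lt(max(abs(superposeStructures(st, st)@dr)), 1e-12)
    # missing residues in B get zero displacement, with a warning
    stPart <- toy$displaced[toy$displaced$residue <= 10, ]
    expect_warning(defP <- superposeStructures(st, stPart), "missing")
    drM <- matrix(defP@dr, ncol = 3, byrow = TRUE)
    expect_true(all(drM[st$residue > 10, ] == 0))
    # fewer than 3 shared residues is an error
    expect_error(superposeStructures(st, st[st$residue <= 2, ]), "at least 3")
})

test_that("toy structures round-trip through PDB and bio3d parsing", {
    toy <- makeToyStructure(6, "helix", seed = 6)
    p <- withr::local_tempfile(fileext = ".pdb")
    writeToyPDB(toy$reference, p)
    st <- readStructurePDB(p)
    expect_equal(nrow(st), 12L)
    expect_equal(st$role, toy$reference$role)
    expect_equal(st$x, toy$reference$x, tolerance = 1e-3)
    expect_equal(st$residue, toy$reference$residue)
})
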