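test_that("PCA of the worked example isolates the effect direction", {
    sp <- pcaSpectrum(covariance(workedExampleEnsemble()))
    expect_equal(eigenValues(sp), c(0.5, 0.25, 0), tolerance = 1e-12)
    # last PC proportional to (1, -1, 0), first to (1, 1, 0)
    expect_equal(abs(eigenVectors(sp)[, 3]), c(1, 1, 0) / sqrt(2))
    expect_equal(eigenVectors(sp)[1, 3] * eigenVectors(sp)[2, 3], -0.5)
    expect_equal(eigenVectors(sp)[, 1], c(1, 1, 0) / sqrt(2))
    # identity covariance: flat spectrum
    spI <- pcaSpectrum(diag(4))
    expect_equal(eigenValues(spI), rep(1, 4))
})

test_that("eigendecomposition agrees with an independent SVD oracle", {
    C <- randomPSD(5, seed = 61)
    sp <- pcaSpectrum(C)
    sv <- svd(C)          # independent route for a PSD matrix
    expect_equal(eigenValues(sp), sv$d, tolerance = 1e-8)
    for (j in 1:5)
        expect_equal(abs(eigenVectors(sp)[, j]), abs(sv$u[, j]),
                     tolerance = 1e-8)
    # eigen-equation residual and orthonormality
    for (j in 1:5)
        expect_lt(max(abs(C %*% eigenVectors(sp)[, j] -
                          eigenValues(sp)[j] * eigenVectors(sp)[, j])),
                  1e-8 * norm(C, "2"))
    expect_error(pcaSpectrum(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("ICOD recovers a planted outer-product coupling", {
    # construct C by inverting I + kappa * delta delta^T: the off-diagonal
    # of C^-1 is exactly kappa delta_l delta_l', so the top ICOD eigenvector
    # must recover delta
    set.seed(71)
    L <- 50
    delta <- rnorm(L); delta <- delta / sqrt(sum(delta^2))
    Cinv <- diag(L) + 5 * tcrossprod(delta)
    C <- solve(Cinv)
    sp <- icodSpectrum(C)
    expect_gt(recovery(eigenVectors(sp)[, 1], delta), 0.99)
    # diagonal covariance: no couplings at all
    spD <- icodSpectrum(diag(c(0.1, 0.2, 0.15)))
    expect_equal(eigenValues(spD), rep(0, 3))
    # singular covariance names the pseudocount remedy
    expect_error(icodSpectrum(matrix(c(1, 1, 1, 1), 2)), "pseudocount")
})

test_that("the inverse covariance follows the small-coupling law", {
    d <- makeDelta(50, 10, seed = 81)
    sel <- selectionModel("gaussian", d, gamma = 0)   # kappa sum(d^2) = 10
    ens <- sampleEnsemble(d, sel, 50000, seed = 82)
    C <- covarianceMatrix(covariance(ens, lambda = 0.01))
    Cinv <- solve(C)
    pred <- sel@kappa * tcrossprod(deltaVector(d))
    off <- upper.tri(Cinv)
    expect_gt(cor(Cinv[off], pred[off]), 0.9)
})

test_that("Recovery matches its closed-form examples and invariances", {
    d <- workedExampleDelta()
    expect_equal(recovery(c(1, 1, 0) / sqrt(2), d), 1)
    expect_equal(recovery(c(1, -1, 0), d), 1)
    expect_equal(recovery(c(1, 0, 0), d), 1 / sqrt(2))
    expect_equal(recovery(deltaVector(d), d), 1)    # parallel vectors
    set.seed(91)
    for (i in 1:20) {
        v <- rnorm(30); dd <- rnorm(30)
        r <- recovery(v, dd)
        expect_gte(r, 0); expect_lte(r, 1)
        # invariant under rescaling and per-site sign flips
        signs <- sample(c(-1, 1), 30, replace = TRUE)
        expect_equal(recovery(3.7 * signs * v, dd), r)
        expect_equal(recovery(v, -2 * dd), r)
    }
    expect_error(recovery(rep(0, 3), d), "zero vector")
})

test_that("the random-expectation baseline matches sphere marginals", {
    # single nonzero effect: expectation is the exact sphere marginal E|nu_1|
    for (L in c(10, 100)) {
        d <- c(1, rep(0, L - 1))
        re <- recoveryRandomExpectation(d, nDraws = 40000, seed = 5)
        expect_equal(re$estimate, sphereAbsMarginal(L), tolerance = 0.02)
    }
    # uniform effects at L = 100: MC and closed form within 2%
    dU <- rep(1, 100)
    reU <- recoveryRandomExpectation(dU, nDraws = 40000, seed = 6)
    expect_equal(reU$estimate, reU$closedForm, tolerance = 0.02)
    # output strictly inside (0, 1)
    d <- makeDelta(40, 8, seed = 7)
    re <- recoveryRandomExpectation(d, seed = 8)
    expect_gt(re$estimate, 0); expect_lt(re$estimate, 1)
})

test_that("SCA reduces to |C| for flat conservation and needs interior frequencies", {
    set.seed(101)
    X <- matrix(rbinom(600, 1, 0.5), 100, 6)
    ens <- weightedEnsemble(X)
    cov <- covariance(ens, lambda = 0.01)
    # replace fractions by exactly 1/4 (phi = |log 3| for background 0.5)
    # -> spectrum equals that of |phi C phi| with constant phi: same
    # eigenvectors as |C|
    phiConst <- new("CovarianceResult", Cmat = covarianceMatrix(cov),
                    mutantFractions = rep(0.25, 6), pseudocount = 0.01,
                    provenance = list())
    spectrum <- scaSpectrum(phiConst)
    direct <- eigen(abs(covarianceMatrix(cov)) * abs(log(1 / 3))^2,
                    symmetric = TRUE)
    expect_equal(eigenValues(spectrum), direct$values, tolerance = 1e-10)
    # frequencies at 0/1 without pseudocount are rejected with guidance
    bad <- covariance(weightedEnsemble(cbind(rep(1L, 4), rbinom(4, 1, 0.5))))
    expect_error(scaSpectrum(bad), "pseudocount")
})

test_that("SCA succeeds under biased selection but breaks down unbiased", {
    d <- makeDelta(100, 20, seed = 111)
    re <- recoveryRandomExpectation(d, seed = 112)$estimate
    recs <- sapply(c(0, 2), function(g) {
        sel <- selectionModel("gaussian", d, gamma = g)
        cov <- covariance(sampleEnsemble(d, sel, 1e5, seed = 113),
                          lambda = 0.01)
        c(sca = recovery(scaSectorEstimate(scaSpectrum(cov)), d),
          icod = recovery(eigenVectors(icodSpectrum(cov))[, 1], d))
    })
    # biased: SCA informative, above the random baseline
    expect_gt(recs["sca", 2], re)
    # unbiased: SCA near random while ICOD recovers the sector
    expect_lt(recs["sca", 1], 2 * re)
    expect_gt(recs["icod", 1], 0.9)
    # ICOD robust in both regimes
    expect_gt(recs["icod", 2], 0.9)
})

test_that("ICA disentangles mixed sector vectors", {
    # constructed mixing oracle: two sparse orthogonal sectors rotated 45deg
    set.seed(121)
    L <- 60
    d1 <- d2 <- rep(0, L)
    d1[1:12] <- rnorm(12, 0, 5); d2[31:42] <- rnorm(12, 0, 5)
    v1 <- d1 / sqrt(sum(d1^2)); v2 <- d2 / sqrt(sum(d2^2))
    mixed <- cbind((v1 + v2) / sqrt(2), (v1 - v2) / sqrt(2))
    sp <- new("SpectralResult", values = c(2, 1), vectors = mixed,
              matrixKind = "icod", source = list())
    comps <- icaDisentangle(sp, nComponents = 2, seed = 3)
    bestFor <- function(d) max(vapply(comps, recovery, numeric(1), delta = d))
    expect_gt(bestFor(d1), 0.95)
    expect_gt(bestFor(d2), 0.95)
    # determinism given the seed
    comps2 <- icaDisentangle(sp, nComponents = 2, seed = 3)
    expect_identical(comps, comps2)
    # nComponents = 1 returns the top eigenvector unchanged
    expect_equal(icaDisentangle(sp, nComponents = 1)[[1]], mixed[, 1])
    expect_error(icaDisentangle(sp, nComponents = 5), "exceeds")
})

test_that("two selected traits yield two ICOD outliers that ICA separates", {
    pair <- makeDeltaPair(100, 20, overlapFraction = 0, seed = 131)
    msel <- multiTraitSelection(
        pair, lapply(pair, function(d) selectionModel("gaussian", d,
                                                      gamma = 0)))
    ens <- sampleEnsemble(pair[[1]], msel, 1e5, seed = 132)
    sp <- icodSpectrum(covariance(ens, lambda = 0.01))
    expect_equal(countOutliers(eigenValues(sp)), 2L)
    comps <- icaDisentangle(sp, seed = 133)   # default count = outliers
    expect_equal(length(comps), 2L)
    for (d in pair)
        expect_gt(max(vapply(comps, recovery, numeric(1), delta = d)), 0.8)
    # a single selected trait yields a single dominant outlier
    d1 <- makeDelta(100, 20, seed = 134)
    sp1 <- icodSpectrum(covariance(
        sampleEnsemble(d1, selectionModel("gaussian", d1, gamma = 0),
                       5e4, seed = 135), lambda = 0.01))
    expect_equal(countOutliers(eigenValues(sp1)), 1L)
})

test_that("PCA and ICOD agree for unbiased selection; ICOD wins under bias", {
    d <- makeDelta(60, 12, seed = 141)
    # unbiased: last PC of C and first ICOD eigenvector both recover delta
    cov0 <- covariance(sampleEnsemble(
        d, selectionModel("gaussian", d, gamma = 0), 5e4, seed = 142),
        lambda = 0.01)
    pcaRec <- recovery(eigenVectors(pcaSpectrum(cov0))[, 60], d)
    icodRec <- recovery(eigenVectors(icodSpectrum(cov0))[, 1], d)
    expect_gt(pcaRec, 0.9)
    expect_gt(icodRec, 0.9)
    expect_lt(abs(pcaRec - icodRec), 0.05)
    # strongly biased selection drives conservation that disrupts the last
    # PC but not ICOD
    cov3 <- covariance(sampleEnsemble(
        d, selectionModel("gaussian", d, gamma = 3), 1e5, seed = 143),
        lambda = 0.01)
    expect_gt(recovery(eigenVectors(icodSpectrum(cov3))[, 1], d),
              recovery(eigenVectors(pcaSpectrum(cov3))[, 60], d))
})
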