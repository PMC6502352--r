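toyMsa <- function() {
    # 4 sequences x 5 columns; column 4 is 50% gaps, column 5 conserved
    c("ACD-A",
      "ACDEA",
      "AADEA",
      "CAD-A")
}

test_that("alignment encoding filters gappy columns and fixes the gauge", {
    enc <- encodeAlignment(toyMsa(), gapThreshold = 0.15)
    # column 4 has 50% gaps and is removed
    expect_equal(enc@retainedSites, c(1L, 2L, 3L, 5L))
    expect_equal(enc@gapFrequency[4], 0.5)
    # consensus gauge per retained column: A, C/A tie -> A, D, A
    states <- enc@states
    expect_equal(states[enc@gauge], c("A", "A", "D", "A"))
    # hand-checked encoding of the (site, state) matrix
    expect_equal(states[enc@sequences[1, ]], c("A", "C", "D", "A"))
    expect_equal(states[enc@sequences[4, ]], c("C", "A", "D", "A"))
    # an alignment of identical sequences is flagged as fully conserved
    expect_warning(encodeAlignment(rep("ACDE", 3), gapThreshold = 0.5),
                   "conserved")
    expect_error(encodeAlignment(character(0)), "empty")
    expect_error(encodeAlignment(c("AC", "ACD")), "equal length")
})

test_that("a reference gauge can be supplied explicitly", {
    enc <- encodeAlignment(toyMsa(), gauge = "reference",
                           reference = "AADAA")
    expect_equal(enc@states[enc@gauge], c("A", "A", "D", "A"))
    expect_error(encodeAlignment(toyMsa(), gauge = "reference"),
                 "reference")
})

test_that("the fully mixed limit reproduces uniform-independence structure", {
    enc <- encodeAlignment(toyMsa(), gapThreshold = 0.6)
    q <- length(enc@states)
    mc <- suppressWarnings(multistateCovariance(enc, lambda = 1 - 1e-12))
    expect_equal(unname(mc@frequencies[1, ]), rep(1 / q, q),
                 tolerance = 1e-9)
    # off-site blocks vanish (independence), within-site blocks are the
    # multinomial covariance of the uniform distribution
    sm <- mc@siteMap
    b1 <- sm$row[sm$site == 1]; b2 <- sm$row[sm$site == 2]
    expect_lt(max(abs(mc@Cmat[b1, b2])), 1e-9)
    diagBlock <- mc@Cmat[b1, b1]
    expect_equal(diag(diagBlock), rep(1 / q - 1 / q^2, q - 1),
                 tolerance = 1e-9)
    expect_equal(diagBlock[1, 2], -1 / q^2, tolerance = 1e-9)
})

test_that("the q = 2 multistate pipeline equals the binary pipeline exactly", {
    d <- makeDelta(12, 4, seed = 151)
    sel <- selectionModel("gaussian", d, gamma = 0.3)
    ens <- sampleEnsemble(d, sel, 4000, seed = 152)
    for (lam in c(0, 0.02)) {
        cb <- covariance(ens, lambda = lam)
        cm <- multistateCovariance(ens, lambda = lam)
        expect_lt(max(abs(covarianceMatrix(cb) - cm@Cmat)), 1e-12)
        if (lam > 0) {
            icb <- icodSpectrum(cb)
            icm <- icodMultistate(cm)
            expect_lt(max(abs(eigenValues(icb) -
                              eigenValues(icm@icodSpectrum))), 1e-8)
            # 1x1 blocks: the compressed matrix is |ICOD matrix|
            expect_equal(icm@compressed@fmat, abs(icm@icodMatrix))
        }
    }
})

test_that("Frobenius compression matches hand-computed block norms", {
    # site-resolved matrix with one known off-diagonal block
    d <- makeMultistateDelta(4, 3, 2, seed = 161)
    sel <- selectionModel("gaussian", d, gamma = 0)
    ens <- sampleEnsemble(d, sel, 3000, seed = 162)
    mc <- multistateCovariance(ens, lambda = 0.05)
    res <- icodMultistate(mc)
    sm <- mc@siteMap
    b1 <- sm$row[sm$site == 1]; b3 <- sm$row[sm$site == 3]
    expect_equal(res@compressed@fmat[1, 3],
                 sqrt(sum(res@icodMatrix[b1, b3]^2)))
    expect_equal(diag(res@compressed@fmat), rep(0, 4))
    # all-zero couplings compress to the zero matrix
    zero <- matrix(0, 6, 6)
    Lp <- 3
    expect_equal({
        Fm <- matrix(0, Lp, Lp)
        for (a in 1:2) for (b in (a + 1):3)
            Fm[a, b] <- Fm[b, a] <-
                sqrt(sum(zero[(2 * a - 1):(2 * a), (2 * b - 1):(2 * b)]^2))
        Fm
    }, matrix(0, 3, 3))
})

test_that("q-state ICOD recovers a planted q = 21-style sector", {
    q <- 8
    d <- makeMultistateDelta(25, q, 5, seed = 171)
    sel <- selectionModel("gaussian", d, gamma = 0)
    ens <- sampleEnsemble(d, sel, 4e4, seed = 172)
    mc <- multistateCovariance(ens, lambda = 0.01)
    res <- icodMultistate(mc)
    # top eigenvector of the uncompressed ICOD matrix recovers the
    # flattened effect matrix
    flat <- as.vector(t(effectsMatrix(d)[, -1]))
    expect_gt(recovery(eigenVectors(res@icodSpectrum)[, 1], flat), 0.9)
    # one dominant compressed eigenvalue; sector sites rank first
    ev <- eigenValues(res@spectrum)
    expect_gt(ev[1], 2 * abs(ev[2]))
    expect_setequal(res@ranking[1:5], sectorSites(d))
})

test_that("site scores are stable under gauge change and pseudocounts", {
    d <- makeMultistateDelta(20, 6, 10, sectorScale = 5, backgroundScale = 2,
                             seed = 181)
    sel <- selectionModel("gaussian", d, gamma = 0.5)
    ens <- sampleEnsemble(d, sel, 5e4, seed = 182)
    mcR <- multistateCovariance(ens, lambda = 0.02)
    cons <- apply(mcR@frequencies, 1, which.max)
    mcC <- multistateCovariance(ens, lambda = 0.02, gauge = cons)
    sR <- icodMultistate(mcR); sC <- icodMultistate(mcC)
    nSec <- length(sectorSites(d))
    # the identified sector (top-ranked set) is essentially unchanged by
    # the gauge: at most one site swaps in or out
    expect_gte(length(intersect(sR@ranking[1:nSec], sC@ranking[1:nSec])),
               nSec - 1L)
    # sector-site ranks move by a handful of positions at most
    rkR <- match(sectorSites(d), sR@ranking)
    rkC <- match(sectorSites(d), sC@ranking)
    expect_lte(max(abs(rkR - rkC)), 5)
    # ranking essentially unchanged across pseudocounts in [0.01, 0.05]
    s1 <- icodMultistate(multistateCovariance(ens, lambda = 0.01))
    s5 <- icodMultistate(multistateCovariance(ens, lambda = 0.05))
    expect_gte(cor(s1@siteScores, s5@siteScores, method = "spearman"), 0.95)
})

test_that("conservation scores are KL divergences with the known extremes", {
    q <- 21
    # uniform site scores zero
    expect_equal(conservationScore(matrix(1 / q, 1, q))[1], 0)
    # fully conserved site scores log(21)
    p <- matrix(0, 1, q); p[1, 3] <- 1
    expect_equal(conservationScore(p)[1], log(21))
    # mixing toward uniform strictly decreases the score
    mix <- function(a) (1 - a) * p + a / q
    scores <- sapply(c(0, 0.2, 0.5, 0.9), function(a)
        conservationScore(mix(a))[1])
    expect_true(all(diff(scores) < 0))
})

test_that("multistate SCA produces a site-level spectrum with a leading sector", {
    d <- makeMultistateDelta(20, 5, 4, seed = 191)
    sel <- selectionModel("gaussian", d, gamma = 1.5)   # conservation-driven
    ens <- sampleEnsemble(d, sel, 3e4, seed = 192)
    mc <- multistateCovariance(ens, lambda = 0.02)
    sp <- scaSpectrumMultistate(mc)
    expect_equal(length(eigenValues(sp)), 20L)
    est <- sqrt(abs(eigenVectors(sp)[, 1]))
    top <- order(est, decreasing = TRUE)[1:4]
    expect_gte(length(intersect(top, sectorSites(d))), 3L)
})
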