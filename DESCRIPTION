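Package: icod
Title: Functional Protein Sector Detection by Inverse Covariance Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models natural selection acting on additive protein traits and
    detects the resulting functional sectors from sequence data. Provides an
    elastic-network model mapping the energetics of a conformational change to
    per-residue mutational effects, Boltzmann-weighted sequence-ensemble
    simulators (exhaustive enumeration, importance sampling, Metropolis MCMC),
    weighted covariance estimation, principal component analysis, the Inverse
    Covariance Off-Diagonal (ICOD) method, a Statistical Coupling Analysis
    (SCA) comparator, independent component analysis for multiple selected
    traits, the Recovery statistic with its random baseline, and a 21-state
    extension for amino-acid alignments with pseudocounts, gap filtering and
    Frobenius-norm compression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Matrix,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, SequenceAnalysis, StructuralPrediction, Proteomics
RoxygenNote: 7.3.3
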