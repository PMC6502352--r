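# icod

Detection of **functional protein sectors** — groups of collectively
correlated amino-acid positions — from sequence data, via inverse
covariance analysis.

## The scientific problem

Statistical analyses of large protein alignments reveal sectors of
coevolving residues. A simple physical mechanism can create them: suppose a
scalar protein property (binding affinity, stability, the elastic energy of
a functional conformational change, ...) is an **additive trait**,

T(α) = Σ_l Δ_l(α_l),

where Δ_l(α_l) is the effect on the trait of the amino acid at site *l*
relative to a reference sequence. If natural selection favors particular
values of *T* — for example through a Gaussian fitness
w = −(κ/2)(T − T\*)², with sequences weighted by exp(w) — the
*nonlinearity* of selection couples sites even though the trait itself is
additive (global epistasis). The highly weighted sequences concentrate near
a plane perpendicular to the effect vector Δ, so Δ becomes a
*small-variance* direction of the sequence covariance matrix
C_ll' = ⟨S_l S_l'⟩\* − ⟨S_l⟩\*⟨S_l'⟩\*.

The package implements the **ICOD** (Inverse Covariance Off-Diagonal)
estimator: in the small-coupling regime

C⁻¹_ll' ≈ (1 − δ_ll') κ Δ_l Δ_l' + δ_ll' (1/P_l + 1/(1 − P_l)),

so after zeroing the conservation-dominated diagonal of C⁻¹, the remaining
matrix is essentially the outer product Δ⊗Δ and its **first eigenvector
recovers Δ** — robustly, even under the strongly biased selection that
breaks plain PCA. Agreement between an inferred mode ν and Δ is quantified
by

Recovery = Σ_l |ν_l Δ_l| / (‖ν‖·‖Δ‖) ∈ (0, 1],

with a random-baseline expectation of √(2/(πL))·Σ|Δ_l|/‖Δ‖ for L ≫ 1.

What is in the package:

* **Trait and selection models** — Gaussian, quartic, rectangular-window
  and threshold selection acting on additive traits, single or multiple
  (`selectionModel()`, `multiTraitSelection()`, `fitness()`).
* **Elastic-network module** — a Cα/Cβ spring network built from PDB
  coordinates (cutoff 7.5 Å, constants 2/1/0.5), deformation energies
  ½δrᵀMδr of a conformational change, and the per-residue mutational-effect
  vector from first-order perturbation of spring weakening
  (`buildNetwork()`, `enmMutationalEffects()`, `superposeStructures()`).
* **Ensemble simulators** — exact enumeration, importance sampling and
  Metropolis MCMC of Boltzmann-selected sequence ensembles, with weighted
  covariance estimation and pseudocounts (`sampleEnsemble()`,
  `covariance()`).
* **Spectral detectors** — PCA, ICOD, an SCA (Statistical Coupling
  Analysis) comparator, fixed-point ICA for disentangling multiple selected
  traits, and the Recovery statistic with its random baseline
  (`icodSpectrum()`, `scaSpectrum()`, `icaDisentangle()`, `recovery()`).
* **21-state extension** — one-hot encoding of amino-acid alignments with
  gap filtering and gauge choice, q-state covariance with pseudocounts, and
  Frobenius-norm compression of the ICOD matrix to per-site scores
  (`encodeAlignment()`, `multistateCovariance()`, `icodMultistate()`).
* **Synthetic generators** — sector-structured effect vectors (including
  overlapping pairs and q-state matrices) and toy CA/CB structures, so the
  whole pipeline is testable without downloads (`makeDelta()`,
  `makeToyStructure()`).

## Worked example

```r
library(icod)

delta <- makeDelta(L = 100, nSectorSites = 20, seed = 42)  # planted sector
sel   <- selectionModel("gaussian", delta, gamma = 0)      # unbiased window
ens   <- sampleEnsemble(delta, sel, nSamples = 1e5, seed = 43)
ens
#> WeightedEnsemble: 100000 sequences of length 100 (binary), ESS 69568.6
#>   sampler: importance

sp <- icodSpectrum(covariance(ens, lambda = 0.01))
sp
#> SpectralResult (icod): 100 modes, eigenvalues [-1.39 .. 8.894]

recoveryReport(sp, delta, seed = 44)
#> RecoveryReport: best mode 1 (Recovery 0.9989), random expectation 0.4231
```

The single outlier eigenvalue (8.894 against a bulk of ±0.27) is the
signature of one selected trait; the associated eigenvector matches the
planted effect vector with Recovery 0.9989, far above the 0.4231 random
baseline. `runPipeline()` composes the same stages end-to-end and writes
eigen-spectra, Recovery reports and a hash-stamped resolved configuration;
`inst/scripts/icod-cli.R` exposes the stages as shell subcommands
(`synth-delta`, `sample`, `cov`, `pca`, `icod`, `sca`, `recover`,
`icod21`, `pipeline`).

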