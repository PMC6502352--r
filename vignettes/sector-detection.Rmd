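---
title: "Detecting functional sectors from selected sequence ensembles"
author: "icod package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional sectors from selected sequence ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icod)
```

## The model

The package studies a minimal physical mechanism for protein sectors. A
scalar trait is assumed additive over sites,
$T(\alpha) = \sum_{l=1}^{L} \Delta_l(\alpha_l)$, with mutational effects
$\Delta_l$ measured against a reference sequence
($\Delta_l(\alpha_l^0) = 0$: the *gauge*). Selection acts on the trait, not
on individual sites, through a fitness $w(T)$, and sequences are drawn from
the Boltzmann distribution $P(\alpha) \propto e^{w(\alpha)}$. Because $w$
is a nonlinear function of $T$, selection couples sites — global
(nonspecific) epistasis — even though the trait itself carries no pairwise
terms. The set of sites with dominant $|\Delta_l|$ is the *functional
sector*.

Four selection forms are implemented (`selectionModel()`):

| form | fitness | parameters |
|---|---|---|
| gaussian | $-\tfrac{\kappa}{2}(T-T^*)^2$ | strength $\kappa$, center $T^*$ |
| quartic | $-\tfrac{\kappa_4}{2}(T-T^*)^4$ | strength $\kappa_4$, center $T^*$ |
| rectangular | $0$ iff $|T-T^*|\le h$ (else $-\infty$) | center, half-width $h$ |
| threshold | $0$ iff $T \ge T_t$ (else $-\infty$) | threshold $T_t$ |

An infinite fitness penalty is represented by a `-Inf` sentinel whose
exponential is exactly 0, never `NaN`. Window centers may be given as the
dimensionless *relative bias* $\gamma = (T^* - \langle T\rangle)/
\mathrm{sd}(T)$, with moments taken under the unselected ensemble (all
states equally likely per site); `relativeBias()` recomputes $\gamma$ from
any stored model. Selection on $N$ traits simultaneously sums per-trait
Gaussian terms (`multiTraitSelection()`).

### Default parameters

* $\kappa = 10/\sum_l \Delta_l^2$ — the selection window then scales with
  the width of the unselected trait distribution
  ($\kappa\,\mathrm{var}(T) = 2.5$ for a binary trait), keeping the
  strong-coupling condition $\kappa \sum_l \Delta_l^2 \gg 1$ satisfied
  while leaving the ensemble diverse. Applied at construction time when a
  `MutationalEffects` object is supplied.
* $\kappa_4 = \kappa^2/2$ — chosen so the quartic window loses its first
  e-fold of weight at the same distance $|T - T^*| = \sqrt{2/\kappa}$ as
  the default Gaussian window. No published value exists for this
  constant, so the package declares its own and records the rule in every
  serialized configuration.
* Rectangular bounds are inclusive, and a half-width of zero is allowed:
  it selects $T = T^*$ exactly, which is what the length-3 worked example
  in the test suite uses.

## The elastic-network trait

As a concrete additive trait the package builds an anisotropic Cα/Cβ
elastic network (`buildNetwork()`): every pair of carbons within
$d_c = 7.5$ Å is joined by a harmonic spring, with constants 2
(backbone-adjacent Cα–Cα), 1 (other Cα–Cα and Cα–Cβ) and 0.5 (Cβ–Cβ).
The energetic cost of a conformational change $\delta r$ — obtained by
Kabsch superposition of a second structure onto the reference
(`superposeStructures()`, shared Cα atoms, bio3d) — is the quadratic form
$E = \tfrac12 \delta r^{T} M \delta r$ of the network Hessian. A "mutation"
at residue $l$ weakens every spring incident on its Cβ by a fraction
$\epsilon$ (default 0.2); first-order perturbation in $\epsilon$ gives the
per-residue effect $\Delta_l = \epsilon\,\tfrac12 \delta r^T M^{(1,l)}
\delta r \le 0$ (`enmMutationalEffects()`).

Numerical facts the test suite verifies exactly: the Hessian is positive
semidefinite with six rigid-body zero modes; for a fixed deformation the
single-mutant energy is *exactly* linear in $\epsilon$, so $\Delta_l$
coincides with the exact single-mutant energy change; double mutants are
exactly additive unless the two Cβs share a spring, in which case the
deviation is precisely the $\epsilon^2$ cross term of that spring's
$(1-\epsilon)^2$ factor.

Design choices where the construction was open: the cutoff is evaluated on
the reference structure only (the expansion is around one equilibrium);
residues without a Cβ (glycine) contribute $\Delta_l = 0$ with a warning;
residues matched between structures by author numbering + chain + insertion
code, with the highest-occupancy alternate conformer; residues missing from
the second structure enter $\delta r$ as zero displacement with a warning.

## Ensembles and covariance

Three samplers target $P(\alpha)$:

* `enumerateEnsemble()` — exact Boltzmann weights over all $2^L$ binary
  sequences ($L \le 20$); the oracle for everything else.
* importance sampling — uniform proposals (each state equally likely per
  site), weights $\propto e^{w}$; the workhorse, with the effective sample
  size $1/\sum_i w_i^2$ recorded and a provenance flag below ESS 50.
* Metropolis MCMC — single-site moves, burn-in $10L$ sweeps, one sample
  per $L$ flips, uniform weights; the schedule and acceptance rate are
  recorded. Hard selection windows get a feasible start by resampling.

`covariance()` uses the plain weighted second central moment (the
ensemble-average definition; no small-sample correction). The pseudocount
$\Lambda$ mixes one- and two-site frequencies with the uniform
independent-site distribution — $\tilde f_1 = (1-\Lambda) f_1 + \Lambda/q$,
$\tilde f_2 = (1-\Lambda) f_2 + \Lambda/q^2$ off-site, within-site pair
frequencies staying multinomial — which keeps the pseudocounted matrix a
true covariance (positive semidefinite). Defaults: $\Lambda = 0$ for exact
enumeration, 0.01 for synthetic sampled data, 0.02 for real alignments.

## Detectors

**PCA** (`pcaSpectrum()`): under a narrow selection window the weighted
sequences concentrate near a plane orthogonal to $\Delta$, so the *last*
principal component carries the sector. Strongly biased selection
($\langle S_l \rangle_* \to 1$ at some sites) breaks this: near-conserved
sites dominate the smallest-variance direction.

**ICOD** (`icodSpectrum()`): invert $C$, zero the diagonal (dominated by
single-site conservation $1/P_l + 1/(1-P_l)$), and take the *first*
eigenvector of the remainder, which in the small-coupling regime is the
outer product $\kappa \Delta\Delta^T$. This is robust across the bias
range; the test suite checks the small-coupling law directly (Pearson
$r \ge 0.9$ between off-diagonal $C^{-1}$ entries and
$\kappa\Delta_l\Delta_{l'}$ at $L = 50$, $\kappa\sum\Delta^2 = 10$).

**SCA** (`scaSpectrum()`): the conservation-reweighted absolute covariance
$|\phi_l C_{ll'} \phi_{l'}|$ with the binary weight $\phi_l =
|\ln[P_l(1-\bar q)/((1-P_l)\bar q)]|$, background $\bar q = 0.5$ for
synthetic data. Its first eigenvector (after a component-wise square root,
`scaSectorEstimate()`) recovers sectors only when selection bias creates
conservation; at $\gamma = 0$ the weights vanish and SCA drops to the
random baseline — the comparator behavior the acceptance tests assert. The
q-state variant weights per (site, state) and compresses site-pair blocks
by Frobenius norm.

**Recovery** (`recovery()`): $\sum_l |\nu_l \Delta_l| / (\|\nu\|
\|\Delta\|)$, sign-blind and scale-invariant, maximal at 1 exactly when
$\nu \parallel \Delta$ up to per-site signs. The random baseline is
computed by Monte Carlo over uniform unit vectors, alongside the closed
form $\sqrt{2/(\pi L)}\sum_l|\Delta_l|/\|\Delta\|$ valid for $L \gg 1$
(`recoveryRandomExpectation()`; the test suite checks both against the
exact sphere marginal $\Gamma(L/2)/(\sqrt{\pi}\,\Gamma((L+1)/2))$).

**ICA** (`icaDisentangle()`): with $N$ selected traits the ICOD spectrum
shows $N$ outliers (declared rule: eigenvalues above median + 6 MAD,
`countOutliers()`), but the leading eigenvectors are rotated within the
span of the $\Delta_i$. A fixed-point ICA (symmetric decorrelation, tanh
contrast, seeded random orthogonal start, tolerance $10^{-8}$, at most 1000
iterations — non-convergence is an error reporting the iteration count)
finds the rotation whose components are maximally non-Gaussian across
sites, aligning each with one effect vector. No ICA implementation is
available among the package's dependencies, so the fixed-point iteration is
implemented here.

Eigenvector sign convention everywhere: the largest-magnitude component is
made positive. Recovery is sign-blind, but reports stay deterministic.

## The 21-state extension

Real alignments use $q = 21$ states (20 amino acids + gap, gap treated as a
state). `encodeAlignment()` removes columns with more than 15% gaps
(default, configurable), fixes a per-site gauge state — consensus by
default, ties broken alphabetically, or an explicit reference — and
one-hot encodes the $q - 1$ non-gauge states. `multistateCovariance()`
forms the $L(q-1)$-dimensional covariance with the pseudocount mixture
above; `icodMultistate()` inverts, zeroes the $(q-1)\times(q-1)$ diagonal
blocks *before* compression, compresses each off-diagonal site-pair block
to its Frobenius norm, and ranks sites by the magnitudes of the top
eigenvector of the compressed matrix. Optional 80%-identity sequence
reweighting is available but off by default — the generative model has no
phylogeny. With $q = 2$ the whole chain reduces *exactly* (to $10^{-8}$
and better) to the binary pipeline, which the acceptance tests assert.

A caveat established while validating: the full-length ranking produced by
the compressed ICOD matrix is gauge-*robust* but not gauge-*invariant*.
Sector sites keep their places across gauge changes at realistic sample
sizes, but the relative order of background sites (near-zero scores) is
sampling noise — block Frobenius norms accumulate noise in quadrature, so
rank correlations computed over all sites converge slowly with the number
of sequences. Tests therefore assert stability of the identified sector
set and of sector-site ranks, not a full-vector rank correlation.
Pseudocount changes within $\Lambda \in [0.01, 0.05]$ leave the ranking
essentially unchanged (Spearman $\ge 0.95$ asserted).

## Synthetic data: what it emulates and what it does not

`makeDelta()` plants `nSectorSites` positions with effects
$\sim\mathcal N(0, \sigma_s^2)$ among background sites
$\sim\mathcal N(0, \sigma_b^2)$, default ratio $\sigma_s/\sigma_b = 10$
(an `all_negative` half-normal policy mirrors the elastic-network case
where weakening springs can only lower the deformation energy).
`makeDeltaPair()` builds two sectors with a prescribed overlap fraction —
disjoint 20-site sectors at 0%, identical 100-site sectors at 100% —
with independent effect values on shared sites. `makeMultistateDelta()`
puts the sector structure in the per-site norm across the $q-1$ non-gauge
states. `makeToyStructure()` provides reproducible helix or random-coil
CA/CB geometries with a localized coherent displacement as the
"conformational change". All generators are pure functions of their
parameters and seed.

Note that with Gaussian effect magnitudes the smallest sector effects
overlap the background tail: the top-20 magnitudes coincide with the
planted sector only on average (the suite asserts a mean overlap
$\ge 0.75$ across seeds), which is a property of the declared
distributions, not an estimator failure.

What passing tests on these ensembles do **not** show about real data: no
phylogenetic correlations between sequences, no specific (pairwise)
epistasis, no structural-contact constraints, and alignment columns are
generated independently given the trait — so performance on natural
alignments, where conservation, phylogeny and contacts confound the
covariance, will be lower than on these benchmarks. The q = 21 pipeline is
validated on synthetic ensembles; applying it to a real family additionally
requires a trustworthy alignment.

## Problem sizes and numerical choices

The test and acceptance runs use: exhaustive enumeration up to $L = 12$;
importance sampling with $10^5$ sequences at $L = 100$ (20 sector sites)
across $\gamma \in [-1, 1]$ averaged over 10 seeds; $5\times10^4$
sequences for the $L = 50$ small-coupling check; $10^5$ two-trait samples
for the ICA benchmark; 20-residue toy structures for the elastic-network
exactness checks. These sizes were chosen so each property is measured
well inside its sampling error while a full run stays comfortably
interactive.

Matrix inversions use dense `solve()`; a singular covariance raises an
error naming the pseudocount remedy rather than silently regularizing. An
optional ridge exists on `icodSpectrum()` but the frequency pseudocount is
the preferred regularization, matching inverse-covariance practice in
sequence analysis. Weighted covariance accumulation is done in one pass
with `crossprod`; the q-state one-hot matrix is sparse.

## Known limitations

* Importance sampling degenerates for extreme biases ($|\gamma| \gtrsim
  3$): the effective sample size collapses and MCMC (or larger proposal
  batches) is the better tool; the provenance flags low ESS.
* The outlier rule (median + 6 MAD) is a heuristic; the number of
  informative modes only *often* equals the number of selected traits.
* `enumerateEnsemble()` is exponential by design and guards at $L = 20$.
* The Metropolis sampler is single-threaded R; it is intended for
  moderate $L$ and sample counts, with importance sampling preferred
  whenever weights remain healthy.
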