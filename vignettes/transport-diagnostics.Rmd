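---
title: "Transport diagnostics for excitation character: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport diagnostics for excitation character: models, conventions, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excitOT)
```

## The problem

Linear-response TDDFT expands an electronic excitation in single-orbital
transitions $\varphi_i \to \varphi_a$ with amplitudes $X_{ia}$, $Y_{ia}$ and
weights $c_{ia} = X_{ia}^2 + Y_{ia}^2$. Whether a given excitation is
*local*, *charge transfer* (CT) or *Rydberg* matters because approximate
functionals err very differently across these classes — but the label is
usually assigned by visual inspection. This package computes quantitative
diagnostics of excitation character from the orbitals on a regular 3D grid
(Gaussian cube files), and evaluates how well they classify.

Two families of diagnostics are implemented:

* **Overlap.** $\Lambda = \sum_{ia} c_{ia} \langle |\varphi_a| , |\varphi_i|
  \rangle / \sum_{ia} c_{ia}$, the weighted modulus overlap. $\Lambda$ is
  blind beyond the point where supports become disjoint: once the overlap is
  zero, it stays zero however far the density travels.
* **Transport.** $\Theta = \sum_{ia} c_{ia} S_\varepsilon(\rho_i, \rho_a) /
  \sum_{ia} c_{ia}$, where $\rho = |\varphi|^2$ and $S_\varepsilon$ is the
  debiased (Sinkhorn) divergence of entropically regularized optimal
  transport under the squared-Euclidean cost. $S_\varepsilon$ keeps growing
  quadratically with the transfer distance where the overlap has plateaued,
  which is exactly the regime that distinguishes long-range CT.

The dimensionless variant $\Theta'$ divides each transition's divergence by
the electron-position variance of the transition pair, and the
orbital-independent variant applies the same construction to attachment and
detachment densities derived from ground/excited one-particle density
matrices, together with their overlap $\phi_S$.

## The solver

The entropic transport problem is solved by Sinkhorn iteration in the log
domain. Two structural facts keep 0.8 bohr molecular grids tractable on one
CPU:

1. The squared-Euclidean Gibbs kernel factorizes over grid axes, so one
   kernel application is three small dense matrix products (a log-sum-exp
   reduction per axis); the $N^2$ cost matrix is never formed.
2. All updates act on scaled potentials $u = f/\varepsilon$ with
   per-column max-shifts, so the iteration is stable down to small
   $\varepsilon$ where the Gibbs kernel underflows almost everywhere.

The reported value is the primal objective of the coupling implied by the
dual potentials. Writing $\log \pi = \log(a \otimes b) + u + v -
C/\varepsilon$, the cost term cancels algebraically and the primal value
reduces to $\varepsilon(\langle r, u\rangle + \langle s, v\rangle -
(\mathrm{mass}(\pi) - 1))$ with $r$, $s$ the implied marginals — so the
number stays meaningful even when the iteration is stopped at loose
tolerance. Convergence is declared on the $L^1$ marginal violation
(default $10^{-6}$ mass units, 5000 iteration cap; non-convergence is a
flagged warning so batch runs complete). Self-terms $\mathrm{OT}_\varepsilon
(\rho,\rho)$ use the damped symmetric fixed-point iteration with equal
potentials, halving their cost.

**Initialization.** By default the iteration is *annealed*: it starts at
$\varepsilon = d_\mathrm{max}$ and halves down to the target, warm-starting
the potentials at each level. Annealing changes only the starting point of
the final fixed-point iteration, never the fixed point itself (the suite
verifies fixed and annealed schedules agree to $10^{-8}$); it was preferred
over a fixed-$\varepsilon$ default because it removes the slow-convergence
cliff at small $\varepsilon$ without affecting results.

## Choosing the regularization

$\varepsilon$ shares units with the cost (bohr²). It is set on a halving
ladder from the grid geometry, $\varepsilon = d_\mathrm{max} \cdot
2^{-\sigma}$ with integer $\sigma$ and $d_\mathrm{max}$ the squared
bounding-box diagonal (the maximum of the cost on the grid). The ladder is
isolated in `epsilon_from_sigma()`, so a different base is a one-line
change. Two facts about this ladder matter in practice, both verified
against the closed-form entropic value between Gaussians
(`gaussian_ot_reference()`):

* For *translation-dominated* transport (equal-shape source and target) the
  debiasing cancels the entropic bias exactly — $S_\varepsilon = d^2$ at
  any $\varepsilon$ for equal-width Gaussians — so $\Theta$ is converged on
  the ladder already at $\sigma = 4$, the default operating point.
* For *shape-changing* transport (e.g. a valence density flowing into a
  diffuse one, or any centrosymmetric rearrangement) the divergence at
  $\sigma = 4$ can be far from its converged value, because
  $d_\mathrm{max}/16$ is typically larger than every internal length scale
  of a small molecule. Convergence studies of such excitations must climb
  the ladder (σ of 8–10) and should not trust a single low-σ point. This is
  a property of the halving ladder itself, not of the solver.

## Variance convention for the dimensionless diagnostic

"Normalized by the variance of the electron position" admits two readings:
the second moment about a fixed molecular center, or each density's central
variance. The package defaults to the **central variance** (mean of the two
densities' second moments about their own barycenters, averaged per
transition before $c$-weighting) for two reasons. First, it makes $\Theta'$
exactly invariant under uniform dilation *and* translation of the geometry.
Second, it preserves the Gaussian overlap relation: for equal-width pairs
$S = d^2$, the central variance is $3s^2$, and $-\log\Lambda = d^2/(8s^2)$,
hence

$$\Theta' = \tfrac{8}{3}\,(-\log \Lambda)$$

exactly in the small-$\varepsilon$ limit — the analytically controllable
form of the observed $\Theta'$–$\log\Lambda$ correlation. With moments
taken about the molecular midpoint instead, the normalizer picks up a
$d^2/4$ term and the relation ceases to be linear. A fixed center (for
example `nuclear_centroid()` of the cube's atom list) can still be passed
explicitly to every variance-normalized function. Normalization is applied
per transition, not to the aggregate: a one-transition excitation then has
$\Theta'$ independent of how the remaining weight is distributed.

The $\phi_S$ normalizer is the arithmetic mean of the attachment and
detachment masses, $\phi_S = \int\sqrt{\rho_A\rho_D} / \tfrac12(m_A+m_D)$.
Where a logarithm of $\phi_S$ is reported the package uses base 10 (one
unit is one decade of overlap).

## Grid and quadrature conventions

Cube values are treated as voxel-center samples with midpoint quadrature
(weight = voxel volume); the quadrature error is second order in the
spacing. All production grids use 0.8 bohr spacing. Grids must capture at
least 99% of each density (`mass_and_coverage()`), and densities are
renormalized to exact unit mass before any transport call, because the
balanced transport problem requires equal-mass marginals; truncation below
the coverage threshold is an error for model densities and a warning in the
batch pipeline. Transition weights below $c_{ia} = 0.05$ are excluded and
the remaining weights renormalized, mirroring the truncated transition
lists printed by electronic-structure codes; the threshold is configurable
because it biases $\Lambda$ and $\Theta$ when many small amplitudes exist.
Attachment/detachment eigenvalues with $|\lambda| < 10^{-10}$ are treated
as zero; eigenvector sign is irrelevant since only densities are formed.

## The synthetic generator

`synthetic_excitation_set()` produces labeled Gaussian model excitations on
one shared grid (box auto-sized from the most diffuse class member):

| class | construction | default parameters |
|---|---|---|
| local | concentric equal-width pair, small center jitter | jitter ≤ 0.3 bohr |
| CT | equal-width pair pulled apart | separation 5–7 bohr |
| Rydberg | concentric, final orbital more diffuse | width ratio 3–4 |

Defaults encode the study conditions: unit base variance (a compact valence
density), CT separations of 3–4 bond lengths so the pair is genuinely
charge-separated yet forms a compact cluster in feature space, and Rydberg
surrogates that are *diffuse rather than displaced* — deliberately probing
the known failure mode that displacement-based diagnostics conflate
diffusivity with charge transfer. The generator warns when class parameter
ranges overlap, since separability-by-construction is its contract.

What the generator does **not** emulate: nodal structure (model densities
are smooth lobe mixtures, which inflates overlap-type quantities — the
formaldehyde surrogate reproduces the scale of the transport diagnostic but
overestimates $\phi_S$ for exactly this reason), basis-set tails,
anisotropic Rydberg envelopes, and near-degenerate transition mixing.
Passing tests on synthetic data therefore validate the *operators*, not the
chemistry of any particular molecule.

Synthetic stand-ins for three real systems are provided for benchmark
exercises (`synthetic_n2_excitations()`, `synthetic_hcl_ct_excitations()`,
`synthetic_formaldehyde_ad()`): Gaussian-lobe orbital models at
experimental geometries with Slater-orbital spatial extents. They are
labeled synthetic everywhere; no electronic-structure calculation stands
behind them.

## Classifier protocol

The k-NN classifier z-scores every feature on the training set before
computing Euclidean distances (the diagnostic planes mix bohr² with
dimensionless axes; raw mode is available for sensitivity checks). Vote
ties are broken by the smallest mean distance to the query among tied
classes, making predictions deterministic. Evaluation defaults to
stratified 5-fold cross-validation with per-fold confusion matrices summed,
so each point is scored exactly once; resubstitution (`folds = 0`) is
available for comparison. Class imbalance is reported via the class counts,
not corrected. `k = 13` follows the square-root-of-training-set heuristic
at the ~170-point scale.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their grids so every check
runs on one CPU in minutes: brute-force oracle comparisons on ≤ 64-voxel
densities (exact convex minimization via `constrOptim` is the independent
reference there), Gaussian-limit checks on ±16 bohr boxes at 0.8 bohr
spacing (41³ voxels), the classifier sanity check on 20 excitations per
class, and ladder-convergence studies on ±8 bohr boxes. These sizes are
choices of the validation design, not limits of the solver; the axis-wise
kernel keeps per-iteration cost linear in the voxel count times the
per-axis extent.

## Known limitations

* Only balanced transport under the squared-Euclidean cost; no unbalanced
  marginals, no alternative costs, no GPU path.
* The closed-form Gaussian reference covers diagonal (axis-aligned)
  covariances; it is a validation oracle, not a general-purpose solver.
* Densities sampled on different grids must be resampled externally; binary
  operations require exactly matching grids.
* The halving ladder's $\sigma = 4$ operating point is adequate only for
  translation-dominated transport (see above); shape-dominated problems
  need larger σ, at higher iteration cost.
* Centrosymmetric CT (donor and acceptor barycenters coincide) defeats any
  displacement-sensitive diagnostic, $\Theta$ included.
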