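# excitOT

Optimal-transport diagnostics for the character of molecular electronic
excitations.

## Why

Approximate TDDFT functionals err very differently on **local**,
**charge-transfer (CT)** and **Rydberg** excitations, so labeling an
excitation is the first step of trusting (or redoing) a calculation — yet
the label is usually assigned by eyeballing orbitals. The classic
quantitative handle is the amplitude-weighted orbital overlap

Λ = Σᵢₐ c_ia ⟨|φ_a|, |φ_i|⟩ / Σᵢₐ c_ia,  c_ia = X²_ia + Y²_ia,

which is blind once the initial and final orbitals stop overlapping: it
plateaus at zero no matter how far the density actually moved. This package
implements the transport-based alternative

Θ = Σᵢₐ c_ia S_ε(ρ_i, ρ_a) / Σᵢₐ c_ia,  ρ = |φ|²,

where S_ε is the debiased (Sinkhorn) divergence of entropically regularized
optimal transport under the squared-Euclidean cost — a quantity that keeps
growing quadratically with the transfer distance where Λ has flat-lined.
Also included: the dimensionless, variance-normalized Θ′ (which for
Gaussian orbitals relates to the overlap as Θ′ = (8/3)(−log Λ)), the
difference-density CT length D_CT, attachment/detachment density analysis
with the overlap ϕ_S and the orbital-independent Θ′ variant, and a k-NN
classifier with confusion-matrix evaluation over any of these diagnostic
planes.

The Sinkhorn solver is written for regular volumetric grids: log-domain
iterations with an axis-separable Gibbs kernel, so a 41³ molecular grid at
0.8 bohr spacing runs in seconds per divergence on one CPU and the N² cost
matrix is never formed. Everything operates on Gaussian cube files; a
synthetic Gaussian-density generator makes the entire pipeline testable
without any electronic-structure code.

## Worked example

A charge-transfer toy model: two equal-width Gaussian orbital densities
(s² = 1 bohr²) pulled 4 bohr apart, where the overlap has already collapsed
but transport measures the displacement exactly.

```r
library(excitOT)

grid <- grid_template(halfwidth = 8, spacing = 0.8)
donor    <- gaussian_orbital(c(-2, 0, 0), var = 1, grid)
acceptor <- gaussian_orbital(c( 2, 0, 0), var = 1, grid)

exc <- excitation("ct_demo", list(
  transition(i = 1, a = 2, X = 1, initial = donor, final = acceptor)))

lambda_diagnostic(exc)                          # 0.1353353
theta(exc, transport_config(sigma = 8))         # 16 bohr^2
theta_prime(exc, transport_config(sigma = 8))   # 5.333333
```

The overlap Λ ≈ e^(−d²/8s²) = e^(−2) ≈ 0.136 is already deep in its
plateau, while Θ recovers the squared displacement d² = 16 bohr² to the printed
precision, and Θ′ = 16/(3s²) ≈ 5.33 is the dimensionless version — equal to
(8/3)(−log Λ) as expected for Gaussians. Running the same pair through the
batch pipeline (`write_synthetic_manifest()` → `run_diagnostics()`) gives
the same numbers from cube files on disk, and
`run_classification(diagnostics, feature_sets = list(c("theta_prime",
"log_lambda")))` evaluates a k = 13 nearest-neighbor classifier with
5-fold cross-validated confusion matrices.

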