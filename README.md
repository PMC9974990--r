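# dimes

Maximum-entropy ensembles of 3D chromatin structures from pairwise
distance data.

Multiplexed FISH imaging measures the 3D positions of genomic loci in
thousands of single cells; Hi-C measures population contact probabilities
that convert to distances through a power law. Both yield the same robust
summary — a matrix of mean (squared) pairwise distances between loci —
and both leave the same inverse problem: what *ensemble* of 3D structures
is consistent with that matrix? This package is for computational
biologists and biophysicists who want to turn a distance (or contact)
matrix into such an ensemble, interrogate its higher-order statistics, and
predict how structural variants reshape it.

## The model

Among all distributions over loci coordinates reproducing the constraints
⟨‖**x**ᵢ − **x**ⱼ‖²⟩ = aᵢⱼ, the maximum-entropy one is the multivariate
Gaussian

P({**x**ᵢ}) ∝ exp( −Σ_{i<j} k_{ij} ‖**x**ᵢ − **x**ⱼ‖² ),

with one Lagrange multiplier k_{ij} per pair. Assembling K (off-diagonal
k_{ij}, diagonal −Σ_{j≠i} k_{ij}) gives, per spatial dimension, covariance
Σ = −K⁺ and the closed form ⟨r²ᵢⱼ⟩ = 3(Σᵢᵢ + Σⱼⱼ − 2Σᵢⱼ). The package:

- **fits** K to a target distance matrix by iterative scaling (γ = 10,
  scale-invariant) or gradient descent, with missing-data masking — held
  out entries never update their coupling and are *predicted* by the
  fitted model;
- **samples** conformations exactly by normal modes (each non-zero mode
  ~ N(0, −1/ωᵢ), zero mode pinned at the center of mass);
- **converts** contact maps through ⟨rᵢⱼ⟩ = Λ p_{ij}^{−1/α} (α = 4,
  Λ = 1 by default; `calibrate_conversion()` fits both);
- **analyzes** ensembles: per-pair distance distributions and
  Jensen–Shannon divergences, triplet co-localization π_{ijk} and
  gap-product Z-scores, radius of gyration and shape anisotropy κ²,
  single-cell domain-boundary probabilities, conformation-space
  clustering, A/B mixing Q_k and long-range order F_k;
- **interprets** the couplings: correlation matrix ρ, PC1 compartments,
  ⟨k(s)⟩ profiles and histograms by pair class, additivity diagnostics;
- **perturbs**: segment inversions and locus deletions on K, scored by the
  perturbation index PI = √(Σ(⟨r̃ᵢⱼ⟩−⟨rᵢⱼ⟩)² / Σ⟨r̃ᵢⱼ⟩²);
- **simulates** ground-truth fixtures (Rouse chains, A/B block copolymers,
  imaging-like degraded cells) so everything above is testable without
  external data.

## Worked example

Recover a planted model from imaging-like synthetic cells:

```r
library(dimes)

# ground truth: an A/B block copolymer at a 300 nm bond scale
fixture <- make_block_copolymer(n_loci = 32, block_spec = 8L, seed = 11)
K_true  <- fixture$connectivity / 300^2            # nm^-2

# imaging-like data: 1500 cells, 10% dropout, 20 nm localization noise
cells  <- make_synthetic_cells(K_true, n_cells = 1500,
                               missing_rate = 0.1, noise_sd = 20, seed = 11)
target <- ensemble_mean_sq_distances(cells)        # nm^2

# fit the maximum-entropy model
fit <- fit_iterative_scaling(target, tol = 5e-3, max_iter = 30000)
print(fit)
#> dimes fit (iterative_scaling): N = 32 loci, 4481 iterations, converged
#>   final relative error: 0.004999

# fidelity: fitted vs ground-truth mean distances
d2_true <- mean_sq_distances(covariance_from_connectivity(K_true))
ut <- upper.tri(d2_true)
cor(sqrt(fit$fitted_d2[ut]), sqrt(d2_true[ut]))
#> [1] 0.9992

# compartments from the fitted couplings
rho  <- correlation_from_connectivity(fit$connectivity)
comp <- compartments_from_correlation(rho, reference_labels = fixture$labels)
mean(comp$label == fixture$labels)
#> [1] 1

# sample an ensemble; score A/B mixing and long-range order
ens <- sample_conformations(fit$connectivity, n_samples = 500, seed = 1)
mean(mixing_metric(ens, fixture$labels, k = 8))   # 0 = mixed, 2 = demixed
#> [1] 1.475
mean(longrange_metric(ens, k = 8))                # 1 = straight chain
#> [1] 4.018

# which locus matters most? deletion perturbation profile
pi_prof <- pi_deletion_profile(fit$connectivity)
which.max(pi_prof); max(pi_prof, na.rm = TRUE)
#> [1] 10
#> [1] 0.167
```

Reading the numbers: the fitted model reproduces the ground-truth mean
distance map to r = 0.9992 from noisy, incomplete single-cell data; the
planted compartments are recovered perfectly from the fitted couplings;
Q₈ ≈ 1.5 says the A and B blocks are strongly demixed in space, and
F₈ ≈ 4 says sequence-distant loci are frequent spatial neighbours (the
same-class blocks co-locate); the deletion profile singles out locus 10 —
near a block boundary — as most structurally load-bearing.

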