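---
title: "Maximum-entropy chromatin ensembles from pairwise distances"
author: "dimes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy chromatin ensembles from pairwise distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimes)
```

## The model

Multiplexed FISH imaging reports the 3D coordinates of selected genomic
loci in thousands of individual cells; Hi-C reports population-averaged
contact probabilities that can be converted to distances. Either way, the
experimentally robust summary is the matrix of mean (squared) pairwise
distances $\langle r_{ij}^2 \rangle$ between $N$ loci. The inverse problem
this package solves is: which *distribution* over conformations
$\{\mathbf{x}_i\}$ should one infer from that matrix?

Among all distributions reproducing the constraints
$\langle \lVert \mathbf{x}_i - \mathbf{x}_j \rVert^2 \rangle = a_{ij}$, the
maximum-entropy choice is unique and has the Gaussian form

$$P(\{\mathbf{x}_i\}) \propto
  \exp\Big(-\sum_{i<j} k_{ij}\, \lVert \mathbf{x}_i - \mathbf{x}_j \rVert^2\Big),$$

with one Lagrange multiplier $k_{ij}$ per pair. Collecting the multipliers
into the **connectivity matrix** $K$ with $K_{ij} = k_{ij}$ for $i \ne j$
and $K_{ii} = -\sum_{j \ne i} k_{ij}$ makes each spatial dimension an
independent zero-mean Gaussian with covariance $\Sigma = -K^{+}$ (the
Moore–Penrose pseudoinverse), and

$$\langle r_{ij}^2 \rangle = 3\,\omega_{ij}^2, \qquad
  \omega_{ij}^2 = \Sigma_{ii} + \Sigma_{jj} - 2\Sigma_{ij}.$$

This is the Boltzmann form of a generalized Rouse model (harmonic springs
between arbitrary monomer pairs), but it is derived from the data rather
than assumed: $k_{ij}$ may be negative (effective repulsion) provided $K$
stays negative semidefinite, i.e. provided the density remains
normalizable. $K$ always has the uniform vector in its null space — the
model says nothing about where the center of mass sits — and for a
connected coupling graph that zero mode is unique.

Two consistency notes, both load-bearing:

* **Factor-of-two convention.** The literal density above implies a
  covariance of $-K^{+}/2$; the operational convention used throughout
  this package (and standard in this literature) is $\Sigma = -K^{+}$ with
  mode variance $-1/\omega_i$ in the sampler. The two conventions differ
  only by a global factor of 2 on every $k_{ij}$; we use the latter,
  consistently, everywhere.
* **Units.** Distances are nm, squared distances nm², couplings nm⁻².
  Everything rescales trivially: multiplying all distances by $c$ divides
  all couplings by $c^2$, so "model units" (bond scale 1) are fine for
  method work and can be rescaled afterwards.

## Fitting the couplings

`connectivity_from_distances()` inverts the algebra directly: double-center
$-\tfrac12 (a_{ij}/3)$ under the zero-row-sum gauge to get $\Sigma$, then
$K = -\Sigma^{+}$. This is exact for model-realizable targets but fragile
for experimental ones (a noisy matrix need not be realizable, and the
inversion offers no way to mask missing entries), so the recommended route
is iterative:

* **Iterative scaling** (`fit_iterative_scaling()`):
  $k_{ij} \leftarrow k_{ij} + \frac{\gamma}{\sum_{i<j}\langle r_{ij}^2\rangle}
  \ln \frac{\langle r_{ij}^2\rangle}{a_{ij}}$, with $\gamma = 10$. The
  normalization by the total model distance makes the update
  scale-invariant, so the same $\gamma$ works in nm or model units. This
  is the primary optimizer. (For a *single*-pair problem the normalizing
  sum has one term and $\gamma = 10$ overshoots; use a smaller rate for
  toy systems of two loci.)
* **Gradient descent** (`fit_gradient_descent()`):
  $k_{ij} \leftarrow k_{ij} + \gamma\,(\langle r_{ij}^2\rangle - a_{ij})$.
  The sign is fixed by the exponential-family dual — the gradient of
  $\ln Z(k) + \sum k_{ij} a_{ij}$ in $k_{ij}$ is
  $a_{ij} - \langle r_{ij}^2\rangle$ — so a pair the model renders too
  extended gets a *stronger* coupling, the same orientation as the
  iterative-scaling update. Here $\gamma$ carries units and its stable
  range shrinks with the number of pairs; the default
  $1/(P\,\overline{a}^2)$ (with $P$ the number of observed pairs) is
  deliberately conservative. Gradient descent exists mainly as an
  independent cross-check and as the route that accepts a ridge penalty
  $\lambda \sum k_{ij}^2$ (default $\lambda = 0$); our ridge is a design
  choice, not a reproduction of any published regularizer.

Per iteration, $\Sigma$ comes from the Laplacian identity
$L^{+} = (L + \mathbf{1}\mathbf{1}^{\mathsf T}/N)^{-1} -
\mathbf{1}\mathbf{1}^{\mathsf T}/N$ (with $L = -K$) via Cholesky; if the
factorization fails, the eigendecomposition path clips any positive
eigenvalues to zero (**NSD repair** — clipping happens in the eigenbasis,
and because positive modes are orthogonal to the uniform vector the
zero-row-sum gauge survives). Convergence is declared when the relative
mean absolute error $\overline{|\langle r^2\rangle - a|}/\overline{a}$
drops below `tol` (default $10^{-2}$); the fit aborts with the trace
attached if the error grows to ten times its running minimum, or if the
update becomes non-finite (a collapsed pair).

**Initialization.** The default is an ideal chain: nearest-neighbour
couplings set so the model's mean squared distance matches the target's
mean. It guarantees a connected, well-posed starting model and a sane
starting error. `direct_inversion` (PSD-projected) starts at the algebraic
solution — on a realizable target that is already the fixed point.
An all-zero start is *not* offered: $K = 0$ has no pseudoinverse gauge, so
the first iteration could not even evaluate its distances.

**Missing data.** `NA` entries in the target (or an explicit mask) are
never used in an update: their couplings stay frozen at the
initialization (zero for non-backbone pairs). Identifiability requires
the observed pairs to form a connected graph; the fit refuses otherwise.
After convergence the model's full analytic distance matrix supplies
predictions for the held-out pairs. A caveat worth stating plainly:
held-out prediction leans on the *regularity* of the coupling structure.
Real chromatin couplings vary smoothly with genomic separation (plus a
compartment modulation), and on such targets 90% masking still yields
held-out Pearson correlations near 0.99. On an adversarial target whose
couplings are dense and idiosyncratic pair-by-pair, held-out accuracy
degrades (we measure ≈ 0.81 on our strongest block fixture) — no amount of
fitting the observed entries can recover information that is simply not
propagated by the network.

## Sampling

`sample_conformations()` eigendecomposes $K$, draws each non-zero mode of
each spatial dimension from $\mathcal N(0, -1/\omega_i)$, pins the zero
mode to zero (center of mass at the origin), and superposes. Draws follow
a fixed order (conformation, then dimension x/y/z, then mode), so a seed
reproduces the ensemble bitwise. More than one near-zero mode means the
coupling graph is disconnected and sampling refuses. The sampler is
validated against the analytic second moments (elementwise agreement
within $4/\sqrt{M}$) and against the Gaussian-separation identity
$\operatorname{Var}(r^2) = \tfrac23 \langle r^2 \rangle^2$.

## Contacts and distances

Contact probabilities and mean distances are linked by the power law
$\langle r_{ij} \rangle = \Lambda\, p_{ij}^{-1/\alpha}$; squaring gives the
distance-map input. Defaults are $\alpha = 4$ and $\Lambda = 1$ (structures
fitted at $\Lambda = 1$ rescale trivially once a physical length is
known). `calibrate_conversion()` fits both parameters to a reference
distance matrix by minimizing the mean squared deviation of *distances*
(not squared distances), using a deterministic log-spaced grid over
$\alpha \in [2, 8]$ with the optimal $\Lambda$ in closed form per grid
point and two refinement passes. Raw-count matrices are normalized by
their maximum off-diagonal entry before conversion — a stated convention,
not a claim about how any particular consortium normalizes. Zero-contact
pairs become missing entries rather than infinite distances.

## Ensemble statistics

All statistics are functions of inter-locus distances only, hence
invariant under rigid motions (asserted in the tests).

* **Distance distributions and JSD.** Per-pair histograms on shared
  Freedman–Diaconis bins; the Jensen–Shannon divergence uses log base 2 so
  it lives in $[0, 1]$, with the $0\log 0 = 0$ convention in empty bins.
* **Triplets.** $\pi_{ijk}(a)$ is the fraction of conformations with all
  three mutual distances below $a$. The default threshold $a = 300$ nm is
  the value at which model–experiment agreement peaks for chromatin-scale
  imaging data; for synthetic systems set $a$ to the system's own scale
  (e.g. the median mean pairwise distance). Z-scores normalize each
  triplet against the set sharing its sequence-gap *product*
  $|j-i|\cdot|k-j|$, with the population standard deviation;
  zero-spread groups (including singletons) score 0 by convention.
* **Shape.** Per-conformation gyration tensor of a locus segment:
  $R_g$ is the root of its trace; the relative shape anisotropy
  $\kappa^2 = 1 - 3(\lambda_1\lambda_2 + \lambda_2\lambda_3 +
  \lambda_3\lambda_1)/(\lambda_1+\lambda_2+\lambda_3)^2$ runs from 0
  (sphere) to 1 (line).
* **Domain boundaries.** For each cell, each locus $i$ gets an
  insulation-style score: the mean distance between the windows
  $[i-w+1, i]$ and $[i+1, i+w]$ divided by the mean distance within them,
  so a call at $i$ marks a domain edge between $i$ and $i+1$. Because that
  ratio exceeds 1 for any extended chain, scores are normalized by their
  per-cell median; boundaries are local maxima of the normalized score
  above 1.2 (both $w = 5$ and the threshold are configurable). This
  algorithm is this package's concrete choice; boundary probability is the
  fraction of scoreable cells calling the locus. Notably, ideal
  homopolymer ensembles already show nonzero, roughly flat boundary
  probabilities — domain-like patterns in single cells partly reflect
  generic polymer fluctuations, a point the tests assert.
* **Conformation space.** The metric
  $D_{mn} = \sqrt{\tfrac{1}{N^2}\sum_{i,j}(r^{(m)}_{ij} - r^{(n)}_{ij})^2}$
  (ordered pairs, as written) feeds a 2D classical-MDS embedding and
  Ward-linkage agglomerative clustering (`hclust`, `ward.D2`). We chose
  deterministic MDS for the embedding step — the clustering downstream of
  the metric is standard machinery, and a seeded stochastic embedding
  would add variance without adding information at these ensemble sizes.
  Each cluster reports its fraction, mean distance map, and the
  representative conformation with the lowest mean $D_{mn}$ to its
  cluster mates.
* **Mixing and long-range order.** $Q_k$ compares each locus's $k$
  nearest spatial neighbours against the random-mixing expectation
  $\tilde n_A = k N_A/N$; 0 means perfect mixing, 2 is the demixed ceiling
  for equal class sizes. Beware the tempting "alternating chain" example:
  on a straight chain with strictly alternating labels, each locus's two
  nearest neighbours are both of the *opposite* class, which scores 1.8 —
  nearly demixed by this metric. A configuration that genuinely realizes
  perfect mixing at $k = 2$ is a ring with period-4 AABB labels, where
  every locus sees exactly one A and one B; the acceptance suite uses it.
  $F_k$ averages the sequence separation $|j - i|$ over each locus's $k$
  spatial neighbours, normalized by the straight-chain value
  $F_{0,k} = \tfrac12(1 + k/2)$, so values above 1 flag long-range
  contacts. Neighbour ties break deterministically toward the lower locus
  index.

## Couplings as interactions

The fitted $k_{ij}$ are effective interaction strengths.
`correlation_from_connectivity()` computes the Pearson correlation between
coupling rows — the standard compartment recipe applied to couplings — and
`compartments_from_correlation()` takes PC1 of that matrix, labelling
negative scores A and positive B (eigenvector sign fixed by reference
labels when given, else by forcing the first locus negative). One
deliberate refinement: the columns within one locus of $i$ and of $j$ are
excluded from both rows before correlating (configurable via
`exclude_neighbors`). The backbone couplings are orders of magnitude above
the epigenetic ones; left in, they dominate the row variance and bury the
compartment signal whenever the couplings carry fit noise. For
compartment analysis of *fitted* couplings, fit tightly (`tol = 5e-3` or
below): the residual fitting error is structured, and at the default
`tol = 1e-2` it measurably blurs the coupling correlations.

`k_profile_by_s()` gives $\langle k(s) \rangle$ per pair class (A-A, B-B,
A-B). The per-class mean at separation $s$ is normalized by that class's
pair count at $s$ — normalizing by all $N - s$ pairs would damp whichever
class is sparse at that separation. `additivity_diagnostic()` tests the
decomposition $k_{ij} = k_0(i, j) + k_e(\text{class}_i, \text{class}_j)$:
if it holds, the pairwise differences of class profiles are flat in $s$,
and the function reports those difference curves with a flatness summary.

## Structural variants

An inversion of loci $[a, b]$ is an index permutation of the coupling
table — a similarity transform, so the spectrum (and semidefiniteness) is
preserved exactly and double inversion is the identity. Deleting a locus
removes its row and column and reassembles the diagonal ("cut the
springs"). The alternative semantics — Gaussian marginalization, which
keeps effective couplings routed *through* the deleted locus — is
implemented internally as a cross-check: the two agree exactly when the
locus is a leaf of the coupling graph and provably differ otherwise (for
a 1–2–3 chain with a weak direct 1–3 spring, cutting locus 2 leaves only
the direct spring, while marginalizing keeps the series combination).
Deletion can disconnect the graph, and — when negative couplings are
present — can leave a non-semidefinite minor; both cases are refused, and
`pi_deletion_profile()` reports such loci as `NA`. Duplications and
insertions change the locus set in ways no coupling edit expresses; they
are rejected with instructions to refit on the mutated map.

The **perturbation index**
$\mathrm{PI} = \sqrt{\sum_{i<j} (\langle\tilde r_{ij}\rangle -
\langle r_{ij}\rangle)^2 / \sum_{i<j} \langle\tilde r_{ij}\rangle^2}$
(on distances, not squared distances) is zero at identity, nonnegative,
and invariant to a common rescaling of both maps.

## The synthetic ground truths

The package is validated entirely on generated data with known answers:

* `make_rouse_chain(N, k)` — the analytic anchor:
  $\langle r_{ij}^2 \rangle = 3|i-j|/k$ (graph resistance distance).
* `make_block_copolymer()` — backbone chain (coupling 1) plus planted A/B
  blocks: within-class couplings 0.3, cross-class −0.01, 20% log-normal
  jitter, blocks of 8. The within-class default is chosen so the planted
  compartments produce a distance-map checkerboard of realistic contrast
  *and* remain statistically recoverable from a few thousand cells at
  N ≈ 64 — weaker couplings leave the coupling-space compartment signal
  below the fit-noise floor at that sample size. Negative cross couplings
  are the only semidefiniteness risk, so only they are scaled down until
  $K$ is NSD, and then halved once more: a fixture *at* the NSD boundary
  has an arbitrarily soft A-vs-B mode whose extreme distances make the
  inverse problem needlessly stiff (with the margin, a typical refit
  converges in ~2×10⁴ iterations; without it, it stalls).
* `make_synthetic_cells()` — imaging-like degradation: isotropic Gaussian
  localization noise (default 20 nm per coordinate, inflating apparent
  squared distances by $6\sigma^2$ in expectation) and per-locus dropout
  (default 10%). The noise model is additive Gaussian on coordinates —
  the simplest defensible emulation; it does not model locus misassignment,
  chromatic offsets, or z-anisotropy of real microscopes.

What the fixtures do *not* emulate: experimental distance maps are not
exactly model-realizable, localization errors are not isotropic or
homoscedastic, and real compartment structure is not block-periodic.
Passing tests therefore demonstrate the *inference machinery* — exact
algebra, convergent optimization, faithful sampling, correct statistics —
not field performance on any particular dataset.

## Problem sizes and numerics

The validation workloads use N = 64–65 loci and M = 3000 conformations
(fits of 10⁴–3×10⁴ iterations, a few tens of seconds each); unit tests
work at N ≤ 32 with brute-force oracles at N ≤ 6. Pseudoinverse zero modes
are detected at relative tolerance 10⁻¹⁰ of the largest eigenvalue
magnitude; distance matrices clip numerical negatives at zero; pair means
with fewer than `min_cells` observations are masked (`min_cells = 1` by
default, with a warning under 5 observations). Degenerate inputs — the
zero matrix, disconnected graphs, constant contact maps, all-missing
targets — raise errors naming the defect rather than limping on.

## Known limitations

* The method constrains second moments only; distributional agreement
  beyond Gaussian (e.g. heavy-tailed pair distances from rare looping) is
  outside the model class.
* Held-out (masked) prediction quality depends on coupling regularity, as
  quantified above.
* Compartment calling from couplings needs tight fits and adequate cell
  counts; at M = 3000, N = 64 the default study conditions sit comfortably
  above the noise floor, but halving either erodes the margin.
* No polymer dynamics: the ensemble is an equilibrium-like distribution;
  nothing here speaks to loop-extrusion kinetics or temporal ordering.
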