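Package: dimes
Title: Maximum-Entropy Ensembles of 3D Chromatin Structures from Pairwise
    Distances
Version: 0.1.0
Authors@R: person("Alex", "Doran", email = "adoran.chromatin@gmail.com",
    role = c("aut", "cre"))
Description: Reconstructs an ensemble of three-dimensional chromatin
    conformations from a matrix of mean squared pairwise distances between
    genomic loci, as measured by multiplexed FISH imaging or inferred from
    Hi-C contact maps. The maximum-entropy distribution consistent with the
    distance constraints is a multivariate Gaussian whose precision structure
    is a Laplacian-style connectivity matrix of Lagrange multipliers; the
    package fits that matrix by iterative scaling or gradient descent
    (including masked, missing-data fitting), samples conformations by normal
    modes, and computes downstream ensemble statistics: pairwise distance
    distributions and Jensen-Shannon divergences, triplet co-localization
    probabilities and Z-scores, radius of gyration and shape anisotropy,
    single-cell domain boundary probabilities, conformation clustering, A/B
    compartment inference from the fitted couplings, spatial mixing and
    long-range interaction metrics, and structural-variant (inversion and
    deletion) perturbation predictions scored by a perturbation index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
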