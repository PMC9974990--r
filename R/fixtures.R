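# Synthetic ground-truth generators: every downstream stage can be tested
# against models with known connectivity, planted compartment labels, and
# imaging-like degraded coordinate tables (missing loci, localization
# noise), without any external data.

#' Ideal-chain (Rouse) connectivity matrix
#'
#' Nearest-neighbour couplings of strength `k` along the backbone. Its mean
#' squared distances are the closed form `<r_ij^2> = 3 |i - j| / k` (the
#' graph resistance distance of a path, scaled by `1/k`), which makes this
#' the canonical analytic oracle for the model algebra.
#'
#' @param n_loci number of loci `N >= 2`.
#' @param k backbone coupling (> 0), default 1.
#' @return connectivity matrix.
#' @export
make_rouse_chain <- function(n_loci, k = 1) {
  if (n_loci < 2) stop("n_loci must be >= 2", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  od <- matrix(0, n_loci, n_loci)
  idx <- cbind(seq_len(n_loci - 1L), seq_len(n_loci - 1L) + 1L)
  od[idx] <- k
  od[idx[, 2:1]] <- k
  assemble_connectivity(od)
}

#' Block-copolymer connectivity with planted A/B compartments
#'
#' A backbone chain plus label-dependent long-range couplings: pairs within
#' the same compartment class attract (`k_intra > 0`), cross-class pairs
#' couple weakly or repel (`k_inter`, typically negative). Couplings carry
#' multiplicative log-normal jitter (seeded) so no two pairs are identical.
#' Only the cross-class couplings can break negative semidefiniteness
#' (positive couplings keep the model a weighted-graph Laplacian); if the
#' assembled matrix is not negative semidefinite, the cross-class couplings
#' are scaled down (factor 0.7 per pass) until it is, and one final halving
#' leaves a conditioning margin: a fixture sitting exactly at the
#' semidefiniteness boundary has an arbitrarily soft A-vs-B mode, which
#' makes its distances extreme and the inverse problem needlessly stiff.
#'
#' @param n_loci number of loci.
#' @param block_spec either an integer vector of successive block lengths
#'   (recycled to cover `n_loci`, labels alternating A, B, A, ...) or a
#'   character vector of per-locus labels of length `n_loci`. Default:
#'   alternating blocks of 8.
#' @param k_intra within-class coupling (default 0.3). The default is
#'   strong enough that the planted compartments produce a clear
#'   checkerboard in the distance map and remain statistically recoverable
#'   from a few thousand noisy cells.
#' @param k_inter cross-class coupling (default -0.01; clipped further by
#'   the semidefiniteness pass).
#' @param backbone_k nearest-neighbour coupling (default 1).
#' @param jitter_sd standard deviation of the log-normal jitter on the
#'   non-backbone couplings (default 0.2; 0 disables).
#' @param seed RNG seed for the jitter.
#' @return list with `connectivity` and `labels` (character vector).
#' @export
make_block_copolymer <- function(n_loci, block_spec = 8L, k_intra = 0.3,
                                 k_inter = -0.01, backbone_k = 1,
                                 jitter_sd = 0.2, seed = 1L) {
  if (n_loci < 4) stop("n_loci must be >= 4", call. = FALSE)
  if (backbone_k <= 0) stop("backbone_k must be > 0", call. = FALSE)
  labels <- if (is.character(block_spec)) {
    if (length(block_spec) != n_loci) {
      stop("label vector must have length n_loci", call. = FALSE)
    }
    block_spec
  } else {
    lens <- rep(as.integer(block_spec),
                length.out = ceiling(n_loci / min(block_spec)) + 1L)
    lab <- rep(rep(c("A", "B"), length.out = length(lens)), times = lens)
    lab[seq_len(n_loci)]
  }
  if (!all(labels %in% c("A", "B")) || length(unique(labels)) < 2) {
    stop("labels must contain both A and B", call. = FALSE)
  }
  set.seed(seed)
  same <- outer(labels, labels, "==")
  od <- ifelse(same, k_intra, k_inter)
  if (jitter_sd > 0) {
    jit <- matrix(exp(stats::rnorm(n_loci^2, 0, jitter_sd)), n_loci)
    jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
    od <- od * jit
  }
  diag(od) <- 0
  idx <- cbind(seq_len(n_loci - 1L), seq_len(n_loci - 1L) + 1L)
  od[idx] <- backbone_k
  od[idx[, 2:1]] <- backbone_k
  backbone <- matrix(FALSE, n_loci, n_loci)
  backbone[idx] <- TRUE
  backbone[idx[, 2:1]] <- TRUE
  K <- assemble_connectivity(od)
  ## negative cross-class couplings are the only semidefiniteness risk:
  ## scale them down until K is NSD, then once more as a conditioning
  ## margin (a fixture at the NSD boundary has an arbitrarily soft
  ## A-vs-B mode with extreme distances)
  cross <- !same & !backbone & od < 0
  if (any(cross)) {
    for (pass in 1:200) {
      w <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
      if (w[1] <= 1e-10 * max(abs(w))) break
      od[cross] <- od[cross] * 0.7
      K <- assemble_connectivity(od)
    }
    od[cross] <- od[cross] * 0.5
    K <- assemble_connectivity(od)
  }
  list(connectivity = K, labels = labels)
}

#' Imaging-like synthetic cells
#'
#' Emulates a multiplexed FISH deposit: samples `M` conformations from the
#' model, adds isotropic Gaussian localization noise to every coordinate,
#' and drops each locus independently per cell with probability
#' `missing_rate`. Localization noise inflates the apparent mean squared
#' distances by `6 * noise_sd^2` in expectation (independent noise on both
#' loci of a pair, three dimensions each).
#'
#' @param K connectivity matrix (ground truth).
#' @param n_cells number of cells `M`.
#' @param missing_rate per-locus dropout probability (default 0.1).
#' @param noise_sd localization noise standard deviation per coordinate, nm
#'   (default 20).
#' @param seed RNG seed.
#' @return `M x N x 3` coordinate array with `NA` for missing loci and
#'   attribute `source = "experimental"`.
#' @export
make_synthetic_cells <- function(K, n_cells, missing_rate = 0.1,
                                 noise_sd = 20, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ens <- sample_conformations(K, n_cells, seed = seed)
  n <- dim(ens)[2]
  if (noise_sd > 0) {
    ens <- ens + array(stats::rnorm(length(ens), 0, noise_sd), dim = dim(ens))
  }
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_cells * n) < missing_rate, n_cells, n)
    for (p in 1:3) {
      xp <- matrix(ens[, , p], n_cells, n)
      xp[drop] <- NA_real_
      ens[, , p] <- xp
    }
  }
  attr(ens, "seed") <- as.integer(seed)
  attr(ens, "source") <- "experimental"
  ens
}
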