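# Normal-mode sampling of 3D conformations from the fitted Gaussian model,
# and the reverse map from an ensemble (sampled or experimental, with
# missing loci) back to a mean squared distance matrix.

#' Sample conformations from the model
#'
#' Draws `n_samples` independent 3D structures from the maximum-entropy
#' distribution defined by the connectivity matrix. `K` is eigendecomposed;
#' for each spatial dimension every non-zero mode `i` receives an amplitude
#' `R_i ~ Normal(0, sd = sqrt(-1/omega_i))` and the coordinates are the mode
#' superposition. The zero (center-of-mass) mode is pinned to zero, so every
#' conformation has its centroid exactly at the origin.
#'
#' Draws are made in a fixed order (conformation-major, then dimension
#' x, y, z, then mode index), so a given seed reproduces the ensemble
#' bitwise.
#'
#' @param K connectivity matrix (negative semidefinite, connected: exactly
#'   one zero mode).
#' @param n_samples number of conformations `M`.
#' @param seed integer RNG seed.
#' @param rtol relative eigenvalue tolerance for the zero mode.
#' @return numeric array `M x N x 3` of coordinates (nm), with attributes
#'   `seed` and `source = "sampled"`.
#' @export
sample_conformations <- function(K, n_samples, seed = 1L, rtol = 1e-10) {
  K <- .check_connectivity(K)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  w <- e$values
  scale <- max(abs(w))
  if (scale == 0) stop("degenerate model: K is the zero matrix", call. = FALSE)
  if (w[1] > rtol * scale) {
    stop(sprintf("invalid connectivity: K has a positive eigenvalue (%.6g)", w[1]),
         call. = FALSE)
  }
  zero <- abs(w) < rtol * scale
  if (sum(zero) > 1L) {
    stop(sprintf("disconnected model: K has %d zero modes (expected 1)", sum(zero)),
         call. = FALSE)
  }
  n <- nrow(K)
  sdvec <- numeric(n)
  sdvec[!zero] <- sqrt(-1 / w[!zero])
  set.seed(seed)
  ## one N(0,1) draw per (conformation, dimension, mode), fixed order
  z <- array(stats::rnorm(n_samples * 3L * n), dim = c(n, 3L, n_samples))
  R <- z * sdvec                                # recycled along modes
  X <- e$vectors %*% matrix(R, nrow = n)        # N x (3 M)
  coords <- aperm(array(X, dim = c(n, 3L, n_samples)), c(3L, 1L, 2L))
  attr(coords, "seed") <- as.integer(seed)
  attr(coords, "source") <- "sampled"
  coords
}

#' Mean squared distances of an ensemble
#'
#' Computes, for every locus pair, the average squared Euclidean distance
#' over the conformations in which both loci are observed (missing loci are
#' `NA` coordinates, as in imaging data). Entries with fewer than
#' `min_cells` observations are reported as `NA`; a warning is issued when
#' any pair is supported by fewer than 5 conformations.
#'
#' @param ens `M x N x 3` coordinate array (missing loci as `NA`).
#' @param min_cells minimum number of conformations required per pair
#'   (default 1; entries below it are masked).
#' @return symmetric `N x N` matrix (`nm^2`), `NA` where unobserved.
#' @export
ensemble_mean_sq_distances <- function(ens, min_cells = 1L) {
  ens <- .check_ensemble(ens)
  m <- dim(ens)[1]
  n <- dim(ens)[2]
  obsl <- !is.na(matrix(ens[, , 1], m, n))
  obs <- obsl * 1
  counts <- crossprod(obs)
  total <- matrix(0, n, n)
  for (p in 1:3) {
    x <- matrix(ens[, , p], m, n)
    x[!obsl] <- 0
    x2 <- x^2
    total <- total + crossprod(x2, obs) + crossprod(obs, x2) - 2 * crossprod(x)
  }
  d2 <- total / counts
  d2[counts < max(1L, min_cells)] <- NA
  diag(d2) <- ifelse(diag(counts) >= max(1L, min_cells), 0, NA)
  low <- counts < 5 & upper.tri(counts)
  if (any(low)) {
    warning(sprintf("%d locus pair(s) observed in fewer than 5 conformations",
                    sum(low)))
  }
  (d2 + t(d2)) / 2
}

## per-conformation N x N Euclidean distance matrices (list), NA-propagating
.conformation_distmats <- function(ens) {
  ens <- .check_ensemble(ens)
  lapply(seq_len(dim(ens)[1]), function(m) {
    as.matrix(stats::dist(ens[m, , ]))
  })
}

.check_ensemble <- function(ens) {
  if (!is.array(ens) || length(dim(ens)) != 3L || dim(ens)[3] != 3L) {
    stop("ensemble must be an M x N x 3 coordinate array", call. = FALSE)
  }
  if (dim(ens)[1] < 1L) stop("ensemble must contain at least one conformation",
                             call. = FALSE)
  ## missingness must be consistent across the three coordinates
  miss <- is.na(ens)
  if (!all(miss[, , 1] == miss[, , 2]) || !all(miss[, , 1] == miss[, , 3])) {
    stop("missing loci must have all three coordinates NA", call. = FALSE)
  }
  ens
}
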