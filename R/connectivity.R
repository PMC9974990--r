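# Core algebra of the maximum-entropy Gaussian model: the connectivity matrix
# K (Laplacian-structured Lagrange multipliers), its covariance Sigma = -K^+,
# and the exact maps between K, Sigma and mean squared distances.

#' Assemble a connectivity matrix from pair couplings
#'
#' Builds the full connectivity matrix `K` from a symmetric table of pair
#' couplings `k_ij`: off-diagonal entries are the couplings and each diagonal
#' entry is minus the sum of the couplings in its row, so that every row of
#' `K` sums to exactly zero (the uniform vector is always in the null space,
#' reflecting translational invariance of the model).
#'
#' Couplings may be negative; the model remains valid as long as the
#' assembled `K` is negative semidefinite (checked where it matters, e.g. in
#' [covariance_from_connectivity()] and [sample_conformations()]).
#'
#' @param offdiag numeric `N x N` symmetric matrix of couplings `k_ij`
#'   (dimensionless in model units, `nm^-2` when distances are in nm). The
#'   diagonal is ignored.
#' @return numeric `N x N` connectivity matrix with zero row sums.
#' @seealso [covariance_from_connectivity()], [mean_sq_distances()],
#'   [connectivity_from_distances()]
#' @examples
#' K <- assemble_connectivity(matrix(c(0, 1, 1, 0), 2))
#' rowSums(K)  # exactly zero
#' @export
assemble_connectivity <- function(offdiag) {
  offdiag <- .check_square(offdiag, "offdiag")
  if (!all(is.finite(offdiag))) {
    stop("offdiag contains non-finite couplings", call. = FALSE)
  }
  .check_symmetric(offdiag, "offdiag")
  K <- (offdiag + t(offdiag)) / 2
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  K
}

#' Covariance matrix of the maximum-entropy distribution
#'
#' The per-dimension coordinate covariance of the model is
#' `Sigma = -K^+`, the negated Moore-Penrose pseudoinverse of the
#' connectivity matrix. The pseudoinverse is taken over the non-null modes;
#' eigenvalues of magnitude below `rtol * max(|eigenvalue|)` are treated as
#' the zero (center-of-mass) mode. `Sigma` is positive semidefinite with
#' zero row sums (same gauge as `K`).
#'
#' @param K connectivity matrix as built by [assemble_connectivity()] (zero
#'   row sums, negative semidefinite).
#' @param rtol relative tolerance separating zero modes from genuine modes,
#'   and allowed slack on positive eigenvalues.
#' @return numeric `N x N` covariance matrix `Sigma` (units `nm^2` when `K`
#'   is in `nm^-2`).
#' @export
covariance_from_connectivity <- function(K, rtol = 1e-10) {
  K <- .check_connectivity(K)
  e <- eigen(K, symmetric = TRUE)
  w <- e$values
  scale <- max(abs(w))
  if (scale == 0) {
    stop("degenerate model: K is the zero matrix (no valid pseudoinverse gauge)",
         call. = FALSE)
  }
  if (w[1] > rtol * scale) {
    stop(sprintf("invalid connectivity: K has a positive eigenvalue (%.6g)", w[1]),
         call. = FALSE)
  }
  nonzero <- abs(w) > rtol * scale
  winv <- ifelse(nonzero, 1 / w, 0)
  sigma <- -(e$vectors %*% (winv * t(e$vectors)))
  (sigma + t(sigma)) / 2
}

#' Mean squared distance matrix of the model
#'
#' Converts the coordinate covariance into the matrix of mean squared
#' pairwise distances: `<r_ij^2> = 3 * (Sigma_ii + Sigma_jj - 2 Sigma_ij)`,
#' the factor 3 accounting for the three independent spatial dimensions.
#'
#' @param sigma covariance matrix from [covariance_from_connectivity()].
#' @return symmetric nonnegative matrix with zero diagonal, units `nm^2`.
#' @export
mean_sq_distances <- function(sigma) {
  sigma <- .check_square(sigma, "sigma")
  s <- diag(sigma)
  d2 <- 3 * (outer(s, s, "+") - 2 * sigma)
  d2[d2 < 0] <- 0  # clip numerical negatives
  d2 <- (d2 + t(d2)) / 2
  diag(d2) <- 0
  d2
}

#' Connectivity matrix directly from a distance matrix
#'
#' Inverts the model algebra without optimization: the target squared
#' distances are Gromov double-centered under the zero-row-sum gauge to
#' recover `Sigma` (`Sigma = -J (d2/3) J / 2` with `J = I - 11'/N`), and the
#' connectivity follows as `K = -Sigma^+`. This is exact when the distance
#' matrix is model-realizable (centered matrix positive semidefinite); for
#' noisy or inconsistent targets the fitting route
#' ([fit_iterative_scaling()]) is recommended instead.
#'
#' @param d2 complete symmetric squared-distance matrix (no `NA`), zero
#'   diagonal.
#' @param project_psd if `TRUE`, negative eigenvalues of the centered matrix
#'   are clipped to zero with a warning; if `FALSE` (default) they raise an
#'   error.
#' @param rtol relative eigenvalue tolerance.
#' @return connectivity matrix `K`.
#' @export
connectivity_from_distances <- function(d2, project_psd = FALSE, rtol = 1e-10) {
  d2 <- .check_d2(d2, require_complete = TRUE)
  n <- nrow(d2)
  omega2 <- d2 / 3
  ## double centering under the center-of-mass gauge
  J <- diag(n) - matrix(1 / n, n, n)
  sigma <- -0.5 * J %*% omega2 %*% J
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  w <- e$values
  scale <- max(abs(w))
  if (scale == 0) stop("degenerate distance matrix (all zero)", call. = FALSE)
  if (min(w) < -rtol * scale) {
    if (!project_psd) {
      stop(sprintf(
        "non-realizable distance matrix: centered matrix has negative eigenvalue (%.6g); set project_psd = TRUE to clip",
        min(w)), call. = FALSE)
    }
    warning(sprintf("clipping %d negative eigenvalue(s) of the centered matrix to zero",
                    sum(w < -rtol * scale)))
    w[w < 0] <- 0
  }
  nonzero <- abs(w) > rtol * scale
  winv <- ifelse(nonzero, 1 / w, 0)
  K <- -(e$vectors %*% (winv * t(e$vectors)))
  K <- (K + t(K)) / 2
  ## restore the exact zero-row-sum structure
  offdiag <- K
  diag(offdiag) <- 0
  assemble_connectivity(offdiag)
}

## ---- internal validation helpers ----

.check_square <- function(m, name) {
  m <- as.matrix(m)
  if (!is.numeric(m) || nrow(m) != ncol(m) || nrow(m) < 2) {
    stop(sprintf("%s must be a square numeric matrix with N >= 2", name),
         call. = FALSE)
  }
  m
}

.check_symmetric <- function(m, name, tol = 1e-8) {
  ref <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > tol * ref) {
    stop(sprintf("%s must be symmetric", name), call. = FALSE)
  }
  invisible(m)
}

.check_connectivity <- function(K, tol = 1e-8) {
  K <- .check_square(K, "K")
  if (!all(is.finite(K))) stop("K contains non-finite values", call. = FALSE)
  .check_symmetric(K, "K")
  ref <- max(abs(K), 1e-300)
  if (max(abs(rowSums(K))) > tol * ref * nrow(K)) {
    stop("K rows must sum to zero; use assemble_connectivity()", call. = FALSE)
  }
  K
}

.check_d2 <- function(d2, require_complete = FALSE) {
  d2 <- .check_square(d2, "d2")
  if (require_complete && anyNA(d2)) {
    stop("d2 must be complete (no missing entries) for this operation",
         call. = FALSE)
  }
  obs <- !is.na(d2)
  if (any(d2[obs] < 0)) stop("d2 must be nonnegative", call. = FALSE)
  m <- d2
  m[is.na(m)] <- 0
  .check_symmetric(m, "d2")
  if (any(is.na(diag(d2))) || any(abs(diag(d2)) > 1e-8 * max(d2[obs], 1e-300))) {
    stop("d2 must have an observed zero diagonal", call. = FALSE)
  }
  d2
}

## adjacency components by breadth-first search; adj is a logical matrix
.graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
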