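# Structural-variant perturbations of the fitted model: segment inversion
# (an index permutation of the couplings), single-locus deletion, the
# perturbation index quantifying the induced change in mean distances, and
# predicted contact maps for edited models.

#' Invert a genomic segment
#'
#' An inversion of loci `[a, b]` permutes the coupling table by the
#' index-reversing permutation on that range: `k'_ij = k_sigma(i),sigma(j)`.
#' The diagonal is reassembled, and because the edit is a permutation
#' similarity the eigenvalues (hence negative semidefiniteness) are
#' preserved exactly. Applying the same inversion twice restores `K`.
#'
#' @param K connectivity matrix.
#' @param segment integer range `c(a, b)` (1-based, `a < b`).
#' @return edited connectivity matrix.
#' @export
invert_segment <- function(K, segment) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  segment <- as.integer(segment)
  if (length(segment) != 2 || segment[1] < 1 || segment[2] > n ||
      segment[1] >= segment[2]) {
    stop("segment must be c(a, b) with 1 <= a < b <= N", call. = FALSE)
  }
  perm <- seq_len(n)
  perm[segment[1]:segment[2]] <- rev(perm[segment[1]:segment[2]])
  od <- K[perm, perm]
  diag(od) <- 0
  assemble_connectivity(od)
}

#' Delete a single locus
#'
#' Removes row and column `i` from the coupling table and reassembles the
#' diagonal, shrinking the model to `N - 1` loci. If removing the locus
#' disconnects the coupling graph the deletion is rejected (the reduced
#' model would no longer define distances between the components).
#'
#' Note this is the "cut the springs" semantics: it differs from Gaussian
#' marginalization of the locus (which keeps effective couplings through the
#' deleted locus) except when the locus is a leaf of the coupling graph.
#'
#' @param K connectivity matrix (`N >= 3`).
#' @param i locus index to delete.
#' @return connectivity matrix of size `(N-1) x (N-1)`.
#' @export
delete_locus <- function(K, i) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  if (n < 3) stop("need N >= 3 to delete a locus", call. = FALSE)
  i <- as.integer(i)
  if (i < 1 || i > n) stop("locus index out of range", call. = FALSE)
  keep <- setdiff(seq_len(n), i)
  od <- K[keep, keep]
  diag(od) <- 0
  adj <- od != 0
  comp <- .graph_components(adj | diag(TRUE, n - 1L))
  if (max(comp) > 1L) {
    stop(sprintf(
      "deleting locus %d disconnects the model (%d components: %s)",
      i, max(comp), paste(tapply(keep, comp, function(x)
        paste0("{", paste(range(x), collapse = "-"), "}")), collapse = " ")),
      call. = FALSE)
  }
  assemble_connectivity(od)
}

#' Perturbation index between two mean distance matrices
#'
#' `PI = sqrt( sum_{i<j} (<r~_ij> - <r_ij>)^2 / sum_{i<j} <r~_ij>^2 )` where
#' `<r~>` is the wild-type mean distance matrix and `<r>` the edited one.
#' The inputs are distances (not squared distances). PI is zero for
#' identical maps, nonnegative, and invariant under rescaling both maps by
#' the same factor.
#'
#' @param d_wt,d_mut `N x N` mean distance matrices (same size; `NA` entries
#'   in either are dropped pairwise).
#' @param pair_subset optional logical matrix selecting the pairs to score.
#' @return nonnegative scalar.
#' @export
perturbation_index <- function(d_wt, d_mut, pair_subset = NULL) {
  d_wt <- .check_square(d_wt, "d_wt")
  d_mut <- .check_square(d_mut, "d_mut")
  if (!all(dim(d_wt) == dim(d_mut))) stop("dimension mismatch", call. = FALSE)
  use <- upper.tri(d_wt) & !is.na(d_wt) & !is.na(d_mut)
  if (!is.null(pair_subset)) use <- use & pair_subset
  if (!any(use)) stop("empty pair subset", call. = FALSE)
  sqrt(sum((d_wt[use] - d_mut[use])^2) / sum(d_wt[use]^2))
}

#' Per-locus deletion perturbation profile
#'
#' For every locus: delete it, recompute the model's mean distances
#' analytically, and score the change against the wild type with
#' [perturbation_index()] restricted to the surviving pairs. Loci whose
#' deletion would disconnect the model — or leave it non-semidefinite,
#' which can happen when negative couplings are present — report `NA`.
#'
#' @param K connectivity matrix.
#' @return numeric vector of per-locus PI values.
#' @export
pi_deletion_profile <- function(K) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  d_wt <- sqrt(mean_sq_distances(covariance_from_connectivity(K)))
  vapply(seq_len(n), function(i) {
    d_mut <- tryCatch(
      sqrt(mean_sq_distances(covariance_from_connectivity(delete_locus(K, i)))),
      error = function(e) NULL)
    if (is.null(d_mut)) return(NA_real_)
    keep <- setdiff(seq_len(n), i)
    perturbation_index(d_wt[keep, keep], d_mut)
  }, numeric(1))
}

#' Predicted contact map for a structural variant
#'
#' Applies a list of edits to the connectivity matrix, recomputes the mean
#' distances analytically, and converts them to a contact map with the
#' power-law relation of [contacts_from_distances()]. Each edit is a list
#' with `op` (`"invert"` or `"delete"`) and locus indices (`start`/`end` for
#' inversions, `locus` for deletions); edits apply in order. Duplications
#' and insertions change the locus set in ways a coupling edit cannot
#' express and are rejected: refit the model to the mutated contact or
#' distance map instead.
#'
#' @param K wild-type connectivity matrix.
#' @param edits list of edit specs (empty list = wild-type round trip).
#' @param lambda_scale,alpha conversion parameters
#'   (see [contacts_from_distances()]).
#' @return contact-probability matrix for the edited model.
#' @export
predict_variant_contact_map <- function(K, edits = list(), lambda_scale = 1,
                                        alpha = 4) {
  K <- .check_connectivity(K)
  for (e in edits) {
    op <- e$op
    if (is.null(op)) stop("each edit needs an 'op' field", call. = FALSE)
    K <- switch(op,
      invert = invert_segment(K, c(e$start, e$end)),
      delete = delete_locus(K, e$locus),
      duplicate = ,
      insert = stop(sprintf(
        "edit '%s' changes the locus set; refit the model to the mutated contact or distance map instead",
        op), call. = FALSE),
      stop(sprintf("unknown edit op '%s'", op), call. = FALSE)
    )
  }
  d2 <- mean_sq_distances(covariance_from_connectivity(K))
  suppressWarnings(contacts_from_distances(d2, lambda_scale, alpha))
}

## Gaussian-marginalization alternative to delete_locus(): integrate the
## locus out of the distribution instead of cutting its couplings. Kept
## internal as a cross-check oracle; equals delete_locus() only for leaves.
.marginalize_locus_d2 <- function(K, i) {
  sigma <- covariance_from_connectivity(K)
  keep <- setdiff(seq_len(nrow(K)), i)
  mean_sq_distances(sigma[keep, keep])
}
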