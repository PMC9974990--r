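# Contact-probability <-> spatial-distance conversion and its calibration.
#
# Contact probabilities p_ij and mean distances are related by the power law
# <r_ij> = Lambda * p_ij^(-1/alpha): alpha controls the decay, Lambda sets
# the physical length scale. alpha = 4 is the default when it cannot be
# determined experimentally; Lambda = 1 yields structures in model units
# that can simply be rescaled afterwards.

#' Squared distances from a contact map
#'
#' Applies `<r_ij^2> = (Lambda * p_ij^(-1/alpha))^2` entrywise. Raw count
#' matrices are first normalized by their maximum off-diagonal entry (pass
#' `normalize = TRUE`); zero-probability pairs cannot be converted and are
#' returned as `NA`.
#'
#' @param p symmetric matrix of contact probabilities in `[0, 1]` (or raw
#'   counts with `normalize = TRUE`).
#' @param lambda_scale length scale `Lambda` (> 0), in the distance unit of
#'   the analysis (nm or um).
#' @param alpha power-law exponent (> 0), default 4.
#' @param normalize divide by the maximum off-diagonal entry before
#'   converting (for raw-count input).
#' @return squared-distance matrix, `NA` where `p_ij = 0`.
#' @export
distances_from_contacts <- function(p, lambda_scale = 1, alpha = 4,
                                    normalize = FALSE) {
  p <- .check_contacts(p, normalize = normalize)
  .check_conversion(lambda_scale, alpha)
  d2 <- (lambda_scale * p^(-1 / alpha))^2
  d2[p == 0] <- NA
  diag(d2) <- 0
  (d2 + t(d2)) / 2
}

#' Contact map from squared distances
#'
#' Inverse of [distances_from_contacts()]: `p_ij = (sqrt(d2_ij)/Lambda)^(-alpha)`,
#' capped at 1 (pairs closer than `Lambda` are in certain contact). The
#' diagonal is set to 1 by convention. Zero off-diagonal distances are
#' capped with a warning.
#'
#' @param d2 squared-distance matrix (`NA` entries propagate).
#' @inheritParams distances_from_contacts
#' @return contact-probability matrix in `[0, 1]`.
#' @export
contacts_from_distances <- function(d2, lambda_scale = 1, alpha = 4) {
  d2 <- .check_d2(d2)
  .check_conversion(lambda_scale, alpha)
  zero_off <- d2 == 0 & !diag(TRUE, nrow(d2))
  if (any(zero_off, na.rm = TRUE)) {
    warning("zero off-diagonal distances capped at contact probability 1")
  }
  p <- (sqrt(d2) / lambda_scale)^(-alpha)
  p[p > 1] <- 1
  diag(p) <- 1
  (p + t(p)) / 2
}

#' Calibrate the contact-to-distance conversion
#'
#' Finds `(Lambda, alpha)` minimizing the mean squared deviation between
#' distances converted from the contact map and a reference mean distance
#' matrix: `chi = (2/(N(N-1))) * sum_{i<j} (r_converted - r_reference)^2`.
#' Note the objective is on distances, not squared distances.
#'
#' The search is deterministic: for each `alpha` on a log-spaced grid over
#' `[2, 8]` the optimal `Lambda` is available in closed form (linear
#' least squares in `Lambda`), and the grid is refined twice around the best
#' `alpha`.
#'
#' @param p contact map (probabilities).
#' @param d2_ref reference squared-distance matrix (`NA` allowed; at least
#'   10 overlapping informative pairs required).
#' @param alpha_range search interval for `alpha` (default `c(2, 8)`).
#' @param grid_size points per grid pass (default 61).
#' @return list with `lambda_scale`, `alpha`, and the attained `chi`.
#' @export
calibrate_conversion <- function(p, d2_ref, alpha_range = c(2, 8),
                                 grid_size = 61) {
  p <- .check_contacts(p)
  d2_ref <- .check_d2(d2_ref)
  if (!all(dim(p) == dim(d2_ref))) stop("dimension mismatch", call. = FALSE)
  ut <- upper.tri(p)
  use <- ut & !is.na(d2_ref) & p > 0
  if (sum(use) < 10) {
    stop("need at least 10 overlapping observed pairs to calibrate",
         call. = FALSE)
  }
  pv <- p[use]
  rv <- sqrt(d2_ref[use])
  if (max(pv) - min(pv) < 1e-12) {
    stop("unidentifiable calibration: contact map is constant on observed pairs",
         call. = FALSE)
  }
  obj <- function(alpha) {
    q <- pv^(-1 / alpha)
    lam <- sum(q * rv) / sum(q * q)   # closed-form optimal Lambda
    list(lambda = lam, chi = mean((lam * q - rv)^2))
  }
  lo <- log(alpha_range[1]); hi <- log(alpha_range[2])
  best <- NULL
  for (pass in 1:3) {
    alphas <- exp(seq(lo, hi, length.out = grid_size))
    res <- lapply(alphas, obj)
    chis <- vapply(res, `[[`, numeric(1), "chi")
    i <- which.min(chis)
    best <- list(lambda_scale = res[[i]]$lambda, alpha = alphas[i],
                 chi = chis[i])
    step <- (hi - lo) / (grid_size - 1)
    lo <- log(best$alpha) - step
    hi <- log(best$alpha) + step
  }
  best
}

.check_contacts <- function(p, normalize = FALSE) {
  p <- .check_square(p, "p")
  .check_symmetric(p, "p")
  if (any(p < 0, na.rm = TRUE)) stop("contact values must be nonnegative",
                                     call. = FALSE)
  if (normalize) {
    od <- p
    diag(od) <- NA
    mx <- max(od, na.rm = TRUE)
    if (mx <= 0) stop("cannot normalize an all-zero contact map", call. = FALSE)
    p <- p / mx
    p[p > 1] <- 1
  } else if (any(p > 1, na.rm = TRUE)) {
    stop("contact probabilities must lie in [0, 1]; raw counts need normalize = TRUE",
         call. = FALSE)
  }
  diag(p) <- 1
  p
}

.check_conversion <- function(lambda_scale, alpha) {
  if (!is.numeric(lambda_scale) || lambda_scale <= 0) {
    stop("lambda_scale must be > 0", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  invisible(NULL)
}
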