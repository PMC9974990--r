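# Fitting the connectivity matrix to a target mean squared distance matrix.
#
# Both optimizers exploit the Gaussian structure: at each step the model's
# mean squared distances are computed analytically from Sigma = -K^+, then
# the couplings are updated multiplicatively in log-ratio space (iterative
# scaling) or by the raw residual (gradient descent). Missing target entries
# (NA, or an explicit mask) are never used to update their coupling.

#' Fit by iterative scaling
#'
#' Updates each coupling as
#' `k_ij(t+1) = k_ij(t) + gamma / sum_{i<j} <r_ij^2>(t) * log(<r_ij^2>(t) / a_ij)`
#' where `a_ij` is the target squared distance. The constant learning rate
#' `gamma = 10` gives good convergence while remaining stable; the update is
#' scale-invariant (rescaling all distances rescales the couplings exactly
#' inversely), so the same `gamma` works in nm or model units.
#'
#' Convergence is declared when the relative mean absolute error
#' `mean(|<r^2> - a|) / mean(a)` over unmasked pairs drops below `tol`. If
#' the error grows to ten times its running minimum the fit aborts with an
#' error carrying the trace. After each update the connectivity matrix is
#' kept negative semidefinite by clipping any positive eigenvalues to zero
#' in the eigenbasis (which preserves the zero-row-sum gauge).
#'
#' @param target symmetric matrix of target mean squared distances `a_ij`
#'   (`nm^2`); off-diagonal entries must be positive where observed. `NA`
#'   entries are treated as missing and frozen (see [fit_with_mask()]).
#' @param gamma learning rate (default 10).
#' @param max_iter maximum number of iterations.
#' @param tol relative convergence threshold (default 1e-2).
#' @param init initialization: `"ideal_chain"` (nearest-neighbour couplings
#'   scaled so the model's mean squared distance matches the target's mean),
#'   `"direct_inversion"` ([connectivity_from_distances()] with PSD
#'   projection), or `"user"` (supply `k0`).
#' @param k0 user-supplied initial connectivity matrix (for `init = "user"`).
#' @param mask optional logical matrix, `TRUE` marking pairs to exclude from
#'   fitting (combined with `is.na(target)`).
#' @return an object of class `dimes_fit`: a list with elements
#'   `connectivity` (the fitted `K`), `fitted_d2` (the model's full squared
#'   distance matrix), `error_trace`, `converged`, `n_iter`, `method`, and
#'   `mask` (logical matrix of frozen pairs, or `NULL`).
#' @references none
#' @seealso [fit_gradient_descent()], [fit_with_mask()], [model_error()]
#' @export
fit_iterative_scaling <- function(target, gamma = 10, max_iter = 10000,
                                  tol = 1e-2, init = c("ideal_chain",
                                                       "direct_inversion",
                                                       "user"),
                                  k0 = NULL, mask = NULL) {
  .fit_engine(target, method = "iterative_scaling", gamma = gamma,
              max_iter = max_iter, tol = tol, ridge = 0,
              init = match.arg(init), k0 = k0, mask = mask)
}

#' Fit by gradient descent
#'
#' Gradient descent on the maximum-entropy dual objective
#' `ln Z(k) + sum k_ij a_ij`, whose gradient in each coupling is
#' `a_ij - <r_ij^2>(t)`; the update is therefore
#' `k_ij(t+1) = k_ij(t) + gamma * (<r_ij^2>(t) - a_ij)`: a model that is
#' too extended on a pair tightens that coupling, one that is too compact
#' relaxes it (the same orientation as the iterative-scaling update). An
#' optional ridge penalty `ridge * sum k_ij^2` on the objective contributes
#' `-2 * gamma * ridge * k_ij` shrinkage to the update.
#'
#' Unlike iterative scaling the learning rate carries units
#' (`nm^-2` per `nm^2`) and its stable range shrinks with problem size; the
#' default `1 / (P * mean(a)^2)`, with `P` the number of observed pairs, is
#' scale-aware and conservative. Iterative scaling is the recommended
#' optimizer; gradient descent mainly serves as an independent cross-check
#' and as the route that admits regularization.
#'
#' @inheritParams fit_iterative_scaling
#' @param gamma learning rate; `NULL` (default) selects
#'   `1 / (P * mean(a_ij)^2)`.
#' @param ridge ridge regularization weight `lambda >= 0` (default 0).
#' @return a `dimes_fit` object; see [fit_iterative_scaling()].
#' @export
fit_gradient_descent <- function(target, gamma = NULL, max_iter = 10000,
                                 tol = 1e-2, ridge = 0,
                                 init = c("ideal_chain", "direct_inversion",
                                          "user"),
                                 k0 = NULL, mask = NULL) {
  .fit_engine(target, method = "gradient_descent", gamma = gamma,
              max_iter = max_iter, tol = tol, ridge = ridge,
              init = match.arg(init), k0 = k0, mask = mask)
}

#' Fit with missing data and predict the held-out distances
#'
#' Pairs flagged missing (`NA` in `target` or `TRUE` in `mask`) never update
#' their coupling: they stay frozen at the initialization value (the
#' ideal-chain initialization guarantees the model stays connected through
#' the backbone). After convergence the fitted model's analytic distance
#' matrix provides predictions for every pair, including the held-out ones.
#'
#' @inheritParams fit_iterative_scaling
#' @param method `"iterative_scaling"` (default) or `"gradient_descent"`.
#' @param ... further arguments passed to the chosen fitter.
#' @return a `dimes_fit` object whose `fitted_d2` element contains the full
#'   predicted squared-distance matrix (read off held-out predictions there).
#' @export
fit_with_mask <- function(target, mask = NULL,
                          method = c("iterative_scaling", "gradient_descent"),
                          ...) {
  method <- match.arg(method)
  if (method == "iterative_scaling") {
    fit_iterative_scaling(target, mask = mask, ...)
  } else {
    fit_gradient_descent(target, mask = mask, ...)
  }
}

#' Relative model-vs-target error
#'
#' Mean over unmasked pairs `i < j` of `|<r_ij^2> - a_ij|`, divided by the
#' mean target value: the convergence metric used by the fitters. The
#' measure is zero iff the model matches the target exactly on unmasked
#' entries, and is not symmetric under swapping the roles of model and
#' target (the normalization is by the target scale).
#'
#' @param K connectivity matrix.
#' @param target target squared-distance matrix (`NA` = excluded).
#' @param mask optional logical matrix of additional exclusions.
#' @return nonnegative scalar.
#' @export
model_error <- function(K, target, mask = NULL) {
  target <- .check_d2(target)
  obs <- .observed_pairs(target, mask)
  d2 <- mean_sq_distances(covariance_from_connectivity(K))
  mean(abs(d2[obs] - target[obs])) / mean(target[obs])
}

#' @export
print.dimes_fit <- function(x, ...) {
  cat(sprintf("dimes fit (%s): N = %d loci, %d iterations, %s\n",
              x$method, nrow(x$connectivity), x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  final relative error: %.4g\n", tail(x$error_trace, 1)))
  if (!is.null(x$mask)) {
    cat(sprintf("  masked pairs: %d of %d\n",
                sum(x$mask[upper.tri(x$mask)]),
                sum(upper.tri(x$mask))))
  }
  invisible(x)
}

## ---- internals ----

## logical matrix of observed (fit-driving) off-diagonal pairs
.observed_pairs <- function(target, mask = NULL) {
  obs <- !is.na(target)
  diag(obs) <- FALSE
  if (!is.null(mask)) {
    mask <- .check_square(mask * 1, "mask") > 0
    .check_symmetric(mask * 1, "mask")
    obs <- obs & !mask
  }
  obs
}

.fit_engine <- function(target, method, gamma, max_iter, tol, ridge, init,
                        k0, mask) {
  target <- .check_d2(target)
  n <- nrow(target)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  obs <- .observed_pairs(target, mask)
  if (!any(obs)) stop("no observed pairs to fit", call. = FALSE)
  if (any(target[obs] <= 0)) {
    stop("target must be strictly positive on observed off-diagonal pairs",
         call. = FALSE)
  }
  ## identifiability: observed pairs must form a connected graph
  comp <- .graph_components(obs | diag(TRUE, n))
  if (max(comp) > 1L) {
    stop(sprintf(
      "unidentifiable: observed pairs leave the loci graph disconnected (%d components: %s)",
      max(comp), paste(tapply(seq_len(n), comp, function(i)
        paste0("{", paste(range(i), collapse = "-"), "}")), collapse = " ")),
      call. = FALSE)
  }
  mean_a <- mean(target[obs])
  if (is.null(gamma)) {
    gamma <- if (method == "iterative_scaling") 10
             else 1 / (sum(obs) / 2 * mean_a^2)
  }
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)

  K <- switch(init,
    ideal_chain = {
      sep <- abs(row(target) - col(target))
      kchain <- 3 * mean(sep[upper.tri(sep)]) / mean_a
      od <- matrix(0, n, n)
      idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
      od[idx] <- kchain
      od[idx[, 2:1]] <- kchain
      assemble_connectivity(od)
    },
    direct_inversion = {
      full <- target
      if (anyNA(full)) {
        stop("init = 'direct_inversion' requires a complete target",
             call. = FALSE)
      }
      suppressWarnings(connectivity_from_distances(full, project_psd = TRUE))
    },
    user = .check_connectivity(k0)
  )

  ut <- upper.tri(target)
  obs_ut <- obs & ut
  trace <- numeric(max_iter)
  converged <- FALSE
  n_iter <- 0L
  d2 <- NULL
  for (t in seq_len(max_iter)) {
    sk <- .sigma_with_repair(K)
    K <- sk$K
    d2 <- mean_sq_distances(sk$sigma)
    err <- mean(abs(d2[obs] - target[obs])) / mean_a
    n_iter <- t
    trace[t] <- err
    if (err <= tol) {
      converged <- TRUE
      break
    }
    if (err > 10 * min(trace[seq_len(t)]) && t > 1) {
      cond <- simpleError(sprintf(
        "fit diverged at iteration %d (error %.4g, minimum %.4g)",
        t, err, min(trace[seq_len(t)])))
      cond$error_trace <- trace[seq_len(t)]
      stop(cond)
    }
    delta <- if (method == "iterative_scaling") {
      (gamma / sum(d2[ut])) * log(d2[obs_ut] / target[obs_ut])
    } else {
      gamma * (d2[obs_ut] - target[obs_ut]) - 2 * gamma * ridge * K[obs_ut]
    }
    if (any(!is.finite(delta))) {
      cond <- simpleError(sprintf(
        "fit diverged at iteration %d (non-finite update: the model collapsed on some pairs; reduce gamma)",
        t))
      cond$error_trace <- trace[seq_len(t)]
      stop(cond)
    }
    od <- K
    diag(od) <- 0
    od[obs_ut] <- od[obs_ut] + delta
    od[lower.tri(od)] <- t(od)[lower.tri(od)]
    K <- assemble_connectivity(od)
  }

  if (!converged) {
    ## final K was updated after the last error evaluation; re-sync
    sk <- .sigma_with_repair(K)
    K <- sk$K
    d2 <- mean_sq_distances(sk$sigma)
  }

  structure(list(
    connectivity = K,
    fitted_d2 = d2,
    error_trace = trace[seq_len(n_iter)],
    converged = converged,
    n_iter = n_iter,
    method = method,
    gamma = gamma,
    tol = tol,
    mask = if (anyNA(target) || !is.null(mask)) !obs | diag(TRUE, n) else NULL
  ), class = "dimes_fit")
}

## Sigma = -K^+ via the Laplacian shift identity (fast Cholesky path); on
## failure, eigendecompose and clip positive eigenvalues (NSD repair).
.sigma_with_repair <- function(K, rtol = 1e-10) {
  n <- nrow(K)
  P <- matrix(1 / n, n, n)
  A <- -K + P
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    sigma <- chol2inv(ch) - P
    return(list(sigma = (sigma + t(sigma)) / 2, K = K))
  }
  e <- eigen(K, symmetric = TRUE)
  w <- e$values
  scale <- max(abs(w))
  if (scale == 0) stop("degenerate model: K is zero during fitting", call. = FALSE)
  pos <- w > rtol * scale
  if (any(pos)) {
    w[pos] <- 0
    K <- e$vectors %*% (w * t(e$vectors))
    K <- (K + t(K)) / 2
    od <- K
    diag(od) <- 0
    K <- assemble_connectivity(od)
  }
  nonzero <- abs(w) > rtol * scale
  winv <- ifelse(nonzero, 1 / w, 0)
  sigma <- -(e$vectors %*% (winv * t(e$vectors)))
  list(sigma = (sigma + t(sigma)) / 2, K = K)
}
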