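# Independent oracles used across the suite. These deliberately re-derive
# quantities by exhaustive loops or closed forms, never through the package
# functions they are checking.

# random connected negative-semidefinite connectivity matrix: a chain plus
# random extra positive couplings (positive couplings keep -K a graph
# Laplacian, hence PSD, by construction)
random_connected_K <- function(n, seed, extra_density = 0.3) {
  set.seed(seed)
  od <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    od[i, i + 1] <- od[i + 1, i] <- runif(1, 0.5, 2)
  }
  extra <- which(upper.tri(od) & abs(row(od) - col(od)) > 1)
  pick <- extra[runif(length(extra)) < extra_density]
  od[pick] <- runif(length(pick), 0, 0.5)
  od[lower.tri(od)] <- t(od)[lower.tri(od)]
  assemble_connectivity(od)
}

# resistance distance of a uniform nearest-neighbour chain: |i - j| / k
chain_resistance_d2 <- function(n, k) {
  3 * abs(outer(seq_len(n), seq_len(n), "-")) / k
}

# brute-force triplet co-localization over explicit loops
brute_pi <- function(ens, a) {
  n <- dim(ens)[2]
  out <- NULL
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cnt <- 0L
    for (m in seq_len(dim(ens)[1])) {
      rij <- sqrt(sum((ens[m, i, ] - ens[m, j, ])^2))
      rik <- sqrt(sum((ens[m, i, ] - ens[m, k, ])^2))
      rjk <- sqrt(sum((ens[m, j, ] - ens[m, k, ])^2))
      if (rij < a && rik < a && rjk < a) cnt <- cnt + 1L
    }
    out <- rbind(out, data.frame(i = i, j = j, k = k,
                                 pi = cnt / dim(ens)[1]))
  }
  out
}

# brute-force Z-scores grouped by the gap product, population sd
brute_z <- function(pi_df) {
  g <- abs(pi_df$j - pi_df$i) * abs(pi_df$k - pi_df$j)
  z <- numeric(nrow(pi_df))
  for (r in seq_len(nrow(pi_df))) {
    grp <- pi_df$pi[g == g[r]]
    mu <- mean(grp)
    sdv <- sqrt(mean((grp - mu)^2))
    z[r] <- if (sdv == 0) 0 else (pi_df$pi[r] - mu) / sdv
  }
  z
}

# brute-force Q_k / F_k for one conformation by explicit sorting
brute_qf <- function(xyz, labels, k) {
  n <- nrow(xyz)
  nA <- sum(labels == "A"); nB <- sum(labels == "B")
  ntA <- k * nA / n; ntB <- k * nB / n
  f0 <- 0.5 * (1 + k / 2)
  q <- 0; fsum <- 0
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    q <- q + abs(sum(labels[nb] == "A") / ntA - sum(labels[nb] == "B") / ntB)
    fsum <- fsum + sum(abs(nb - i))
  }
  c(Q = q / n, F = fsum / (k * n * f0))
}

# chromatin-like connectivity with smooth genomic-distance decay of the
# couplings, compartment modulation, and mild jitter: the regular structure
# real fitted coupling profiles show, used for held-out-prediction tests
smooth_copolymer_K <- function(n, seed, block = 8L) {
  set.seed(seed)
  s <- abs(outer(seq_len(n), seq_len(n), "-"))
  labels <- rep(rep(c("A", "B"), each = block), length.out = n)
  same <- outer(labels, labels, "==")
  jit <- matrix(exp(rnorm(n * n, 0, 0.05)), n)
  jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
  od <- 0.05 / (1 + (s - 1))^1.5 * ifelse(same, 1.5, 0.5) * jit
  od[s == 1] <- 1
  diag(od) <- 0
  od[lower.tri(od)] <- t(od)[lower.tri(od)]
  assemble_connectivity(od)
}

# a rigid-body transform (rotation about a random axis + translation)
rigid_transform <- function(ens, seed = 99) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
              c(sin(ang[2]), cos(ang[2]), 0), c(0, 0, 1))
  R <- Rx %*% Rz
  shift <- runif(3, -50, 50)
  out <- ens
  for (m in seq_len(dim(ens)[1])) {
    out[m, , ] <- ens[m, , ] %*% t(R) + matrix(shift, dim(ens)[2], 3,
                                               byrow = TRUE)
  }
  out
}
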