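# Ensemble statistics: pairwise distance distributions and Jensen-Shannon
# divergence, triplet co-localization probabilities and Z-scores, gyration
# radius / shape anisotropy, single-cell domain boundary probabilities, the
# conformation-space metric with clustering, and the A/B mixing (Q_k) and
# long-range interaction (F_k) metrics.

#' Per-pair distance histograms
#'
#' Histograms the Euclidean distance of every locus pair over the ensemble,
#' on a common set of bin edges. If `breaks` is not supplied, edges are
#' placed with the Freedman-Diaconis rule on all pooled distances.
#'
#' @param ens `M x N x 3` coordinate array.
#' @param breaks numeric vector of bin edges (optional).
#' @return list with `breaks` and `prob`, a `P x nbin` matrix of bin
#'   probabilities (rows indexed by the pair list in `pairs`).
#' @export
distance_distributions <- function(ens, breaks = NULL) {
  ens <- .check_ensemble(ens)
  if (dim(ens)[1] < 2) stop("need at least 2 conformations", call. = FALSE)
  n <- dim(ens)[2]
  dm <- .pair_distance_matrix(ens)        # P x M, rows = pairs i<j
  if (is.null(breaks)) breaks <- .fd_breaks(as.vector(dm))
  prob <- t(apply(dm, 1, .hist_prob, breaks = breaks))
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  list(breaks = breaks, prob = prob,
       pairs = data.frame(i = pairs[, 1], j = pairs[, 2]))
}

#' Jensen-Shannon divergence between two histogram sets
#'
#' `JSD(p, q) = (KL(p||m) + KL(q||m)) / 2` with `m = (p + q)/2`, logarithms
#' base 2 so the divergence lies in `[0, 1]` (0 for identical
#' distributions, 1 for disjoint supports). Empty bins follow the
#' `0 * log 0 = 0` convention. Both sets must share bin edges.
#'
#' @param p_hist,q_hist outputs of [distance_distributions()] on the same
#'   `breaks`.
#' @return symmetric `N x N` matrix of per-pair JSD values (diagonal `NA`).
#' @export
jsd_matrix <- function(p_hist, q_hist) {
  if (!isTRUE(all.equal(p_hist$breaks, q_hist$breaks))) {
    stop("histograms must share identical bin edges", call. = FALSE)
  }
  if (nrow(p_hist$prob) != nrow(q_hist$prob)) {
    stop("histogram sets cover different numbers of pairs", call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(p_hist$prob)), function(r) {
    .jsd(p_hist$prob[r, ], q_hist$prob[r, ])
  }, numeric(1))
  n <- max(p_hist$pairs$j)
  out <- matrix(NA_real_, n, n)
  out[cbind(p_hist$pairs$i, p_hist$pairs$j)] <- vals
  out[cbind(p_hist$pairs$j, p_hist$pairs$i)] <- vals
  out
}

#' Per-pair JSD between two ensembles
#'
#' Convenience wrapper: for each pair, pools the distances from both
#' ensembles, bins them on shared Freedman-Diaconis edges, and computes the
#' base-2 Jensen-Shannon divergence.
#'
#' @param ens_p,ens_q `M x N x 3` coordinate arrays over the same loci.
#' @return symmetric `N x N` matrix of JSD values (diagonal `NA`).
#' @export
ensemble_jsd <- function(ens_p, ens_q) {
  ens_p <- .check_ensemble(ens_p); ens_q <- .check_ensemble(ens_q)
  if (dim(ens_p)[2] != dim(ens_q)[2]) stop("loci counts differ", call. = FALSE)
  n <- dim(ens_p)[2]
  dp <- .pair_distance_matrix(ens_p)
  dq <- .pair_distance_matrix(ens_q)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]
  out <- matrix(NA_real_, n, n)
  for (r in seq_len(nrow(pairs))) {
    x <- dp[r, ]; y <- dq[r, ]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) next
    breaks <- .fd_breaks(c(x, y))
    v <- .jsd(.hist_prob(x, breaks), .hist_prob(y, breaks))
    out[pairs[r, 1], pairs[r, 2]] <- v
    out[pairs[r, 2], pairs[r, 1]] <- v
  }
  out
}

#' Triplet co-localization probabilities
#'
#' For every triplet `i < j < k`, the fraction of conformations in which all
#' three mutual distances are below the contact threshold `a`:
#' `pi_ijk = Pr(r_ij < a, r_ik < a, r_jk < a)`. The threshold default of
#' 300 nm is where agreement with imaging data peaks for chromatin-scale
#' loci; it should be set to the distance scale of the system at hand.
#'
#' @param ens `M x N x 3` coordinate array (complete conformations).
#' @param a contact threshold (nm).
#' @return object of class `dimes_triplets`: data frame with columns `i`,
#'   `j`, `k`, `gap_product` (`|j-i| * |k-j|`), `pi`, plus attribute
#'   `threshold_a`.
#' @export
triplet_colocalization <- function(ens, a = 300) {
  ens <- .check_ensemble(ens)
  n <- dim(ens)[2]
  if (n < 3) stop("need at least 3 loci", call. = FALSE)
  m <- dim(ens)[1]
  trip <- t(utils::combn(n, 3))
  idx12 <- trip[, 1] + (trip[, 2] - 1L) * n
  idx13 <- trip[, 1] + (trip[, 3] - 1L) * n
  idx23 <- trip[, 2] + (trip[, 3] - 1L) * n
  counts <- numeric(nrow(trip))
  valid <- numeric(nrow(trip))
  for (cm in seq_len(m)) {
    D <- as.matrix(stats::dist(ens[cm, , ]))
    inc <- D < a
    v <- inc[idx12] & inc[idx13] & inc[idx23]
    ok <- !is.na(v)
    counts[ok] <- counts[ok] + v[ok]
    valid <- valid + ok
  }
  pi <- ifelse(valid > 0, counts / valid, NA_real_)
  out <- data.frame(i = trip[, 1], j = trip[, 2], k = trip[, 3],
                    gap_product = abs(trip[, 2] - trip[, 1]) *
                      abs(trip[, 3] - trip[, 2]),
                    pi = pi)
  attr(out, "threshold_a") <- a
  class(out) <- c("dimes_triplets", "data.frame")
  out
}

#' Triplet Z-scores
#'
#' Normalizes each triplet's co-localization probability against the set of
#' triplets sharing the same sequence-gap product `|j-i| * |k-j|`:
#' `Z = (pi - mean(group)) / sd(group)` with the population standard
#' deviation. Groups with zero spread (including singletons) yield `Z = 0`.
#'
#' @param stats output of [triplet_colocalization()].
#' @return the input with a `z` column filled in.
#' @export
triplet_zscore <- function(stats) {
  if (!inherits(stats, "dimes_triplets")) {
    stop("stats must come from triplet_colocalization()", call. = FALSE)
  }
  g <- stats$gap_product
  mu <- stats::ave(stats$pi, g, FUN = function(x) mean(x, na.rm = TRUE))
  sdv <- stats::ave(stats$pi, g, FUN = function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    sqrt(mean((x - mean(x))^2))   # population sd
  })
  z <- ifelse(is.na(sdv) | sdv == 0, 0, (stats$pi - mu) / sdv)
  stats$z <- z
  stats
}

#' Conformations with a co-localized triplet
#'
#' Rejection filter: keeps the conformations in which the three loci of
#' `triplet` are mutually within threshold `a`.
#'
#' @param ens `M x N x 3` coordinate array.
#' @param triplet integer vector of three locus indices.
#' @param a contact threshold (nm).
#' @return the filtered ensemble (possibly zero conformations, with a
#'   warning).
#' @export
colocalized_subset <- function(ens, triplet, a = 300) {
  ens <- .check_ensemble(ens)
  triplet <- as.integer(triplet)
  if (length(triplet) != 3 || anyDuplicated(triplet) ||
      any(triplet < 1) || any(triplet > dim(ens)[2])) {
    stop("triplet must be three distinct locus indices", call. = FALSE)
  }
  keep <- vapply(seq_len(dim(ens)[1]), function(m) {
    D <- stats::dist(ens[m, triplet, ])
    isTRUE(all(D < a))
  }, logical(1))
  if (!any(keep)) warning("no conformation satisfies the co-localization constraint")
  out <- ens[keep, , , drop = FALSE]
  attr(out, "source") <- attr(ens, "source")
  out
}

#' Radius of gyration and shape anisotropy
#'
#' For each conformation, computes the gyration tensor of the chosen locus
#' segment; `R_g` is the square root of its trace and the relative shape
#' anisotropy is `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1+l2+l3)^2`
#' from its eigenvalues (`0` for spherical symmetry, `1` for a line).
#'
#' @param ens `M x N x 3` coordinate array.
#' @param segment integer range `c(i, j)` of loci (default: all).
#' @return data frame with per-conformation `rg` (nm) and `kappa2`.
#' @export
shape_stats <- function(ens, segment = NULL) {
  ens <- .check_ensemble(ens)
  n <- dim(ens)[2]
  if (is.null(segment)) segment <- c(1L, n)
  segment <- as.integer(segment)
  if (length(segment) != 2 || segment[1] < 1 || segment[2] > n ||
      segment[2] - segment[1] < 1) {
    stop("segment must be a locus range of length >= 2 within 1..N", call. = FALSE)
  }
  sel <- segment[1]:segment[2]
  res <- t(vapply(seq_len(dim(ens)[1]), function(m) {
    xyz <- ens[m, sel, , drop = TRUE]
    xyz <- xyz[!is.na(xyz[, 1]), , drop = FALSE]
    if (nrow(xyz) < 2) return(c(NA_real_, NA_real_))
    cc <- sweep(xyz, 2, colMeans(xyz))
    Tg <- crossprod(cc) / nrow(cc)
    lam <- eigen(Tg, symmetric = TRUE, only.values = TRUE)$values
    tr <- sum(lam)
    kap <- 1 - 3 * (lam[1] * lam[2] + lam[2] * lam[3] + lam[1] * lam[3]) / tr^2
    c(sqrt(tr), min(max(kap, 0), 1))
  }, numeric(2)))
  data.frame(rg = res[, 1], kappa2 = res[, 2])
}

#' Single-cell domain boundary probabilities
#'
#' Insulation-style score on per-cell distance matrices. For each cell and
#' each locus `i` (with `w <= i <= N - w`), the mean distance between the
#' window ending at `i` (`i-w+1 .. i`) and the window starting after it
#' (`i+1 .. i+w`) is divided by the mean distance within the two windows,
#' so a boundary call at `i` means a domain edge between loci `i` and
#' `i + 1`. Because this inter/intra ratio is above 1 for any extended
#' chain, the score is normalized by its median across the loci of that
#' cell; loci where the normalized score exceeds `threshold` and is a local
#' maximum are called boundaries. The reported probability is the fraction
#' of scoreable cells calling each locus; edge loci are `NA`.
#'
#' @param cells either an `M x N x 3` coordinate array or a list of per-cell
#'   `N x N` distance matrices (`NA` allowed).
#' @param window window size `w` (default 5 loci each side).
#' @param threshold boundary threshold on the median-normalized score
#'   (default 1.2).
#' @param min_observed minimum fraction of window pairs observed for a score
#'   (default 0.8).
#' @return numeric vector of per-locus boundary probabilities.
#' @export
boundary_probability <- function(cells, window = 5L, threshold = 1.2,
                                 min_observed = 0.8) {
  if (is.array(cells) && length(dim(cells)) == 3L) {
    cells <- .conformation_distmats(cells)
  }
  if (!is.list(cells) || !length(cells)) {
    stop("cells must be a coordinate array or a list of distance matrices",
         call. = FALSE)
  }
  n <- nrow(cells[[1]])
  window <- as.integer(window)
  if (window < 1 || window >= n / 2) stop("window must satisfy 1 <= w < N/2",
                                          call. = FALSE)
  interior <- window:(n - window)
  calls <- matrix(0, length(cells), n)
  scoreable <- matrix(FALSE, length(cells), n)
  for (ci in seq_along(cells)) {
    D <- cells[[ci]]
    score <- rep(NA_real_, n)
    for (i in interior) {
      left <- (i - window + 1L):i
      right <- (i + 1L):(i + window)
      inter <- D[left, right]
      intra <- c(D[left, left][upper.tri(diag(window))],
                 D[right, right][upper.tri(diag(window))])
      nobs <- sum(!is.na(inter)) + sum(!is.na(intra))
      if (nobs < min_observed * (length(inter) + length(intra))) next
      score[i] <- mean(inter, na.rm = TRUE) / mean(intra, na.rm = TRUE)
    }
    med <- stats::median(score, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) next
    nscore <- score / med
    for (i in interior) {
      if (is.na(nscore[i])) next
      scoreable[ci, i] <- TRUE
      nb <- nscore[c(max(1L, i - 1L), min(n, i + 1L))]
      is_max <- all(is.na(nb) | nscore[i] >= nb)
      if (is_max && nscore[i] > threshold) calls[ci, i] <- 1
    }
  }
  prob <- colSums(calls) / pmax(colSums(scoreable), 1L)
  prob[colSums(scoreable) == 0] <- NA_real_
  prob
}

#' Distance between two conformations
#'
#' The conformation-space metric
#' `D_mn = sqrt( (1/N^2) * sum_{i,j} (r_ij^(m) - r_ij^(n))^2 )`, the sum
#' running over all ordered pairs (diagonal terms vanish).
#'
#' @param m,n `N x 3` coordinate matrices.
#' @return nonnegative scalar.
#' @export
conformation_distance <- function(m, n) {
  m <- as.matrix(m); n <- as.matrix(n)
  if (!all(dim(m) == dim(n)) || ncol(m) != 3) {
    stop("conformations must be N x 3 matrices of equal size", call. = FALSE)
  }
  dm <- as.matrix(stats::dist(m))
  dn <- as.matrix(stats::dist(n))
  sqrt(sum((dm - dn)^2) / nrow(m)^2)
}

#' All pairwise conformation distances of an ensemble
#'
#' @param ens `M x N x 3` coordinate array (complete conformations).
#' @return `M x M` symmetric matrix of `D_mn` values.
#' @export
conformation_distance_matrix <- function(ens) {
  ens <- .check_ensemble(ens)
  m <- dim(ens)[1]; n <- dim(ens)[2]
  flat <- t(vapply(seq_len(m), function(i) {
    as.vector(as.matrix(stats::dist(ens[i, , ])))
  }, numeric(n * n)))
  as.matrix(stats::dist(flat)) / n
}

#' Cluster an ensemble of conformations
#'
#' Embeds the conformation-distance matrix `D_mn` in two dimensions by
#' classical multidimensional scaling and applies Ward-linkage agglomerative
#' clustering (`hclust`, `ward.D2`) on the embedding. Reports cluster
#' labels, fractions, per-cluster mean distance maps, and a representative
#' conformation per cluster (the member with the lowest average `D_mn` to
#' its cluster mates).
#'
#' @param ens `M x N x 3` coordinate array.
#' @param n_clusters number of clusters (default 2).
#' @param seed recorded for provenance; the embedding and linkage used here
#'   are deterministic.
#' @return list with `labels`, `fractions`, `representatives` (conformation
#'   indices), `mean_distance_maps` (list of `N x N` matrices), `embedding`
#'   (`M x 2`), and `D` (the `M x M` metric matrix).
#' @export
cluster_ensemble <- function(ens, n_clusters = 2L, seed = 1L) {
  ens <- .check_ensemble(ens)
  m <- dim(ens)[1]
  if (m < n_clusters) stop("need at least n_clusters conformations", call. = FALSE)
  D <- conformation_distance_matrix(ens)
  emb <- stats::cmdscale(stats::as.dist(D), k = 2)
  hc <- stats::hclust(stats::dist(emb), method = "ward.D2")
  labels <- unname(stats::cutree(hc, k = n_clusters))
  fractions <- as.vector(table(factor(labels, levels = seq_len(n_clusters)))) / m
  reps <- vapply(seq_len(n_clusters), function(cl) {
    members <- which(labels == cl)
    if (length(members) == 1L) return(members)
    within <- D[members, members, drop = FALSE]
    members[which.min(rowSums(within) / (length(members) - 1L))]
  }, integer(1))
  maps <- lapply(seq_len(n_clusters), function(cl) {
    members <- which(labels == cl)
    Reduce(`+`, lapply(members, function(i)
      as.matrix(stats::dist(ens[i, , ])))) / length(members)
  })
  list(labels = labels, fractions = fractions, representatives = reps,
       mean_distance_maps = maps, embedding = emb, D = D, seed = seed)
}

#' A/B spatial mixing metric Q_k
#'
#' For each conformation,
#' `Q_k = (1/N) * sum_i | n_A(i;k)/nt_A - n_B(i;k)/nt_B |` where `n_A(i;k)`
#' counts A-loci among the `k` nearest spatial neighbours of locus `i`
#' (self excluded, distance ties broken by lower locus index) and
#' `nt_A = k N_A / N` is the random-mixing expectation. Perfect mixing gives
#' `Q_k = 0`; complete demixing with equal class sizes gives `Q_k = 2`.
#'
#' @param ens `M x N x 3` coordinate array (complete conformations).
#' @param labels character (or factor) vector of per-locus labels `"A"`/`"B"`.
#' @param k number of nearest neighbours.
#' @return numeric vector of per-conformation `Q_k`.
#' @export
mixing_metric <- function(ens, labels, k) {
  ens <- .check_ensemble(ens)
  n <- dim(ens)[2]
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have length N", call. = FALSE)
  if (k >= n || k < 1) stop("k must satisfy 1 <= k < N", call. = FALSE)
  nA <- sum(labels == "A"); nB <- sum(labels == "B")
  if (nA == 0 || nB == 0) {
    stop("both A and B labels are required (one class is empty)", call. = FALSE)
  }
  ntA <- k * nA / n
  ntB <- k * nB / n
  vapply(seq_len(dim(ens)[1]), function(m) {
    D <- as.matrix(stats::dist(ens[m, , ]))
    tot <- 0
    for (i in seq_len(n)) {
      nb <- .knn_indices(D[i, ], i, k)
      cA <- sum(labels[nb] == "A")
      cB <- sum(labels[nb] == "B")
      tot <- tot + abs(cA / ntA - cB / ntB)
    }
    tot / n
  }, numeric(1))
}

#' Long-range interaction metric F_k
#'
#' `F_k = (1/(k N F_0k)) * sum_i sum_{j in m_i(k)} |j - i|` where `m_i(k)`
#' is the set of `k` nearest spatial neighbours of locus `i` and
#' `F_0k = (1/2)(1 + k/2)` is the straight-chain value, so a straight chain
#' scores about 1 and spatial contacts between sequence-distant loci push
#' `F_k` above 1.
#'
#' @inheritParams mixing_metric
#' @return numeric vector of per-conformation `F_k`.
#' @export
longrange_metric <- function(ens, k) {
  ens <- .check_ensemble(ens)
  n <- dim(ens)[2]
  if (k >= n || k < 1) stop("k must satisfy 1 <= k < N", call. = FALSE)
  f0 <- 0.5 * (1 + k / 2)
  vapply(seq_len(dim(ens)[1]), function(m) {
    D <- as.matrix(stats::dist(ens[m, , ]))
    tot <- 0
    for (i in seq_len(n)) {
      nb <- .knn_indices(D[i, ], i, k)
      tot <- tot + sum(abs(nb - i))
    }
    tot / (k * n * f0)
  }, numeric(1))
}

## ---- internals ----

## k nearest neighbours of locus i from its distance row, self excluded,
## ties broken by lower index (order() is stable with index tiebreak)
.knn_indices <- function(drow, i, k) {
  drow[i] <- Inf
  order(drow, seq_along(drow))[seq_len(k)]
}

## P x M matrix of pair distances, pairs enumerated as upper.tri column-major
.pair_distance_matrix <- function(ens) {
  m <- dim(ens)[1]; n <- dim(ens)[2]
  ut <- upper.tri(diag(n))
  out <- matrix(NA_real_, sum(ut), m)
  for (cm in seq_len(m)) {
    D <- as.matrix(stats::dist(ens[cm, , ]))
    out[, cm] <- D[ut]
  }
  out
}

## Freedman-Diaconis bin edges covering the data range
.fd_breaks <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite distances to bin", call. = FALSE)
  rng <- range(x)
  if (rng[1] == rng[2]) return(c(rng[1] - 0.5, rng[2] + 0.5))
  h <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  nb <- if (h <= 0) 1L else max(1L, ceiling(diff(rng) / h))
  seq(rng[1], rng[2], length.out = nb + 1L)
}

## bin probabilities of x on the given edges (values outside clamped in)
.hist_prob <- function(x, breaks) {
  x <- x[is.finite(x)]
  x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = length(breaks) - 1L)
  counts / sum(counts)
}

## base-2 Jensen-Shannon divergence between probability vectors
.jsd <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / m[nz]))
  }
  (kl(p) + kl(q)) / 2
}
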