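# Interpreting the fitted connectivity matrix: correlation structure and A/B
# compartments (PC1), genomic-distance interaction profiles, and per-class
# coupling histograms.

#' Correlation matrix of the connectivity matrix
#'
#' `rho_ij` is the Pearson correlation between the coupling profiles (rows)
#' of loci `i` and `j` — the standard Hi-C compartment recipe applied to
#' couplings instead of contacts. For each pair, the columns within
#' `exclude_neighbors` loci of `i` or of `j` are excluded from both rows:
#' this removes the diagonal, the mutual coupling, and the backbone
#' (polymer-connectivity) couplings, whose magnitude would otherwise drown
#' the long-range epigenetic signal the correlation is meant to expose.
#' Rows with zero variance yield `NA` correlations.
#'
#' @param K connectivity matrix.
#' @param exclude_neighbors half-width of the excluded band around each of
#'   the two loci (default 1: drop `i - 1, i, i + 1` and likewise for `j`).
#'   If the exclusion leaves fewer than 3 columns, it falls back to
#'   dropping only `i` and `j` for that pair.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_from_connectivity <- function(K, exclude_neighbors = 1L) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  if (n < 3) stop("need at least 3 loci", call. = FALSE)
  nb <- as.integer(exclude_neighbors)
  rho <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      drop <- unique(pmin(n, pmax(1, c(outer(c(i, j), -nb:nb, "+")))))
      keep <- setdiff(seq_len(n), drop)
      if (length(keep) < 3) keep <- setdiff(seq_len(n), c(i, j))
      xi <- K[i, keep]; xj <- K[j, keep]
      v <- if (stats::sd(xi) == 0 || stats::sd(xj) == 0) NA_real_
           else stats::cor(xi, xj)
      rho[i, j] <- v
      rho[j, i] <- v
    }
  }
  rho
}

#' A/B compartments from the correlation matrix
#'
#' Takes the leading principal component (PC1) of `rho`; loci with negative
#' PC1 are labelled A and positive PC1 are labelled B. Because eigenvectors
#' are sign-ambiguous, the orientation is fixed either against
#' `reference_labels` (flip so that reference-A loci have negative mean PC1)
#' or, absent a reference, so that the first locus scores negative.
#'
#' @param rho correlation matrix (`NA` rows are excluded from the PCA and
#'   come back unassigned).
#' @param reference_labels optional character vector of `"A"`/`"B"` labels
#'   used only for sign orientation.
#' @return data frame with per-locus `pc1` and `label` (`"A"`, `"B"`, or
#'   `"unassigned"`), plus attributes `n_A`, `n_B`.
#' @export
compartments_from_correlation <- function(rho, reference_labels = NULL) {
  rho <- .check_square(rho, "rho")
  n <- nrow(rho)
  ok <- !apply(rho, 1, anyNA)
  if (sum(ok) < 2) stop("too few loci with defined correlations", call. = FALSE)
  sub <- rho[ok, ok]
  e <- eigen((sub + t(sub)) / 2, symmetric = TRUE)
  if (length(e$values) > 1 &&
      abs(e$values[1] - e$values[2]) < 1e-8 * max(abs(e$values))) {
    warning("degenerate leading eigenvalue: PC1 is not well separated")
  }
  pc1 <- rep(NA_real_, n)
  pc1[ok] <- e$vectors[, 1]
  flip <- if (!is.null(reference_labels)) {
    refA <- reference_labels == "A" & !is.na(pc1)
    if (any(refA) && mean(pc1[refA]) > 0) -1 else 1
  } else {
    first <- which(!is.na(pc1) & pc1 != 0)[1]
    if (!is.na(first) && pc1[first] > 0) -1 else 1
  }
  pc1 <- flip * pc1
  label <- ifelse(is.na(pc1), "unassigned",
                  ifelse(pc1 < 0, "A", ifelse(pc1 > 0, "B", "unassigned")))
  out <- data.frame(locus = seq_len(n), pc1 = pc1, label = label)
  attr(out, "n_A") <- sum(label == "A")
  attr(out, "n_B") <- sum(label == "B")
  out
}

#' Genomic-distance interaction profiles by pair class
#'
#' Mean coupling `<k(s)>` as a function of sequence separation `s = j - i`,
#' split by pair class (A-A, B-B, A-B, plus the unsplit `all` profile). The
#' per-class mean at each `s` is normalized by the number of pairs of that
#' class at that separation (so that sparse classes are not damped).
#'
#' @param K connectivity matrix.
#' @param labels per-locus `"A"`/`"B"` labels (anything else is dropped from
#'   the class profiles but kept in `all`).
#' @return tidy data frame with columns `s`, `class`, `mean_k`, `n_pairs`.
#' @export
k_profile_by_s <- function(K, labels) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have length N", call. = FALSE)
  idx <- which(upper.tri(K), arr.ind = TRUE)
  s <- idx[, 2] - idx[, 1]
  kv <- K[upper.tri(K)]
  cls <- .pair_class(labels[idx[, 1]], labels[idx[, 2]])
  res <- list()
  for (cl in c("all", "AA", "BB", "AB")) {
    sel <- if (cl == "all") rep(TRUE, length(kv)) else !is.na(cls) & cls == cl
    if (!any(sel)) next
    agg <- tapply(kv[sel], s[sel], mean)
    cnt <- tapply(kv[sel], s[sel], length)
    res[[cl]] <- data.frame(s = as.integer(names(agg)), class = cl,
                            mean_k = as.vector(agg),
                            n_pairs = as.vector(cnt))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Coupling histograms by pair class
#'
#' Bins the off-diagonal couplings into A-A, B-B and A-B classes on shared
#' bin edges and reports the per-class means.
#'
#' @param K connectivity matrix.
#' @param labels per-locus `"A"`/`"B"` labels.
#' @param breaks bin edges (default: Freedman-Diaconis on all couplings).
#' @return list with `breaks`, `counts` (named list of per-class bin
#'   counts), and `means` (named vector of per-class mean couplings).
#' @export
k_histograms_by_class <- function(K, labels, breaks = NULL) {
  K <- .check_connectivity(K)
  n <- nrow(K)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have length N", call. = FALSE)
  idx <- which(upper.tri(K), arr.ind = TRUE)
  kv <- K[upper.tri(K)]
  cls <- .pair_class(labels[idx[, 1]], labels[idx[, 2]])
  if (is.null(breaks)) breaks <- .fd_breaks(kv)
  counts <- lapply(c(AA = "AA", BB = "BB", AB = "AB"), function(cl) {
    x <- kv[!is.na(cls) & cls == cl]
    if (!length(x)) return(integer(length(breaks) - 1L))
    tabulate(findInterval(pmin(pmax(x, breaks[1]), breaks[length(breaks)]),
                          breaks, rightmost.closed = TRUE, all.inside = TRUE),
             nbins = length(breaks) - 1L)
  })
  means <- vapply(c(AA = "AA", BB = "BB", AB = "AB"), function(cl) {
    x <- kv[!is.na(cls) & cls == cl]
    if (!length(x)) NA_real_ else mean(x)
  }, numeric(1))
  list(breaks = breaks, counts = counts, means = means)
}

#' Additivity diagnostic for the coupling decomposition
#'
#' If couplings decompose additively into a sequence part and an epigenetic
#' part, `k_ij = k_0(i, j) + k_e(class_i, class_j)`, then the differences
#' `<k_AA(s)> - <k_AB(s)>`, `<k_AA(s)> - <k_BB(s)>` and
#' `<k_BB(s)> - <k_AB(s)>` are independent of `s`. This diagnostic returns
#' those difference curves plus a flatness summary (`sd / |mean|` over the
#' chosen separation range) for each.
#'
#' @param K connectivity matrix.
#' @param labels per-locus `"A"`/`"B"` labels.
#' @param s_range optional `c(min, max)` separation window for the flatness
#'   summary (default: all separations where all three classes have pairs).
#' @return list with `curves` (data frame: `s`, `AA_minus_AB`,
#'   `AA_minus_BB`, `BB_minus_AB`) and `flatness` (named vector).
#' @export
additivity_diagnostic <- function(K, labels, s_range = NULL) {
  prof <- k_profile_by_s(K, labels)
  wide <- lapply(c("AA", "BB", "AB"), function(cl) {
    sub <- prof[prof$class == cl, c("s", "mean_k")]
    names(sub)[2] <- cl
    sub
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "s"), wide)
  if (!nrow(merged)) stop("no separation has pairs of all three classes",
                          call. = FALSE)
  curves <- data.frame(s = merged$s,
                       AA_minus_AB = merged$AA - merged$AB,
                       AA_minus_BB = merged$AA - merged$BB,
                       BB_minus_AB = merged$BB - merged$AB)
  if (is.null(s_range)) s_range <- range(curves$s)
  sel <- curves$s >= s_range[1] & curves$s <= s_range[2]
  flatness <- vapply(c("AA_minus_AB", "AA_minus_BB", "BB_minus_AB"),
                     function(nm) {
    x <- curves[[nm]][sel]
    if (length(x) < 2 || mean(x) == 0) return(ifelse(all(x == x[1]), 0, Inf))
    stats::sd(x) / abs(mean(x))
  }, numeric(1))
  list(curves = curves, flatness = flatness)
}

.pair_class <- function(li, lj) {
  out <- rep(NA_character_, length(li))
  ab <- li %in% c("A", "B") & lj %in% c("A", "B")
  out[ab & li == lj & li == "A"] <- "AA"
  out[ab & li == lj & li == "B"] <- "BB"
  out[ab & li != lj] <- "AB"
  out
}
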