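# Ensemble statistics: distributions, JSD, triplets, shapes, boundaries,
# the conformation metric, clustering, and the mixing / long-range metrics.

make_line_ensemble <- function(spacings) {
  # one conformation per row of spacings laid out along x
  m <- nrow(spacings)
  n <- ncol(spacings) + 1L
  ens <- array(0, c(m, n, 3))
  for (r in seq_len(m)) ens[r, , 1] <- cumsum(c(0, spacings[r, ]))
  ens
}

test_that("distance histograms are normalized on shared edges", {
  ens <- make_line_ensemble(matrix(1, 4, 1))  # all r = 1
  h <- distance_distributions(ens)
  expect_equal(rowSums(h$prob), rep(1, nrow(h$prob)))
  expect_equal(max(h$prob), 1)  # degenerate distances: all mass in one bin
  # sampled dumbbell matches the 3D Gaussian-separation density
  K <- assemble_connectivity(matrix(c(0, 0.5, 0.5, 0), 2))
  ens2 <- sample_conformations(K, 40000, seed = 3)
  h2 <- distance_distributions(ens2)
  mid <- (head(h2$breaks, -1) + tail(h2$breaks, -1)) / 2
  w <- diff(h2$breaks)
  s2 <- 2  # per-axis variance of the separation: <r^2>/3
  dens <- 4 * pi * mid^2 * exp(-mid^2 / (2 * s2)) / (2 * pi * s2)^1.5
  expect_lt(max(abs(h2$prob[1, ] - dens * w)), 0.01)
})

test_that("JSD has its boundary values and detects binning mismatch", {
  ens <- make_line_ensemble(matrix(c(1, 1.2, 0.9, 1.1), 4, 1))
  h <- distance_distributions(ens)
  jsd_self <- jsd_matrix(h, h)
  expect_equal(jsd_self[1, 2], 0)
  # disjoint supports reach the base-2 bound of 1
  breaks <- c(0, 1, 2)
  p <- list(breaks = breaks, prob = matrix(c(1, 0), 1),
            pairs = data.frame(i = 1, j = 2))
  q <- list(breaks = breaks, prob = matrix(c(0, 1), 1),
            pairs = data.frame(i = 1, j = 2))
  expect_equal(jsd_matrix(p, q)[1, 2], 1)
  hbad <- distance_distributions(ens, breaks = c(0, 2, 4))
  expect_error(jsd_matrix(h, hbad), "bin edges")
})

test_that("triplet probabilities match the brute-force count", {
  # 2 conformations: mutual distances ~1 then ~10; a = 2 keeps exactly one
  ens <- array(0, c(2, 3, 3))
  ens[1, 2, 1] <- 1; ens[1, 3, 2] <- 1
  ens[2, 2, 1] <- 10; ens[2, 3, 2] <- 10
  ts <- triplet_colocalization(ens, a = 2)
  expect_equal(ts$pi, 0.5)
  expect_equal(nrow(ts), 1L)
  # larger threshold keeps everything; zero keeps nothing
  expect_equal(triplet_colocalization(ens, a = 100)$pi, 1)
  expect_equal(triplet_colocalization(ens, a = 1e-9)$pi, 0)
  # random small ensemble against the exhaustive oracle
  set.seed(12)
  ens2 <- array(rnorm(8 * 6 * 3, sd = 2), c(8, 6, 3))
  a <- 3
  got <- triplet_colocalization(ens2, a)
  want <- brute_pi(ens2, a)
  expect_equal(got$pi, want$pi)
  expect_equal(got[, c("i", "j", "k")], want[, c("i", "j", "k")],
               ignore_attr = TRUE)
  # monotone non-decreasing in the threshold
  got5 <- triplet_colocalization(ens2, 5)
  expect_true(all(got5$pi >= got$pi))
})

test_that("triplet Z-scores follow the gap-product grouping", {
  set.seed(13)
  ens <- array(rnorm(10 * 6 * 3, sd = 2), c(10, 6, 3))
  ts <- triplet_zscore(triplet_colocalization(ens, 3))
  expect_equal(ts$z, brute_z(ts), tolerance = 1e-12)
  # hand case: two triplets in one group with pi = 0.2 / 0.4 -> Z = -1 / +1
  fake <- triplet_colocalization(array(rnorm(2 * 4 * 3), c(2, 4, 3)), 1)
  fake$gap_product <- c(1, 2, 1, 2)
  fake$pi <- c(0.2, 0.5, 0.4, 0.5)
  zs <- triplet_zscore(fake)
  expect_equal(zs$z[c(1, 3)], c(-1, 1))
  expect_equal(zs$z[c(2, 4)], c(0, 0))  # zero-spread group
})

test_that("co-localized subsets are rejection-filtered", {
  ens <- array(0, c(2, 3, 3))
  ens[1, 2, 1] <- 1; ens[1, 3, 2] <- 1
  ens[2, 2, 1] <- 10; ens[2, 3, 2] <- 10
  kept <- colocalized_subset(ens, c(1, 2, 3), a = 2)
  expect_equal(dim(kept)[1], 1L)
  expect_equal(kept[1, , ], ens[1, , ])
  expect_equal(dim(colocalized_subset(ens, c(1, 2, 3), a = Inf))[1], 2L)
  expect_warning(empty <- colocalized_subset(ens, c(1, 2, 3), a = 1e-12),
                 "no conformation")
  expect_equal(dim(empty)[1], 0L)
})

test_that("gyration radius and shape anisotropy have their closed forms", {
  # two loci at separation d: R_g = d/2, collinear: kappa^2 = 1
  ens <- array(0, c(1, 2, 3)); ens[1, 2, 1] <- 4
  ss <- shape_stats(ens)
  expect_equal(ss$rg, 2)
  expect_equal(ss$kappa2, 1)
  # equilateral triangle: planar with two equal moments -> kappa^2 = 1/4
  tri <- array(0, c(1, 3, 3))
  tri[1, , 1] <- c(0, 1, 0.5)
  tri[1, , 2] <- c(0, 0, sqrt(3) / 2)
  expect_equal(shape_stats(tri)$kappa2, 0.25, tolerance = 1e-12)
  expect_error(shape_stats(ens, segment = c(2, 2)), "segment")
})

test_that("boundary probability flags block interfaces, not interiors", {
  # two rigid well-separated blocks; small per-cell jitter
  set.seed(3)
  n <- 24
  base <- matrix(0, n, 3)
  base[, 1] <- c(seq(0, 11) * 10, 500 + seq(0, 11) * 10)
  cells <- lapply(1:30, function(i) {
    as.matrix(dist(base + matrix(rnorm(n * 3, sd = 2), n, 3)))
  })
  bp <- boundary_probability(cells, window = 4)
  expect_true(all(is.na(bp[c(1:3, 21:24)])))  # edge loci excluded
  expect_gt(bp[12], 0.9)                      # domain edge: last block-1 locus
  expect_lt(max(bp[c(6:9, 16:19)]), 0.2)      # deep interiors
  # pure-distance input: rigid motion of coordinates changes nothing
  ensA <- array(0, c(5, n, 3))
  for (m in 1:5) ensA[m, , ] <- base + matrix(rnorm(n * 3, sd = 2), n, 3)
  expect_equal(boundary_probability(ensA, window = 4),
               boundary_probability(rigid_transform(ensA), window = 4),
               tolerance = 1e-10)
  expect_error(boundary_probability(cells, window = 12), "window")
})

test_that("homopolymer ensembles still show TAD-like boundaries", {
  K <- make_rouse_chain(30, 1)
  ens <- sample_conformations(K, 150, seed = 9)
  bp <- boundary_probability(ens, window = 5)
  inner <- bp[!is.na(bp)]
  expect_gt(mean(inner), 0.02)  # nonzero boundary signal from fluctuations
  expect_lt(diff(range(inner)), 0.5)  # and roughly flat along the chain
})

test_that("the conformation metric is the ordered-pair RMS difference", {
  a <- matrix(0, 2, 3); a[2, 1] <- 1
  b <- matrix(0, 2, 3); b[2, 1] <- 3
  expect_equal(conformation_distance(a, b), sqrt(2))
  expect_equal(conformation_distance(a, a), 0)
  expect_equal(conformation_distance(b, a), conformation_distance(a, b))
  ens <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  D <- conformation_distance_matrix(ens)
  expect_equal(D[2, 3], conformation_distance(ens[2, , ], ens[3, , ]))
  expect_equal(D, t(D))
})

test_that("planted two-population ensembles are recovered by clustering", {
  compact <- make_rouse_chain(16, 4)
  extended <- make_rouse_chain(16, 0.05)
  e1 <- sample_conformations(compact, 60, seed = 1)
  e2 <- sample_conformations(extended, 40, seed = 2)
  ens <- array(0, c(100, 16, 3))
  ens[1:60, , ] <- e1; ens[61:100, , ] <- e2
  cl <- cluster_ensemble(ens, 2)
  expect_equal(sum(cl$fractions), 1)
  expect_lt(abs(max(cl$fractions) - 0.6), 0.05)
  # representatives are members of their own cluster
  expect_equal(cl$labels[cl$representatives], 1:2)
  expect_equal(dim(cl$mean_distance_maps[[1]]), c(16L, 16L))
})

test_that("Q_k and F_k match brute force and the exact configurations", {
  set.seed(21)
  ens <- array(rnorm(6 * 6 * 3, sd = 3), c(6, 6, 3))
  labels <- c("A", "B", "A", "B", "A", "B")
  for (k in c(2, 3)) {
    got_q <- mixing_metric(ens, labels, k)
    got_f <- longrange_metric(ens, k)
    want <- t(sapply(seq_len(6), function(m) brute_qf(ens[m, , ], labels, k)))
    expect_equal(got_q, unname(want[, "Q"]), tolerance = 1e-12)
    expect_equal(got_f, unname(want[, "F"]), tolerance = 1e-12)
  }
  # fully demixed compact blocks score the ceiling Q = 2
  demix <- array(0, c(1, 8, 3))
  demix[1, , 1] <- c(0, 0.1, 0.2, 0.3, 100, 100.1, 100.2, 100.3)
  expect_equal(mixing_metric(demix, rep(c("A", "B"), each = 4), 2), 2)
  expect_error(mixing_metric(demix, rep("A", 8), 2), "empty")
  # straight chain: interior F contribution is exactly 1
  line <- array(0, c(1, 40, 3)); line[1, , 1] <- 1:40
  expect_equal(longrange_metric(line, 2), (38 * 2 + 2 * 3) / (2 * 40 * 1))
  # hairpin: sequence-distant loci in contact push F above the chain value
  hair <- array(0, c(1, 40, 3))
  hair[1, , 1] <- c(1:20, 20:1)
  hair[1, , 2] <- rep(c(0, 0.4), each = 20)
  expect_gt(longrange_metric(hair, 2), longrange_metric(line, 2))
})

test_that("ensemble statistics are invariant under rigid motions", {
  set.seed(31)
  ens <- array(rnorm(8 * 6 * 3, sd = 2), c(8, 6, 3))
  moved <- rigid_transform(ens)
  labels <- rep(c("A", "B"), 3)
  expect_equal(mixing_metric(moved, labels, 2), mixing_metric(ens, labels, 2),
               tolerance = 1e-9)
  expect_equal(longrange_metric(moved, 3), longrange_metric(ens, 3),
               tolerance = 1e-9)
  expect_equal(triplet_colocalization(moved, 3)$pi,
               triplet_colocalization(ens, 3)$pi)
  expect_equal(shape_stats(moved)$rg, shape_stats(ens)$rg, tolerance = 1e-9)
  expect_equal(shape_stats(moved)$kappa2, shape_stats(ens)$kappa2,
               tolerance = 1e-9)
})
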