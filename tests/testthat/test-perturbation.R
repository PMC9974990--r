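# Structural-variant edits of the connectivity matrix and the perturbation
# index.

test_that("segment inversion is an involutive permutation similarity", {
  K <- random_connected_K(10, 51)
  Ki <- invert_segment(K, c(3, 8))
  expect_equal(invert_segment(Ki, c(3, 8)), K)
  # eigenvalues preserved exactly (similarity transform)
  expect_equal(eigen(Ki, symmetric = TRUE, only.values = TRUE)$values,
               eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  # 4-locus hand case: with segment [2, 3], k'_{1,2} = k_{1,3}
  od <- matrix(0, 4, 4)
  od[upper.tri(od)] <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  od[lower.tri(od)] <- t(od)[lower.tri(od)]
  K4 <- assemble_connectivity(od)
  Ki4 <- invert_segment(K4, c(2, 3))
  expect_equal(Ki4[1, 2], K4[1, 3])
  expect_equal(Ki4[1, 3], K4[1, 2])
  expect_error(invert_segment(K, c(0, 5)), "segment")
})

test_that("inverting a symmetric homopolymer changes nothing measurable", {
  K <- make_rouse_chain(12, 1)
  d2_wt <- mean_sq_distances(covariance_from_connectivity(K))
  Ki <- invert_segment(K, c(1, 12))
  d2_inv <- mean_sq_distances(covariance_from_connectivity(Ki))
  expect_equal(d2_inv, d2_wt, tolerance = 1e-10)
})

test_that("relabelling commutes with perturbing", {
  K <- random_connected_K(8, 52)
  perm <- c(8:1)
  Kp <- assemble_connectivity({od <- K[perm, perm]; diag(od) <- 0; od})
  # inverting [2,4] after reversal equals reversing after inverting [5,7]
  left <- invert_segment(Kp, c(2, 4))
  right <- invert_segment(K, c(5, 7))
  rightp <- assemble_connectivity({od <- right[perm, perm]; diag(od) <- 0; od})
  expect_equal(left, rightp)
})

test_that("locus deletion cuts couplings and guards connectivity", {
  K <- make_rouse_chain(6, 1.5)
  Kd <- delete_locus(K, 6)
  expect_equal(Kd, make_rouse_chain(5, 1.5))
  # middle locus of a pure chain disconnects
  expect_error(delete_locus(make_rouse_chain(5, 1), 3), "disconnects")
  # marginalization oracle: equivalent for a leaf...
  K2 <- random_connected_K(7, 53)
  d2_del <- mean_sq_distances(covariance_from_connectivity(delete_locus(K2, 7)))
  d2_marg <- dimes:::.marginalize_locus_d2(K2, 7)
  is_leaf <- sum(K2[7, -7] != 0) == 1
  if (is_leaf) {
    expect_equal(d2_del, d2_marg, tolerance = 1e-8)
  }
  # ...provably different for an interior locus of a chain + bridge
  od <- matrix(0, 3, 3)
  od[1, 2] <- od[2, 1] <- 1
  od[2, 3] <- od[3, 2] <- 1
  od[1, 3] <- od[3, 1] <- 0.25
  K3 <- assemble_connectivity(od)
  del <- mean_sq_distances(covariance_from_connectivity(delete_locus(K3, 2)))
  marg <- dimes:::.marginalize_locus_d2(K3, 2)
  expect_equal(del[1, 2], 3 / 0.25)            # only the direct spring left
  expect_equal(marg[1, 2], 3 / 0.75)           # series springs survive
  expect_gt(abs(del[1, 2] - marg[1, 2]), 1)
})

test_that("the perturbation index satisfies its identities", {
  d <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(perturbation_index(d, d), 0)
  expect_equal(perturbation_index(d, matrix(c(0, 1, 1, 0), 2)), 0.5)
  dw <- sqrt(chain_resistance_d2(8, 1))
  dm <- dw * 0.9
  expect_equal(perturbation_index(3 * dw, 3 * dm),
               perturbation_index(dw, dm), tolerance = 1e-12)
  expect_gte(perturbation_index(dw, dm), 0)
  expect_error(perturbation_index(dw, dm, pair_subset = matrix(FALSE, 8, 8)),
               "empty")
})

test_that("deletion profiles respect symmetry and flag boundary loci", {
  # homopolymer with a next-nearest backbone so deletions stay connected
  n <- 10
  od <- matrix(0, n, n)
  for (i in 1:(n - 1)) od[i, i + 1] <- od[i + 1, i] <- 1
  for (i in 1:(n - 2)) od[i, i + 2] <- od[i + 2, i] <- 0.3
  K <- assemble_connectivity(od)
  prof <- pi_deletion_profile(K)
  expect_equal(length(prof), n)
  # mirror symmetry of the homopolymer
  expect_equal(prof, rev(prof), tolerance = 1e-8)
  # pure chain: deleting any interior locus disconnects -> NA
  chain <- make_rouse_chain(5, 1)
  prof_chain <- pi_deletion_profile(chain)
  expect_true(all(is.na(prof_chain[2:4])))
  expect_false(anyNA(prof_chain[c(1, 5)]))
})

test_that("block-interface loci perturb structure more than interiors", {
  bc <- make_block_copolymer(24, 12L, k_intra = 0.05, k_inter = -0.01,
                             jitter_sd = 0, seed = 1)
  n <- 24
  od <- bc$connectivity; diag(od) <- 0
  for (i in 1:(n - 2)) od[i, i + 2] <- od[i + 2, i] <- od[i, i + 2] + 0.3
  K <- assemble_connectivity(od)
  prof <- pi_deletion_profile(K)
  boundary <- mean(prof[12:13])
  interior <- mean(prof[c(6:7, 18:19)])
  expect_gt(boundary, interior)
})

test_that("variant contact maps compose edits deterministically", {
  K <- random_connected_K(10, 54)
  wt <- predict_variant_contact_map(K, list())
  d2 <- mean_sq_distances(covariance_from_connectivity(K))
  expect_equal(wt, contacts_from_distances(d2), tolerance = 1e-12)
  # double inversion restores the wild type
  edits <- list(list(op = "invert", start = 2, end = 7),
                list(op = "invert", start = 2, end = 7))
  expect_equal(predict_variant_contact_map(K, edits), wt, tolerance = 1e-12)
  # an inversion only reshuffles distances involving rearranged couplings
  one <- predict_variant_contact_map(K, list(list(op = "invert",
                                                  start = 3, end = 6)))
  expect_false(isTRUE(all.equal(one, wt)))
  expect_error(predict_variant_contact_map(
    K, list(list(op = "duplicate", start = 1, end = 2))), "refit")
  expect_error(predict_variant_contact_map(K, list(list(op = "warp"))),
               "unknown edit")
})
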