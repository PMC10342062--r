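kBT_ref <- kB_kcal() * 303.15

test_that("four-bead reduction splits domains at the reference CoM z", {
  # two equal atoms per domain straddling the split: beads sit on the atoms
  co <- array(0, c(4, 3, 5))
  co[1, , ] <- c(0, 0, -6); co[2, , ] <- c(0, 0, 6)
  co[3, , ] <- c(4, 0, -8); co[4, , ] <- c(4, 0, 8)
  top <- topology(c("A", "B", "C", "D"), segment = "protein", mass = 10,
                  domain_label = c("bundle", "bundle", "hash", "hash"))
  tr <- trajectory(co, top, c(50, 50, 50))
  beads <- four_bead_reduction(tr)
  expect_equal(beads$n_beads, 4)
  expect_equal(beads$labels, c("bundle_lower", "bundle_upper",
                               "hash_lower", "hash_upper"))
  # total bead mass equals total atom mass of the two domains
  expect_equal(sum(beads$masses), 40)
  # beads coincide with the atoms (up to the removed CoM translation)
  ref <- beads$reference
  expect_equal(ref[2, 3] - ref[1, 3], 12)
  expect_equal(ref[4, 3] - ref[3, 3], 16)

  # rigid translation of every atom leaves the bead trajectory unchanged
  tr2 <- tr
  tr2$coords <- tr$coords + 3.7
  beads2 <- four_bead_reduction(tr2)
  expect_equal(beads2$positions, beads$positions, tolerance = 1e-12)

  top_bad <- top; top_bad$domain_label[3:4] <- "none"
  expect_error(four_bead_reduction(trajectory(co, top_bad, c(50, 50, 50))),
               "hash")
})

test_that("PCA reproduces closed-form equipartition spectra", {
  masses <- rep(100, 4)
  raw <- cbind(c(-1, 0, 0, -1, 0, 0, 1, 0, 0, 1, 0, 0),
               c(0, 0, -1, 0, 0, 1, 0, 0, -1, 0, 0, 1))
  v <- internal_modes(raw, masses)
  k1 <- 2; k2 <- 0.5
  C <- (kBT_ref / k1) * v[, 1] %*% t(v[, 1]) +
       (kBT_ref / k2) * v[, 2] %*% t(v[, 2])
  spec <- bead_network_spec(masses = masses, reference = bead_ref4,
                            target_covariance = C, n_samples = 5e4, seed = 31)
  tr <- sample_bead_network(spec)
  beads <- bead_trajectory(tr$coords, masses)
  p <- bead_pca(beads, 303.15)
  expect_equal(sum(p$eigenvalues), sum(diag(p$covariance)), tolerance = 1e-10)
  # harmonic spring constants recovered as mode stiffness kBT/lambda
  expect_lt(abs(p$stiffness[1] - k2) / k2, 0.05)
  expect_lt(abs(p$stiffness[2] - k1) / k1, 0.05)
  # eigenvalues match the generator ground truth within 5%
  expect_lt(abs(p$eigenvalues[1] - kBT_ref / k2) / (kBT_ref / k2), 0.05)
  expect_lt(abs(p$eigenvalues[2] - kBT_ref / k1) / (kBT_ref / k1), 0.05)

  # mass-weighted branch: omega = sqrt(k/m) in ps^-1 (equal masses)
  pm <- bead_pca(beads, 303.15, mass_weighted = TRUE)
  conv <- 418.4
  expect_lt(abs(pm$quasi_frequencies[1] - sqrt(conv * k2 / 100)) /
            sqrt(conv * k2 / 100), 0.05)
  expect_lt(abs(pm$quasi_frequencies[2] - sqrt(conv * k1 / 100)) /
            sqrt(conv * k1 / 100), 0.05)
  # equal masses: mass-weighted eigenvalues are m times the unweighted ones
  expect_lt(max(abs(pm$eigenvalues[1:2] - 100 * p$eigenvalues[1:2]) /
                (100 * p$eigenvalues[1:2])), 1e-6)
})

test_that("isotropic fluctuations give a flat spectrum on the internal modes", {
  masses <- rep(50, 4)
  cval <- 0.36
  spec <- bead_network_spec(masses = masses, reference = bead_ref4,
                            target_covariance = cval * diag(12),
                            n_samples = 4e4, seed = 8)
  tr <- sample_bead_network(spec)
  p <- bead_pca(bead_trajectory(tr$coords, masses), 303.15)
  # CoM removal projects out 3 translational modes; the remaining 9 keep c
  expect_lt(max(abs(p$eigenvalues[1:9] - cval) / cval), 0.06)
  expect_lt(max(p$eigenvalues[10:12]) / cval, 0.01)
})

test_that("vibrational weights separate stretch from rigid rotation", {
  # pure two-bead stretch along the connecting axis: wv = 1 exactly
  ref2 <- rbind(c(0, 0, -3), c(0, 0, 3))
  masses2 <- c(10, 10)
  e_stretch <- c(0, 0, -1, 0, 0, 1) / sqrt(2)
  res <- structure(list(eigenvalues = 0.5, eigenvectors = cbind(e_stretch),
                        masses = masses2, reference = ref2,
                        mass_weighted = FALSE, kBT = kBT_ref),
                   class = "aqp_pca")
  res <- vibrational_weights(res)
  expect_equal(res$vib_weights[1], 1)

  # rigid rotation about a principal axis: wv = 0 (to machine precision)
  e_rot <- as.vector(t(cbind(-bead_ref4[, 2], bead_ref4[, 1], 0)))
  e_rot <- e_rot / sqrt(sum(e_rot^2))
  res_r <- structure(list(eigenvalues = 0.5, eigenvectors = cbind(e_rot),
                          masses = rep(10, 4), reference = bead_ref4,
                          mass_weighted = FALSE, kBT = kBT_ref),
                     class = "aqp_pca")
  res_r <- vibrational_weights(res_r)
  expect_lt(res_r$vib_weights[1], 1e-12)

  # random modes: exact agreement with the term-by-term oracle
  set.seed(77)
  E <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  masses <- runif(4, 5, 50)
  res_m <- structure(list(eigenvalues = rep(1, 12), eigenvectors = E,
                          masses = masses, reference = bead_ref4,
                          mass_weighted = FALSE, kBT = kBT_ref),
                     class = "aqp_pca")
  res_m <- vibrational_weights(res_m)
  expect_equal(res_m$vib_weights, oracle_wv(E, bead_ref4, masses),
               tolerance = 1e-12)
})

test_that("a sampled rigid rotation is classified as non-vibrational", {
  spec <- bead_network_spec(masses = rep(100, 4), reference = bead_ref4,
                            target_covariance = matrix(0, 12, 12),
                            rigid_rotation_amplitude = 0.05,
                            n_samples = 2e4, seed = 4)
  tr <- sample_bead_network(spec)
  p <- vibrational_weights(bead_pca(bead_trajectory(tr$coords, rep(100, 4)),
                                    303.15))
  # the dominant mode is the rotation; second-order (theta^2) breathing modes
  # carry ~1e-4 of its variance and are excluded by the relative threshold
  populated <- p$eigenvalues > 0.01 * max(p$eigenvalues)
  expect_true(any(populated))
  expect_lt(max(p$vib_weights[populated]), 0.02)
  # consequently the softness of a pure rotation is ~0
  expect_lt(as.numeric(softness(p)), 0.02 * sum(p$eigenvalues))
})

test_that("softness sums eigenvalues weighted by vibrational character", {
  res <- structure(list(eigenvalues = c(0.5, 0.3),
                        eigenvectors = diag(2)[, 1:2],
                        vib_weights = c(1, 0), kBT = kBT_ref),
                   class = "aqp_pca")
  s <- softness(res)
  expect_equal(as.numeric(s), 0.5)
  expect_equal(attr(s, "per_kBT"), 0.5 / kBT_ref)
  res$vib_weights <- c(0, 0)
  expect_equal(as.numeric(softness(res)), 0)
})

test_that("projected softness obeys the eigenbasis identities", {
  masses <- rep(100, 4)
  raw <- cbind(c(-1, 0, 0, -1, 0, 0, 1, 0, 0, 1, 0, 0),
               c(0, 0, -1, 0, 0, 1, 0, 0, -1, 0, 0, 1),
               rnorm(12))
  set.seed(5)
  v <- internal_modes(raw, masses)
  C <- 0.8 * tcrossprod(v[, 1]) + 0.3 * tcrossprod(v[, 2]) +
       0.1 * tcrossprod(v[, 3])
  spec <- bead_network_spec(masses = masses, reference = bead_ref4,
                            target_covariance = C, n_samples = 2e4, seed = 6)
  tr <- sample_bead_network(spec)
  p <- vibrational_weights(bead_pca(bead_trajectory(tr$coords, masses)))
  # P = e_j picks out lambda_j wv_j
  for (j in c(1, 3, 7))
    expect_equal(projected_softness(p, p$eigenvectors[, j]),
                 p$eigenvalues[j] * p$vib_weights[j], tolerance = 1e-10)
  # Parseval: summing over the full eigenbasis recovers sigma
  tot <- sum(vapply(seq_len(12),
                    function(j) projected_softness(p, p$eigenvectors[, j]), 1))
  expect_equal(tot, as.numeric(softness(p)), tolerance = 1e-10)
  # orthogonal complement of the populated modes projects to ~0
  Pv <- internal_modes(cbind(c(0, 1, 0, 0, -1, 0, 0, 1, 0, 0, -1, 0)), masses)
  resid <- Pv[, 1]
  for (j in 1:3) resid <- resid - sum(resid * v[, j]) * v[, j]
  resid <- resid / sqrt(sum(resid^2))
  expect_lt(projected_softness(p, resid), 5e-3 * as.numeric(softness(p)))
  # sigma_P never exceeds sigma
  set.seed(9)
  for (i in 1:5) {
    Prand <- rnorm(12); Prand <- Prand / sqrt(sum(Prand^2))
    expect_lte(projected_softness(p, Prand), as.numeric(softness(p)) + 1e-12)
  }
  expect_warning(projected_softness(p, rep(1, 12)), "normalis")
})

test_that("rocking-bundle vectors are translation-free, orthogonal and apt", {
  co <- array(0, c(4, 3, 3))
  for (f in 1:3) co[, , f] <- bead_ref4
  beads <- bead_trajectory(co, c(120, 80, 150, 90),
                           labels = c("bundle_lower", "bundle_upper",
                                      "hash_lower", "hash_upper"))
  rb <- rocking_bundle_vectors(beads)
  m3 <- rep(beads$masses, each = 3)
  for (vec in rb) {
    expect_equal(sqrt(sum(vec^2)), 1, tolerance = 1e-12)
    for (d in 1:3) {
      td <- rep(0, 12); td[seq(d, 12, 3)] <- 1
      expect_lt(abs(sum(m3 * td * vec)), 1e-9)     # no net CoM motion
    }
  }
  expect_lt(abs(sum(rb$separation * rb$rocking)), 1e-12)
  # applying the separation pattern increases the bundle-hash distance
  d0 <- beads$reference
  d1 <- d0 + 0.1 * matrix(rb$separation, ncol = 3, byrow = TRUE)
  gap0 <- sum((colMeans(d0[1:2, ]) - colMeans(d0[3:4, ]))^2)
  gap1 <- sum((colMeans(d1[1:2, ]) - colMeans(d1[3:4, ]))^2)
  expect_gt(gap1, gap0)
})

test_that("rank-deficient bead PCA warns and flags trailing zero modes", {
  co <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  beads <- bead_trajectory(co, rep(10, 4))
  expect_warning(expect_warning(p <- bead_pca(beads), "10 frames"),
                 "rank-deficient")
  expect_gt(p$n_zero_modes, 0)
})
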