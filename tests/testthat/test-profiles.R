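test_that("density profiles are normalised number densities", {
  fx <- make_profile_fixture(300, protein_blob = list(n_atoms = 0),
                             n_frames = 120, box = c(30, 30, 60), seed = 7)
  w <- select_atoms(fx, segment = "water")
  pr <- density_profile(fx, w)
  # per-frame histogram counts sum to the selection size
  total <- sum(pr$density) * 1 * 900          # bin width x lateral area
  expect_equal(total, 300, tolerance = 1e-9)
  # uniform slab: density ~ n/V in every interior bin
  expected <- 300 / (30 * 30 * 60)
  inside <- abs(pr$z) < 28
  se <- sqrt(expected * 900 * 120) / (900 * 120)
  expect_lt(max(abs(pr$density[inside] - expected)), 4 * se)
})

test_that("channel opening reports the minimum with ties broken toward z = 0", {
  prof <- structure(data.frame(z = seq(-14.5, 14.5, 1),
                               density = rep(1, 30)),
                    span = 30, class = c("aqp_profile", "data.frame"))
  prof$density[prof$z == -5.5] <- 0.2
  prof$density[prof$z == 3.5] <- 0.2
  op <- channel_opening(prof)
  expect_equal(op$dmin, 0.2)
  expect_equal(op$z_at_dmin, 3.5)

  # flat profile: dmin equals the constant
  prof$density <- 0.7
  expect_equal(channel_opening(prof)$dmin, 0.7)

  # all-zero profile: zero with the degenerate flag
  prof$density <- 0
  op0 <- channel_opening(prof)
  expect_equal(op0$dmin, 0)
  expect_true(op0$degenerate)
})

test_that("layered 2D maps partition the slab and resolve geometry", {
  # cylindrical water column of radius 5
  set.seed(8)
  n <- 400; nf <- 40
  co <- array(0, c(n, 3, nf))
  for (f in seq_len(nf)) {
    r <- 5 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    co[, 1, f] <- r * cos(th); co[, 2, f] <- r * sin(th)
    co[, 3, f] <- runif(n, -15, 15)
  }
  tr <- trajectory(co, topology(rep("OH2", n), segment = "water", mass = 18),
                   c(30, 30, 40))
  w <- select_atoms(tr, segment = "water")
  maps <- layered_density_2d(tr, list(water = w))
  # protein selection on a water-only system: identically zero map
  maps_p <- layered_density_2d(tr, list(protein = select_atoms(
    tr, segment = "protein", label = "protein")))
  expect_true(all(vapply(maps_p$protein, function(h) all(h == 0), TRUE)))
  # counts over the six layers add up to the slab content
  tot <- sum(vapply(maps$water, function(h) sum(h) * 1 * 5 * nf, 1))
  in_slab <- sum(co[, 3, ] > -15 & co[, 3, ] <= 15)
  expect_equal(tot, in_slab, tolerance = 1e-9)
  # filled disc: no density outside the column radius
  h <- maps$water[[3]]
  xc <- as.numeric(rownames(h)); yc <- as.numeric(colnames(h))
  rr <- sqrt(outer(xc^2, yc^2, "+"))
  expect_equal(sum(h[rr > 7]), 0)
  expect_gt(sum(h[rr < 4]), 0)
})

test_that("pairwise energies reproduce the Coulomb and LJ closed forms", {
  m <- energy_model()
  expect_equal(pair_energy(10, q_i = 1, q_j = -1, model = m), -33.20636,
               tolerance = 1e-8)
  # LJ minimum: U(rmin) = -eps, near-zero slope
  u <- pair_energy(c(3.499, 3.5, 3.501), eps_i = 0.25, rminh_i = 1.75,
                   eps_j = 0.25, rminh_j = 1.75, model = m)
  expect_equal(u[2], -0.25, tolerance = 1e-9)
  expect_lt(abs(u[3] - u[1]), 1e-6)
  # beyond the cutoff: exactly zero
  expect_equal(pair_energy(12.5, q_i = 1, q_j = 1, model = m), 0)
})

test_that("a constant-velocity transit gives a flat residence profile", {
  z <- matrix(c(-14, seq(-12, 12, by = 1), 14), nrow = 1)
  co <- array(0, c(1, 3, ncol(z)))
  co[1, 3, ] <- z
  tr <- trajectory(co, topology("OH2", segment = "water", mass = 18,
                                charge = 0, lj_epsilon = 0),
                   c(40, 40, 50), dt_frame = 1)
  ev <- detect_permeation_events(tr, 1)
  expect_equal(nrow(ev), 1)
  suppressWarnings(tp <- transit_profiles(tr, ev, bin_width = 2))
  up <- tp[tp$direction == "up", ]
  integ <- sum(up$residence_time_density) * attr(tp, "bin_width")
  expect_equal(integ, ev$tau, tolerance = 1e-12)
  mid <- up$residence_time_density[abs(up$z) < 10]
  expect_lt(diff(range(mid)) / mean(mid), 1e-9)   # flat at uniform speed
})

test_that("residence-time integrals equal the mean transit time", {
  sp <- channel_spec(n_waters = 60, n_steps = 2e5, dt = 0.1, save_every = 20,
                     channel_radius = 6, seed = 12)
  tr <- simulate_channel_water(sp)
  ev <- detect_permeation_events(tr, select_atoms(tr, segment = "water"))
  tp <- transit_profiles(tr, ev, energetics = FALSE)
  mt <- attr(tp, "mean_tau")
  for (d in c("up", "down")) {
    sub <- tp[tp$direction == d, ]
    if (nrow(sub) == 0) next
    integ <- sum(sub$residence_time_density) * attr(tp, "bin_width")
    expect_lt(abs(integ / mt[[d]] - 1), 0.02)
  }
})

test_that("mobility profiles match a direct recomputation from the trajectory", {
  sp <- channel_spec(n_waters = 50, n_steps = 1e5, dt = 0.1, save_every = 20,
                     channel_radius = 6, seed = 14)
  tr <- simulate_channel_water(sp)
  ev <- detect_permeation_events(tr, select_atoms(tr, segment = "water"))
  ev <- ev[ev$confined, ]
  tp <- transit_profiles(tr, ev, energetics = FALSE, bin_width = 30)
  # oracle: mean 2 ps displacement over the same events, all bins pooled
  lag <- round(2 / tr$dt_frame)
  times <- frame_times(tr)
  disp <- unlist(lapply(seq_len(nrow(ev)), function(k) {
    fr <- which(times >= ev$t_star[k] & times <= ev$t_star[k] + ev$tau[k])
    p <- matrix(tr$coords[ev$molecule_id[k], , fr], nrow = 3)
    if (ncol(p) <= lag) return(numeric(0))
    sqrt(colSums((p[, -(1:lag), drop = FALSE] -
                  p[, 1:(ncol(p) - lag), drop = FALSE])^2))
  }))
  # single 30 A bin per direction: the profile means pool to the oracle mean
  expect_lt(abs(mean(tp$mobility, na.rm = TRUE) - mean(disp)) / mean(disp),
            0.02)
})

test_that("a chargeless, LJ-less water against a parameterised protein is zero", {
  # combining rules: sqrt(0 * eps) = 0 and q_w * q_p = 0 kill every term
  nf <- 30
  co <- array(0, c(3, 3, nf))
  co[1, 3, ] <- c(-14, seq(-12, 12, length.out = nf - 2), 14)
  co[2, , ] <- c(3, 0, 0)
  co[3, , ] <- c(-3, 0, 0)
  top <- topology(c("OH2", "CA", "CA"), segment = c("water", "protein",
                                                    "protein"),
                  mass = c(18, 12, 12), charge = c(0, 0.4, -0.4),
                  lj_epsilon = c(0, 0.2, 0.2), lj_rmin_half = c(0, 2, 2))
  tr <- trajectory(co, top, c(40, 40, 50), dt_frame = 1)
  tr <- center_on_group(tr, 2:3)
  ev <- detect_permeation_events(tr, 1)
  tp <- transit_profiles(tr, ev)
  expect_true(all(abs(tp$u_protein) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(tp$u_total) < 1e-12, na.rm = TRUE))
})

test_that("missing force-field parameters skip energetics with a warning", {
  z <- matrix(c(-14, seq(-12, 12, by = 2), 14), nrow = 1)
  co <- array(0, c(1, 3, ncol(z)))
  co[1, 3, ] <- z
  tr <- trajectory(co, topology("OH2", segment = "water", mass = 18,
                                charge = 0, lj_epsilon = 0),
                   c(40, 40, 50), dt_frame = 1)
  ev <- detect_permeation_events(tr, 1)
  expect_equal(nrow(ev[ev$confined, ]), 1)
  expect_warning(tp <- transit_profiles(tr, ev), "skipped")
  expect_true(all(is.na(tp$u_protein)))
  # geometry profiles are still produced
  expect_gt(sum(tp$residence_time_density), 0)
})
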