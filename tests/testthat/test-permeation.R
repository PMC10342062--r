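make_z_traj <- function(z, dt = 1, box = c(40, 40, 50)) {
  z <- as.matrix(z)
  co <- array(0, c(nrow(z), 3, ncol(z)))
  co[, 3, ] <- z
  trajectory(co, topology(name = rep("OH2", nrow(z)), segment = "water",
                          mass = 18.0154), box, dt)
}

test_that("slab geometry ties the span to the plane and compartment widths", {
  s <- slab_geometry()
  expect_equal(s$span, 30)
  expect_equal(slab_geometry(20, 4)$span, 24)
  expect_error(slab_geometry(-1, 5))
})

test_that("a monotone crossing yields one confined event with exact tau", {
  z <- matrix(c(-14, seq(-12.4, 12.4, length.out = 9), 14), nrow = 1)
  tr <- make_z_traj(z)
  ev <- detect_permeation_events(tr, 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "up")
  expect_equal(ev$t_star, 0)
  expect_equal(ev$tau, 10)
  expect_true(ev$confined)

  # oscillation that never reaches a compartment: no events
  z2 <- matrix(rep(c(-10, 10), 30), nrow = 1)
  expect_equal(nrow(detect_permeation_events(make_z_traj(z2), 1)), 0)
})

test_that("an excursion beyond the planes clears the confined flag", {
  z <- matrix(c(-14, -5, 13.2, -5, 5, 14, 5), nrow = 1)
  # visits upper compartment mid-way: event 1 up confined; then re-arms high,
  # wanders and completes nothing further
  ev <- detect_permeation_events(make_z_traj(z), 1)
  expect_equal(ev$direction, "up")
  expect_equal(nrow(ev), 1)

  # same path but with a dip beyond the lower compartment before completing
  z3 <- matrix(c(-14, -5, -19, -5, 5, 14), nrow = 1)
  ev3 <- detect_permeation_events(make_z_traj(z3), 1)
  expect_equal(nrow(ev3), 1)
  expect_false(ev3$confined)   # strayed outside (-Delta/2, Delta/2)
})

test_that("bulk wrap-arounds through the periodic boundary are not events", {
  # molecule drifts from the lower compartment into deep bulk, wraps to the
  # upper bulk and enters the upper compartment without touching the channel
  z <- matrix(c(-14, -20, -24.5, 24.5, 20, 14), nrow = 1)
  ev <- detect_permeation_events(make_z_traj(z), 1)
  expect_equal(nrow(ev), 0)
})

test_that("event detection matches the brute-force oracle exactly", {
  for (seed in 1:3) {
    tr <- random_walk_traj(50, 3000, step_sd = 1.2, seed = seed)
    cmp <- compare_detection(tr, select_atoms(tr, segment = "water"))
    expect_gt(nrow(cmp$got), 0)
    expect_equal(cmp$got, cmp$expected, tolerance = 1e-12)
  }
})

test_that("detection requires a centred protein", {
  tr <- random_walk_traj(5, 50, seed = 9)
  top <- tr$topology
  top$segment[1] <- "protein"
  top$mass[1] <- 1000
  tr2 <- trajectory(tr$coords, top, tr$box, tr$dt_frame)
  tr2$coords[1, 3, ] <- 5      # protein CoM far from the slab origin
  expect_error(detect_permeation_events(tr2, 2:5), "centred")
})

test_that("the permeation rate is per 100 ns and additive over windows", {
  ev <- data.frame(t_star = seq(0, 299, length.out = 79), tau = 1)
  expect_equal(permeation_rate(ev, window = 300), 26.33, tolerance = 1e-3)
  expect_equal(permeation_rate(ev[0, ], window = 100), 0)
  half1 <- sum(ev$t_star < 150)
  half2 <- sum(ev$t_star >= 150)
  expect_equal(half1 + half2, nrow(ev))
  expect_error(permeation_rate(ev, window = 0), "window")
})

test_that("diffusion permeability follows the unidirectional-rate convention", {
  vw <- 3.018e-23
  expect_equal(diffusion_permeability(79, 300, vw) * 1e15, 3.97,
               tolerance = 0.002)
  expect_equal(diffusion_permeability(40, 300, vw) * 1e15, 2.01,
               tolerance = 0.002)
  expect_equal(diffusion_permeability(0, 300, vw), 0)
  expect_error(diffusion_permeability(10, 0), "duration")
})

test_that("the collective coordinate counts net transits exactly", {
  # full crossing while inside: +1
  z <- matrix(seq(-13, 13, length.out = 40), nrow = 1)
  ser <- collective_coordinate(make_z_traj(z), 1)
  expect_equal(tail(ser$n, 1), 1, tolerance = 1e-12)
  # entering and exiting the same side: net 0
  z2 <- matrix(c(-14, -10, -2, -10, -14), nrow = 1)
  ser2 <- collective_coordinate(make_z_traj(z2), 1)
  expect_equal(tail(ser2$n, 1), 0, tolerance = 1e-12)
  # a bulk wrap-around contributes nothing
  z3 <- matrix(c(20, 24.5, -24.5, -20, 20), nrow = 1)
  ser3 <- collective_coordinate(make_z_traj(z3), 1)
  expect_equal(max(abs(ser3$n)), 0)
})

test_that("osmotic permeability recovers the diffusivity of a random walk", {
  set.seed(21)
  dtf <- 2
  sd_step <- 0.12
  n <- cumsum(c(0, rnorm(6e4, 0, sd_step)))
  ser <- structure(list(times = (seq_along(n) - 1) * dtf, n = n,
                        channel_length = 25, dt_frame = dtf),
                   class = "aqp_collective")
  pf <- osmotic_permeability(ser, vw = 1, fit_window = 100)
  Dn_true <- sd_step^2 / (2 * dtf)
  expect_lt(abs(attr(pf, "Dn_per_ps") - Dn_true) / Dn_true, 0.05)

  # constant series: pf = 0
  ser0 <- structure(list(times = ser$times, n = rep(1, length(n)),
                         channel_length = 25, dt_frame = dtf),
                    class = "aqp_collective")
  expect_equal(as.numeric(osmotic_permeability(ser0, vw = 1,
                                               fit_window = 100)), 0)
  expect_error(osmotic_permeability(ser0, fit_window = 1e6), "shorter")
})

test_that("equilibrium runs show no directional bias beyond counting noise", {
  sp <- channel_spec(n_waters = 60, n_steps = 2e5, dt = 0.1, save_every = 20,
                     channel_radius = 6, seed = 17)
  tr <- simulate_channel_water(sp)
  ev <- detect_permeation_events(tr, select_atoms(tr, segment = "water"))
  up <- sum(ev$direction == "up"); dn <- sum(ev$direction == "down")
  expect_gt(up + dn, 20)
  expect_lte(abs(up - dn), 3 * sqrt(up + dn))
})

test_that("denser frame sampling does not lose events", {
  sp_fine <- channel_spec(n_waters = 40, n_steps = 1e5, dt = 0.05,
                          save_every = 20, channel_radius = 6, seed = 23)
  sp_coarse <- channel_spec(n_waters = 40, n_steps = 1e5, dt = 0.05,
                            save_every = 40, channel_radius = 6, seed = 23)
  tr_f <- simulate_channel_water(sp_fine)
  tr_c <- simulate_channel_water(sp_coarse)
  # identical underlying dynamics: the coarse frames are a subset
  expect_equal(tr_c$coords[, , 2], tr_f$coords[, , 3])
  nf <- nrow(detect_permeation_events(tr_f, select_atoms(tr_f, segment = "water")))
  nc <- nrow(detect_permeation_events(tr_c, select_atoms(tr_c, segment = "water")))
  expect_gte(nf, nc)
})

test_that("permeability summary flags the transport regime", {
  sp <- channel_spec(n_waters = 50, n_steps = 2e5, dt = 0.1, save_every = 20,
                     channel_radius = 7, seed = 19)
  tr <- simulate_channel_water(sp)
  ps <- permeability_summary(tr, select_atoms(tr, segment = "water"),
                             fit_window = 100)
  expect_gt(ps$n_events, 0)
  expect_equal(ps$nw, ps$n_events * 100 / ps$duration)
  expect_false(ps$single_file_regime)   # independent waters: ratio < 2

  # an event-free trajectory gives a zero summary with undefined ratio
  z <- matrix(rep(0, 4000), nrow = 2)
  tr0 <- make_z_traj(z, dt = 25)
  ps0 <- permeability_summary(tr0, 1:2, fit_window = 100)
  expect_equal(ps0$n_events, 0)
  expect_equal(ps0$pd, 0)
  expect_true(is.na(ps0$ratio))
})
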