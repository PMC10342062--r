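# Independent oracles and fixture builders shared across the test files.

# Brute-force permeation-event oracle: frame-by-frame state machine with the
# published two-plane / two-compartment rule, implemented independently of
# the package's compiled scan (vectorised over molecules, explicit loop over
# frames).  z must already be wrapped into the primary cell and centred.
oracle_detect <- function(z, times, half, small) {
  nm <- nrow(z); nf <- ncol(z)
  armed <- integer(nm); t_arm <- integer(nm); nonmid <- integer(nm)
  rows <- vector("list", 256); oi <- 0
  for (t in seq_len(nf)) {
    zz <- z[, t]
    zone <- integer(nm)
    zone[zz <= -half - small] <- -2L
    zone[zz > -half - small & zz < -half] <- -1L
    zone[zz > half & zz < half + small] <- 1L
    zone[zz >= half + small] <- 2L
    for (i in which(zone == 1L & armed == -1L)) {
      oi <- oi + 1
      rows[[oi]] <- c(i, times[t_arm[i]], times[t] - times[t_arm[i]], 1,
                      nonmid[i] == 0L)
    }
    for (i in which(zone == -1L & armed == 1L)) {
      oi <- oi + 1
      rows[[oi]] <- c(i, times[t_arm[i]], times[t] - times[t_arm[i]], -1,
                      nonmid[i] == 0L)
    }
    lo <- zone == -1L; hi <- zone == 1L
    armed[lo] <- -1L; armed[hi] <- 1L
    t_arm[lo | hi] <- t; nonmid[lo | hi] <- 0L
    olo <- zone == -2L; ohi <- zone == 2L
    armed[olo & armed == 1L] <- 0L
    armed[ohi & armed == -1L] <- 0L
    nonmid[olo | ohi] <- nonmid[olo | ohi] + 1L
  }
  if (oi == 0)
    return(data.frame(molecule = integer(0), t_star = numeric(0),
                      tau = numeric(0), direction = numeric(0),
                      confined = logical(0)))
  m <- do.call(rbind, rows[seq_len(oi)])
  out <- data.frame(molecule = m[, 1], t_star = m[, 2], tau = m[, 3],
                    direction = m[, 4], confined = m[, 5] == 1)
  out[order(out$molecule, out$t_star), ]
}

# run the package detector and the oracle on the same trajectory and return
# both event tables in a comparable, sorted layout
compare_detection <- function(traj, waters, slab = slab_geometry()) {
  ev <- detect_permeation_events(traj, waters, slab)
  got <- data.frame(molecule = ev$molecule_id, t_star = ev$t_star,
                    tau = ev$tau,
                    direction = ifelse(ev$direction == "up", 1, -1),
                    confined = ev$confined)
  got <- got[order(got$molecule, got$t_star), ]
  idx <- if (inherits(waters, "aqp_selection")) waters$indices else waters
  z <- traj$coords[idx, 3, , drop = FALSE]
  z <- matrix(z, nrow = length(idx))
  bz <- traj$box[1, 3]
  z <- z - bz * round(z / bz)
  exp <- oracle_detect(z, (seq_len(traj$n_frames) - 1) * traj$dt_frame,
                       slab$delta_big / 2, slab$delta_small)
  exp$molecule <- idx[exp$molecule]
  rownames(got) <- rownames(exp) <- NULL
  list(got = got, expected = exp)
}

# random-walk water trajectory: nm independent Gaussian walkers in z
# (wrapped box), lateral coordinates frozen at 0
random_walk_traj <- function(nm, nf, step_sd = 1, box = c(40, 40, 50),
                             dt_frame = 2, seed = 1) {
  set.seed(seed)
  z0 <- runif(nm, -box[3] / 2, box[3] / 2)
  steps <- matrix(rnorm(nm * (nf - 1), 0, step_sd), nrow = nm)
  z <- cbind(z0, z0 + t(apply(steps, 1, cumsum)))
  z <- z - box[3] * round(z / box[3])
  co <- array(0, c(nm, 3, nf))
  co[, 3, ] <- z
  trajectory(co, topology(name = rep("OH2", nm), segment = "water",
                          mass = 18.0154),
             box, dt_frame)
}

# term-by-term vibrational-weight oracle: plain loops over beads, moment of
# inertia about the angular-momentum axis through the CoM
oracle_wv <- function(e_mat, ref, masses) {
  nm <- ncol(e_mat)
  wv <- numeric(nm)
  for (i in seq_len(nm)) {
    e <- matrix(e_mat[, i], ncol = 3, byrow = TRUE)
    w_tot <- 0
    gam <- c(0, 0, 0)
    for (k in seq_len(nrow(e))) {
      w_tot <- w_tot + 0.5 * masses[k] * sum(e[k, ]^2)
      r <- ref[k, ]
      gam <- gam + masses[k] *
        c(r[2] * e[k, 3] - r[3] * e[k, 2],
          r[3] * e[k, 1] - r[1] * e[k, 3],
          r[1] * e[k, 2] - r[2] * e[k, 1])
    }
    g2 <- sum(gam^2)
    if (g2 < 1e-18) { wv[i] <- 1; next }
    ax <- gam / sqrt(g2)
    J <- 0
    for (k in seq_len(nrow(e)))
      J <- J + masses[k] * (sum(ref[k, ]^2) - sum(ref[k, ] * ax)^2)
    w_r <- g2 / (2 * J)
    wv[i] <- min(max((w_tot - w_r) / w_tot, 0), 1)
  }
  wv
}

# orthonormal displacement patterns free of mass-weighted translation, built
# by projecting raw patterns and re-orthogonalising
internal_modes <- function(raw, masses) {
  n <- length(masses)
  P <- diag(3 * n)
  for (d in 1:3) {
    t_d <- rep(0, 3 * n)
    t_d[seq(d, 3 * n, by = 3)] <- 1
    w <- rep(masses, each = 3) * t_d
    P <- P - outer(t_d, w) / sum(masses)   # removes mass-weighted CoM shift
  }
  out <- NULL
  for (j in seq_len(ncol(raw))) {
    v <- P %*% raw[, j]
    if (!is.null(out)) for (k in seq_len(ncol(out)))
      v <- v - sum(v * out[, k]) * out[, k]
    v <- v / sqrt(sum(v^2))
    out <- cbind(out, v)
  }
  out
}

# default four-bead rectangle reference used across PCA tests
bead_ref4 <- rbind(c(-5, 0, -7.5), c(-5, 0, 7.5), c(5, 0, -7.5), c(5, 0, 7.5))
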