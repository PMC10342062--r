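# Synthetic trajectory generators with known ground truth.
#
# Two families: (1) overdamped Brownian channel-water systems — bulk
# reservoirs, an impenetrable membrane slab pierced by a cylindrical channel,
# a tabulated axial potential U(z), and an optional single-file regime with
# fixed in-channel occupancy N; (2) harmonic bead networks sampled from a
# prescribed covariance, with optional superposed rigid-body rotation, so
# that PCA eigenvalues, vibrational weights and softness are recoverable
# against ground truth.  Every generator takes an explicit seed; the same
# spec is bit-reproducible.

# run code under a private R RNG stream; the global seed state is restored
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a Brownian channel-water system
#'
#' @param box orthorhombic box lengths `c(Lx, Ly, Lz)`, Angstrom.  The
#'   membrane slab occupies `|z| < membrane_span/2`; the remaining z range on
#'   each side is bulk reservoir.
#' @param membrane_span membrane thickness, Angstrom (default 30, the full
#'   span a permeating water must cross).
#' @param channel_radius radius of the cylindrical channel, Angstrom.
#' @param potential optional `data.frame(z, u)` with U(z) in kcal/mol;
#'   `NULL` means a flat potential.
#' @param diffusion_coefficient water diffusion coefficient D, A^2/ps
#'   (default 0.23, bulk water at ~300 K).
#' @param n_waters number of water molecules (single-site, tracked by their
#'   oxygen position).
#' @param single_file if `TRUE`, the channel holds exactly
#'   `single_file_occupancy` waters that cannot pass each other; occupancy is
#'   maintained by exchange with the reservoirs at the mouths.
#' @param single_file_occupancy in-channel water count N for the single-file
#'   regime.
#' @param temperature K.
#' @param dt integration timestep, ps.
#' @param n_steps number of integration steps.
#' @param save_every store every this-many steps (frame stride; the stored
#'   `dt_frame` is `dt * save_every`).
#' @param membrane set `FALSE` for a free bulk box with no membrane or
#'   channel (used, e.g., to validate diffusion estimators).
#' @param seed mandatory integer seed.
#' @return object of class `aqp_channel_spec`.
#' @export
channel_spec <- function(box = c(40, 40, 50), membrane_span = 30,
                         channel_radius = 4, potential = NULL,
                         diffusion_coefficient = 0.23, n_waters = 60,
                         single_file = FALSE, single_file_occupancy = 4,
                         temperature = 303.15, dt = 0.05,
                         n_steps = 1e5, save_every = 20,
                         membrane = TRUE, seed) {
  if (missing(seed)) stop("channel_spec: a seed is mandatory")
  stopifnot(length(box) == 3, all(box > 0), channel_radius > 0,
            diffusion_coefficient >= 0, dt > 0, n_steps >= 1,
            save_every >= 1, membrane_span > 0, membrane_span < box[3])
  if (single_file && single_file_occupancy < 1)
    stop("channel_spec: single-file occupancy must be >= 1")
  if (!is.null(potential))
    stopifnot(is.data.frame(potential), all(c("z", "u") %in% names(potential)))
  structure(list(box = box, membrane_span = membrane_span,
                 channel_radius = channel_radius, potential = potential,
                 diffusion_coefficient = diffusion_coefficient,
                 n_waters = n_waters, single_file = single_file,
                 single_file_occupancy = single_file_occupancy,
                 temperature = temperature, dt = dt, n_steps = n_steps,
                 save_every = save_every, membrane = membrane,
                 seed = as.integer(seed)),
            class = "aqp_channel_spec")
}

#' Gaussian axial potential barrier
#'
#' Convenience builder for a tabulated U(z) with a single Gaussian barrier,
#' e.g. the ~4 kcal/mol constriction barrier typical of an inward-facing
#' transporter channel.
#'
#' @param height barrier height, kcal/mol.
#' @param center barrier position, Angstrom.
#' @param width Gaussian sigma, Angstrom.
#' @param z_range,dz tabulation range and grid spacing.
#' @return `data.frame(z, u)` suitable for [channel_spec()].
#' @export
gaussian_barrier <- function(height = 4, center = 0, width = 3,
                             z_range = c(-17, 17), dz = 0.1) {
  z <- seq(z_range[1], z_range[2], by = dz)
  data.frame(z = z, u = height * exp(-(z - center)^2 / (2 * width^2)))
}

#' Simulate a Brownian channel-water trajectory
#'
#' Integrates overdamped Langevin dynamics for the spec's waters and returns
#' a standard trajectory (single-site waters, segment `"water"`).  In
#' single-file mode the in-channel ordering along z is preserved at every
#' step and the occupancy is exactly N at all times.
#'
#' @param spec an [channel_spec()].
#' @return an `aqp_trajectory` with attribute `"n_exchanges"` (single-file
#'   mouth exchanges).
#' @export
simulate_channel_water <- function(spec) {
  stopifnot(inherits(spec, "aqp_channel_spec"))
  kT <- .kB * spec$temperature
  if (!is.null(spec$potential)) {
    zg <- seq(min(spec$potential$z), max(spec$potential$z), by = 0.1)
    ug <- approx(spec$potential$z, spec$potential$u, zg, rule = 2)$y
    ng <- length(zg)
    du <- numeric(ng)
    du[2:(ng - 1)] <- (ug[3:ng] - ug[1:(ng - 2)]) / (zg[3] - zg[1])
    maxstep <- max(abs(du)) * spec$dt * spec$diffusion_coefficient / kT
    if (maxstep > 0.5)
      stop("simulate_channel_water: dt too large for the potential barrier ",
           "(deterministic step ", signif(maxstep, 3), " A > 0.5 A)")
  } else {
    zg <- numeric(0); du <- numeric(0)
  }
  res <- cpp_simulate_channel(
    spec$n_waters, spec$box[1], spec$box[2], spec$box[3],
    spec$membrane_span, spec$channel_radius, zg, du,
    spec$diffusion_coefficient, kT, spec$dt, as.integer(spec$n_steps),
    as.integer(spec$save_every), spec$single_file,
    as.integer(spec$single_file_occupancy), spec$membrane, spec$seed)
  top <- topology(name = rep("OH2", spec$n_waters),
                  residue_id = seq_len(spec$n_waters),
                  residue_name = "TIP3", segment = "water",
                  mass = 18.0154, charge = 0,
                  lj_epsilon = 0.1521, lj_rmin_half = 1.7682)
  traj <- trajectory(res$coords, top, spec$box,
                     dt_frame = spec$dt * spec$save_every)
  attr(traj, "n_exchanges") <- res$n_exchanges
  attr(traj, "spec") <- spec
  traj
}

#' Specification of a harmonic bead network
#'
#' @param masses bead masses, amu (length n).
#' @param reference n x 3 reference (mean) positions, Angstrom.  Default: a
#'   four-bead rectangle mimicking two membrane-spanning domains (two beads
#'   each for the lower/upper halves of a "bundle" at x < 0 and a "hash" at
#'   x > 0).
#' @param target_covariance 3n x 3n positive semi-definite covariance of the
#'   vibrational displacements, A^2 (coordinate order: bead-major x,y,z).
#' @param rigid_rotation_amplitude sd of the per-frame rigid rotation angle,
#'   radians (0 = none).
#' @param rotation_axis axis of the superposed rigid rotation.
#' @param n_samples number of frames.
#' @param dt_frame frame spacing, ps.
#' @param seed mandatory integer seed.
#' @return object of class `aqp_bead_spec`.
#' @export
bead_network_spec <- function(masses = rep(5000, 4),
                              reference = NULL,
                              target_covariance,
                              rigid_rotation_amplitude = 0,
                              rotation_axis = c(0, 0, 1),
                              n_samples = 5000, dt_frame = 1, seed) {
  if (missing(seed)) stop("bead_network_spec: a seed is mandatory")
  n <- length(masses)
  if (is.null(reference)) {
    stopifnot(n == 4)
    reference <- rbind(c(-5, 0, -7.5), c(-5, 0, 7.5),
                       c(5, 0, -7.5), c(5, 0, 7.5))
  }
  reference <- as.matrix(reference)
  stopifnot(all(masses > 0), nrow(reference) == n, ncol(reference) == 3)
  C <- as.matrix(target_covariance)
  stopifnot(nrow(C) == 3 * n, ncol(C) == 3 * n)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop("bead_network_spec: target covariance must be symmetric")
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("bead_network_spec: target covariance must be positive semi-definite")
  structure(list(n_beads = n, masses = as.numeric(masses),
                 reference = reference, target_covariance = (C + t(C)) / 2,
                 rigid_rotation_amplitude = rigid_rotation_amplitude,
                 rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2)),
                 n_samples = as.integer(n_samples), dt_frame = dt_frame,
                 seed = as.integer(seed)),
            class = "aqp_bead_spec")
}

# rotation matrix about a unit axis (Rodrigues)
.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Sample a harmonic bead-network trajectory
#'
#' Frames are drawn independently from a multivariate normal with the spec's
#' covariance about the reference structure; an optional rigid-body rotation
#' about the centre of mass is superposed frame by frame; the mass-weighted
#' centre-of-mass translation is removed exactly from every frame.
#'
#' @param spec a [bead_network_spec()].
#' @param domain_label optional per-bead domain labels (e.g.
#'   `c("bundle","bundle","hash","hash")`) stored in the topology.
#' @return an `aqp_trajectory` with segment `"protein"` beads.
#' @export
sample_bead_network <- function(spec, domain_label = "none") {
  stopifnot(inherits(spec, "aqp_bead_spec"))
  n <- spec$n_beads; nf <- spec$n_samples
  eg <- eigen(spec$target_covariance, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  A <- eg$vectors %*% diag(sqrt(lam), length(lam))
  ref <- as.vector(t(spec$reference))        # bead-major x,y,z
  m <- spec$masses
  co <- with_seed(spec$seed, {
    Z <- matrix(rnorm(nf * 3 * n), nrow = 3 * n)
    X <- A %*% Z + ref                       # 3n x nf
    out <- array(0, c(n, 3, nf))
    angles <- if (spec$rigid_rotation_amplitude > 0)
      rnorm(nf, 0, spec$rigid_rotation_amplitude) else numeric(nf)
    for (f in seq_len(nf)) {
      P <- matrix(X[, f], ncol = 3, byrow = TRUE)
      com <- colSums(P * m) / sum(m)
      if (angles[f] != 0) {
        R <- .rotation_matrix(spec$rotation_axis, angles[f])
        P <- sweep(sweep(P, 2, com) %*% t(R), 2, com, "+")
        com <- colSums(P * m) / sum(m)
      }
      out[, , f] <- sweep(P, 2, com)         # remove CoM translation
    }
    out
  })
  top <- topology(name = paste0("BD", seq_len(n)), residue_id = seq_len(n),
                  residue_name = "BEA", segment = "protein", mass = m,
                  domain_label = domain_label)
  trajectory(co, top, box = c(500, 500, 500), dt_frame = spec$dt_frame)
}

#' Build a static-density profile fixture
#'
#' Generates a trajectory with water, pseudo-protein and optional membrane
#' segments in which every frame's waters are an independent ideal-gas
#' snapshot whose z density can carry a constructed depletion (constriction)
#' zone.  Protein atoms carry charges and LJ parameters so interaction-energy
#' profiles are computable.
#'
#' @param n_waters waters per frame.
#' @param protein_blob list with `n_atoms`, `spread` (A), `charge` (e),
#'   `epsilon` (kcal/mol), `rmin_half` (A); `n_atoms = 0` gives a
#'   protein-free fixture.
#' @param n_frames frames to generate.
#' @param box box lengths, Angstrom.
#' @param depletion optional list `(center, width, keep)`: water density at
#'   the constriction is multiplied by
#'   `1 - (1-keep) * exp(-(z-center)^2/(2 width^2))`.
#' @param membrane_atoms number of static membrane pseudo-atoms in the slab
#'   `10 < |z| < 15`.
#' @param water_charge partial charge on the single-site waters.
#' @param seed mandatory integer seed.
#' @return an `aqp_trajectory`.
#' @export
make_profile_fixture <- function(n_waters,
                                 protein_blob = list(n_atoms = 20, spread = 5,
                                                     charge = 0.2,
                                                     epsilon = 0.1,
                                                     rmin_half = 2.0),
                                 n_frames = 50, box = c(30, 30, 60),
                                 depletion = NULL, membrane_atoms = 0,
                                 water_charge = -0.834, seed) {
  if (missing(seed)) stop("make_profile_fixture: a seed is mandatory")
  stopifnot(n_waters > 0, n_frames > 0)
  np <- protein_blob$n_atoms
  with_seed(seed, {
    # static pseudo-protein cluster at the origin
    pro <- if (np > 0) matrix(rnorm(np * 3, 0, protein_blob$spread), ncol = 3)
           else matrix(0, 0, 3)
    mem <- if (membrane_atoms > 0) {
      zm <- runif(membrane_atoms, 10, 15) * sample(c(-1, 1), membrane_atoms,
                                                   replace = TRUE)
      cbind(runif(membrane_atoms, -box[1] / 2, box[1] / 2),
            runif(membrane_atoms, -box[2] / 2, box[2] / 2), zm)
    } else matrix(0, 0, 3)
    keepfun <- if (is.null(depletion)) function(z) rep(TRUE, length(z))
      else function(z) runif(length(z)) <
        1 - (1 - depletion$keep) * exp(-(z - depletion$center)^2 /
                                       (2 * depletion$width^2))
    n_atoms <- n_waters + np + membrane_atoms
    co <- array(0, c(n_atoms, 3, n_frames))
    for (f in seq_len(n_frames)) {
      zs <- numeric(0)
      while (length(zs) < n_waters) {
        cand <- runif(2 * n_waters, -box[3] / 2, box[3] / 2)
        zs <- c(zs, cand[keepfun(cand)])
      }
      zs <- zs[seq_len(n_waters)]
      wat <- cbind(runif(n_waters, -box[1] / 2, box[1] / 2),
                   runif(n_waters, -box[2] / 2, box[2] / 2), zs)
      co[, , f] <- rbind(wat, pro, mem)
    }
    top <- topology(
      name = c(rep("OH2", n_waters), rep("CA", np), rep("C2", membrane_atoms)),
      residue_id = seq_len(n_atoms),
      residue_name = c(rep("TIP3", n_waters), rep("PRO", np),
                       rep("POPC", membrane_atoms)),
      segment = c(rep("water", n_waters), rep("protein", np),
                  rep("membrane", membrane_atoms)),
      mass = c(rep(18.0154, n_waters), rep(100, np), rep(50, membrane_atoms)),
      charge = c(rep(water_charge, n_waters),
                 rep(if (np > 0) protein_blob$charge else 0, np),
                 rep(0, membrane_atoms)),
      lj_epsilon = c(rep(0.1521, n_waters),
                     rep(if (np > 0) protein_blob$epsilon else 0, np),
                     rep(0.1, membrane_atoms)),
      lj_rmin_half = c(rep(1.7682, n_waters),
                       rep(if (np > 0) protein_blob$rmin_half else 0, np),
                       rep(2, membrane_atoms)))
    trajectory(co, top, box, dt_frame = 2)
  })
}

#' Build a constructed-effect multi-window fixture
#'
#' Concatenates independently generated segments, one per analysis window,
#' in which a single effect scale jointly modulates (a) the channel-water
#' subsystem — the constriction barrier is lowered and the water diffusion
#' coefficient raised as the scale grows, so the channel opening dmin and
#' the permeation rate nw rise together — and (b) an embedded eight-atom
#' bundle/hash pseudo-protein whose fluctuation amplitude along the
#' separation and rocking patterns grows with the same scale, so the domain
#' softness rises too.  The result is ground truth for the windowed
#' correlation analysis: every flux/opening/softness panel has a positive
#' correlation by construction.
#'
#' @param n_windows number of windows (segments).
#' @param window_ns window length, ns.
#' @param effect per-window effect scales (default an increasing ramp
#'   0.6..1.6).
#' @param mode which inputs the effect scale modulates:
#'   `"opening"` ramps the constriction barrier down (channel opening and
#'   flux grow together at fixed dynamics — the channel-opening panel);
#'   `"dynamics"` ramps the water diffusion coefficient and the domain
#'   fluctuation amplitude at fixed barrier (flux per unit opening and local
#'   diffusion grow with softness — the softness panels);
#'   `"combined"` ramps everything.
#' @param n_waters waters per segment.
#' @param base_D baseline water diffusion coefficient, A^2/ps.
#' @param seed mandatory integer seed.
#' @return an `aqp_trajectory` with `water` and domain-labelled `protein`
#'   segments; attribute `effect` stores the per-window scales.
#' @export
make_window_fixture <- function(n_windows = 8, window_ns = 5,
                                effect = seq(0.6, 1.6,
                                             length.out = n_windows),
                                mode = c("combined", "opening", "dynamics"),
                                n_waters = 80, base_D = 0.23, seed) {
  if (missing(seed)) stop("make_window_fixture: a seed is mandatory")
  mode <- match.arg(mode)
  stopifnot(n_windows >= 3, length(effect) == n_windows)
  dt <- 0.1; save_every <- 20
  fpw <- round(window_ns * 1000 / (dt * save_every))
  n_steps <- fpw * save_every
  # bead displacement patterns (equal masses): bundle-hash separation along
  # x and the rocking pattern; both mass-CoM-free by symmetry
  v_sep <- c(1, 0, 0, 1, 0, 0, -1, 0, 0, -1, 0, 0) / 2
  v_rock <- c(1, 0, 0, -1, 0, 0, -1, 0, 0, 1, 0, 0) / 2
  ref <- rbind(c(-5, 0, -7.5), c(-5, 0, 7.5), c(5, 0, -7.5), c(5, 0, 7.5))
  segs <- vector("list", n_windows)
  ramp <- function(x) (x - min(effect)) / max(diff(range(effect)), 1e-9)
  for (w in seq_len(n_windows)) {
    sw <- effect[w]
    h <- if (mode == "dynamics") 1.0 else 2.0 - 1.5 * ramp(sw)
    Dw <- if (mode == "opening") base_D else base_D * sw
    amp <- if (mode == "opening") 0.02 else 0.02 * sw
    cs <- channel_spec(box = c(40, 40, 50), channel_radius = 6,
                       potential = gaussian_barrier(height = h, center = 0,
                                                    width = 2.5),
                       diffusion_coefficient = Dw,
                       n_waters = n_waters, dt = dt, n_steps = n_steps,
                       save_every = save_every, seed = seed + 17 * w)
    wat <- simulate_channel_water(cs)
    wat <- subset_frames(wat, seq_len(fpw))
    C <- amp * (v_sep %o% v_sep + v_rock %o% v_rock)
    bs <- bead_network_spec(masses = rep(4000, 4), reference = ref,
                            target_covariance = C, n_samples = fpw,
                            dt_frame = dt * save_every, seed = seed + 1000 + w)
    beads <- sample_bead_network(bs)
    # expand each bead into two atoms so the four-bead reduction and the
    # selected-residue softness both have material to work with
    co <- array(0, c(8, 3, fpw))
    off <- c(-0.5, 0.5)
    for (b in 1:4) for (j in 1:2) {
      co[(b - 1) * 2 + j, , ] <- beads$coords[b, , ]
      co[(b - 1) * 2 + j, 2, ] <- co[(b - 1) * 2 + j, 2, ] + off[j]
    }
    ptop <- topology(name = rep("CA", 8),
                     residue_id = 1:8, residue_name = "DOM",
                     segment = "protein", mass = rep(2000, 8),
                     domain_label = rep(c("bundle", "hash"), each = 4))
    pro <- trajectory(co, ptop, wat$box[seq_len(fpw), , drop = FALSE],
                      dt_frame = dt * save_every)
    segs[[w]] <- merge_atoms(wat, pro)
  }
  out <- Reduce(bind_frames, segs)
  attr(out, "effect") <- effect
  out
}
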