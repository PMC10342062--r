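# Density and per-transit profiles along the membrane normal.

#' Water number-density profile along z
#'
#' Time-averaged histogram of the selection's wrapped z coordinates,
#' normalised to number density (A^-3) using the lateral box area.  The
#' profile carries `dmin`, the minimum density within the membrane span,
#' used as the channel-opening measure.
#'
#' @param traj centred trajectory.
#' @param selection atoms to histogram (e.g. water oxygens).
#' @param bin_width z bin width, Angstrom.
#' @param window optional time window `c(t0, t1)` in ns (inclusive of frames
#'   with `t0 <= t < t1`); `NULL` uses all frames.
#' @param span membrane span over which `dmin` is sought, Angstrom.
#' @return object of class `aqp_profile`: data.frame with `z` (bin centre)
#'   and `density`, plus attributes `dmin`, `z_at_dmin`, `species`, `window`.
#' @export
density_profile <- function(traj, selection, bin_width = 1, window = NULL,
                            span = 30) {
  idx <- .as_indices(traj, selection)
  frames <- .window_frames(traj, window)
  if (length(frames) == 0) stop("density_profile: empty time window")
  z <- .wrapped_z(traj, idx)[, frames, drop = FALSE]
  half_bz <- max(traj$box[frames, 3]) / 2
  edges <- seq(-ceiling(half_bz / bin_width) * bin_width,
               ceiling(half_bz / bin_width) * bin_width, by = bin_width)
  counts <- tabulate(findInterval(as.vector(z), edges), length(edges) - 1)
  area <- mean(traj$box[frames, 1] * traj$box[frames, 2])
  dens <- counts / (length(frames) * bin_width * area)
  centers <- edges[-length(edges)] + bin_width / 2
  out <- data.frame(z = centers, density = dens)
  inside <- abs(centers) <= span / 2
  dm <- .profile_min(centers[inside], dens[inside])
  structure(out, dmin = dm$value, z_at_dmin = dm$z, degenerate = dm$degenerate,
            species = if (inherits(selection, "aqp_selection"))
              selection$label else "selection",
            window = window, span = span, bin_width = bin_width,
            class = c("aqp_profile", "data.frame"))
}

.window_frames <- function(traj, window) {
  if (is.null(window)) return(seq_len(traj$n_frames))
  t_ns <- frame_times(traj) / 1000
  which(t_ns >= window[1] & t_ns < window[2])
}

# minimum with ties broken toward z closest to 0
.profile_min <- function(z, d) {
  if (length(d) == 0 || all(d == 0))
    return(list(value = 0, z = NA_real_, degenerate = TRUE))
  mn <- min(d)
  cand <- z[d == mn]
  list(value = mn, z = cand[which.min(abs(cand))], degenerate = FALSE)
}

#' Channel opening from a density profile
#'
#' The channel-opening measure is the minimum of the water number-density
#' profile within the membrane span; ties are broken toward the z closest to
#' the membrane centre.  An all-zero profile returns 0 with
#' `degenerate = TRUE`.
#'
#' @param profile an [density_profile()] result.
#' @return list with `dmin` (A^-3), `z_at_dmin` (A) and `degenerate`.
#' @export
channel_opening <- function(profile) {
  span <- attr(profile, "span")
  inside <- abs(profile$z) <= span / 2
  dm <- .profile_min(profile$z[inside], profile$density[inside])
  list(dmin = dm$value, z_at_dmin = dm$z, degenerate = dm$degenerate)
}

#' Layered 2D density maps
#'
#' Per z layer and per selection, the (x, y) number-density map averaged over
#' the window — the standard way to visualise where water sits relative to
#' the protein domains in consecutive slabs across the membrane.
#'
#' @param traj centred trajectory.
#' @param selections named list of selections (e.g.
#'   `list(water = ..., protein = ...)`).
#' @param z_layers list of `c(lo, hi)` z ranges, Angstrom; default six 5 A
#'   layers spanning -15..15.
#' @param bin_xy lateral bin width, Angstrom.
#' @param window optional `c(t0, t1)` ns window.
#' @return nested list `[[selection]][[layer]]` of matrices (x rows, y
#'   columns, A^-3), with bin-centre dimnames; attribute `layers`.
#' @export
layered_density_2d <- function(traj, selections,
                               z_layers = lapply(seq(-15, 10, 5),
                                                 function(a) c(a, a + 5)),
                               bin_xy = 1, window = NULL) {
  if (inherits(selections, "aqp_selection")) selections <- list(selections)
  frames <- .window_frames(traj, window)
  bx <- max(traj$box[frames, 1]) / 2; by <- max(traj$box[frames, 2]) / 2
  ex <- seq(-ceiling(bx / bin_xy) * bin_xy, ceiling(bx / bin_xy) * bin_xy,
            by = bin_xy)
  ey <- seq(-ceiling(by / bin_xy) * bin_xy, ceiling(by / bin_xy) * bin_xy,
            by = bin_xy)
  empty_map <- matrix(0, length(ex) - 1, length(ey) - 1,
                      dimnames = list(ex[-length(ex)] + bin_xy / 2,
                                      ey[-length(ey)] + bin_xy / 2))
  out <- lapply(selections, function(sel) {
    n_sel <- if (inherits(sel, "aqp_selection")) length(sel$indices)
             else length(sel)
    if (n_sel == 0)                     # e.g. no protein in a water-only box
      return(lapply(z_layers, function(ly) empty_map))
    idx <- .as_indices(traj, sel)
    x <- matrix(traj$coords[idx, 1, frames], nrow = length(idx))
    y <- matrix(traj$coords[idx, 2, frames], nrow = length(idx))
    z <- .wrapped_z(traj, idx)[, frames, drop = FALSE]
    lapply(z_layers, function(ly) {
      sel_in <- z > ly[1] & z <= ly[2]
      h <- matrix(0, length(ex) - 1, length(ey) - 1,
                  dimnames = list(ex[-length(ex)] + bin_xy / 2,
                                  ey[-length(ey)] + bin_xy / 2))
      if (any(sel_in)) {
        ix <- findInterval(x[sel_in], ex, rightmost.closed = TRUE)
        iy <- findInterval(y[sel_in], ey, rightmost.closed = TRUE)
        ok <- ix >= 1 & ix <= nrow(h) & iy >= 1 & iy <= ncol(h)
        for (k in which(ok)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
      }
      h / (length(frames) * bin_xy^2 * (ly[2] - ly[1]))
    })
  })
  attr(out, "layers") <- z_layers
  out
}

#' Nonbonded interaction model
#'
#' Pairwise Lennard-Jones (CHARMM Rmin/2 convention, Lorentz-Berthelot
#' combining) plus Coulomb, truncated at the cutoff.  These are analysis
#' energies for per-molecule interaction profiles, not simulation forces.
#'
#' @param cutoff nonbonded cutoff, Angstrom.
#' @param coulomb_constant Coulomb constant, kcal A / (mol e^2).
#' @return object of class `aqp_energy_model`.
#' @export
energy_model <- function(cutoff = 12, coulomb_constant = .kCoulomb) {
  stopifnot(cutoff > 0)
  structure(list(cutoff = cutoff, coulomb_constant = coulomb_constant),
            class = "aqp_energy_model")
}

#' Pairwise interaction energy
#'
#' `U(r) = eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ] + k q_i q_j / r` for
#' `r < cutoff`, else 0, with `eps_ij = sqrt(eps_i eps_j)` and
#' `rmin_ij = rmin_half_i + rmin_half_j`.
#'
#' @param r distance(s), Angstrom.
#' @param eps_i,eps_j LJ well depths, kcal/mol.
#' @param rminh_i,rminh_j LJ Rmin/2 values, Angstrom.
#' @param q_i,q_j charges, e.
#' @param model an [energy_model()].
#' @return energy in kcal/mol (vectorised over `r`).
#' @export
pair_energy <- function(r, eps_i = 0, rminh_i = 0, q_i = 0,
                        eps_j = 0, rminh_j = 0, q_j = 0,
                        model = energy_model()) {
  eps <- sqrt(eps_i * eps_j)
  rmin <- rminh_i + rminh_j
  u <- numeric(length(r))
  ok <- r < model$cutoff & r > 0
  if (any(ok)) {
    sr6 <- (rmin / r[ok])^6
    u[ok] <- eps * (sr6^2 - 2 * sr6) +
      model$coulomb_constant * q_i * q_j / r[ok]
  }
  u
}

#' Per-transit profiles: residence time, mobility, energetics, forces
#'
#' Restricted to confined permeation events (waters that crossed the whole
#' inter-plane region without leaving it), this computes, binned along z and
#' separated by direction:
#' \itemize{
#'   \item `residence_time_density` dtau/dz (ps/A): per event, each frame
#'     adds `dt_frame` to the bin holding the molecule, divided by bin width
#'     and the number of events, so the integral over the span equals the
#'     mean transit time tau;
#'   \item `mobility` (A): mean 3D displacement over the mobility timestep
#'     (default 2 ps);
#'   \item `u_protein`, `u_total` (kcal/mol): mean interaction energy of the
#'     transiting water with the protein, and with everything else (protein,
#'     membrane, other waters);
#'   \item `force_protein`, `force_total` (kcal/mol/A): mean |dU/ds| along
#'     the molecule's own 3D path, by centred finite differences.
#' }
#' Energetics require charges/LJ parameters in the topology; if absent the
#' geometric profiles are still produced with a warning.
#'
#' @param traj centred trajectory.
#' @param events an [detect_permeation_events()] table.
#' @param model an [energy_model()].
#' @param bin_width z bin width, Angstrom.
#' @param span z range `[-span/2, span/2]` profiled.
#' @param mobility_dt mobility timestep, ps.
#' @param energetics compute interaction energies/forces (slow for large
#'   systems).
#' @return `data.frame` of class `aqp_transit` with one row per
#'   (direction, bin): columns `direction`, `z`, `residence_time_density`,
#'   `mobility`, `u_protein`, `u_total`, `force_protein`, `force_total`;
#'   attribute `mean_tau` (ps, per direction).
#' @export
transit_profiles <- function(traj, events, model = energy_model(),
                             bin_width = 1, span = 30, mobility_dt = 2,
                             energetics = TRUE) {
  ev <- events[events$confined, , drop = FALSE]
  if (nrow(ev) == 0) stop("transit_profiles: no confined events")
  top <- traj$topology
  have_ff <- any(top$lj_epsilon != 0) || any(top$charge != 0)
  if (energetics && !have_ff) {
    warning("topology carries no charges/LJ parameters; energetics skipped")
    energetics <- FALSE
  }
  edges <- seq(-span / 2, span / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  nb <- length(centers)
  times <- frame_times(traj)
  mob_lag <- max(1L, round(mobility_dt / traj$dt_frame))
  pro <- which(top$segment == "protein")
  res <- list()
  mean_tau <- c(up = NA_real_, down = NA_real_)
  for (dirn in c("up", "down")) {
    evd <- ev[ev$direction == dirn, , drop = FALSE]
    if (nrow(evd) == 0) next
    mean_tau[dirn] <- mean(evd$tau)
    tsum <- numeric(nb)
    mob_sum <- numeric(nb); mob_n <- numeric(nb)
    up_sum <- numeric(nb); ut_sum <- numeric(nb); e_n <- numeric(nb)
    fp_sum <- numeric(nb); ft_sum <- numeric(nb); f_n <- numeric(nb)
    for (k in seq_len(nrow(evd))) {
      i <- evd$molecule_id[k]
      f0 <- which.min(abs(times - evd$t_star[k]))
      f1 <- which.min(abs(times - (evd$t_star[k] + evd$tau[k])))
      fr <- f0:f1
      zk <- traj$coords[i, 3, fr]
      # endpoint frames sit in the compartments just outside the span; clamp
      # them into the edge bins so the dtau/dz integral equals tau exactly
      bins <- pmin(pmax(findInterval(zk, edges, rightmost.closed = TRUE), 1L),
                   nb)
      # residence time: each frame-to-next interval credited to its bin
      tsum <- tsum + tabulate(bins[-length(bins)], nb) * traj$dt_frame
      # mobility over mob_lag frames
      if (length(fr) > mob_lag) {
        p0 <- t(matrix(traj$coords[i, , fr[1:(length(fr) - mob_lag)]], nrow = 3))
        p1 <- t(matrix(traj$coords[i, , fr[(mob_lag + 1):length(fr)]], nrow = 3))
        disp <- sqrt(rowSums((p1 - p0)^2))
        bb <- bins[1:(length(fr) - mob_lag)]
        for (j in seq_along(bb)) {
          mob_sum[bb[j]] <- mob_sum[bb[j]] + disp[j]
          mob_n[bb[j]] <- mob_n[bb[j]] + 1
        }
      }
      if (energetics) {
        uP <- numeric(length(fr)); uT <- numeric(length(fr))
        for (j in seq_along(fr)) {
          f <- fr[j]
          pos <- traj$coords[i, , f]
          box <- traj$box[f, ]
          others <- setdiff(seq_len(traj$n_atoms), i)
          opos <- matrix(traj$coords[others, , f], ncol = 3)
          uAll <- .pairwise_energies(pos, opos, top, i, others, box, model)
          uP[j] <- sum(uAll[top$segment[others] == "protein"])
          uT[j] <- sum(uAll)
        }
        for (j in seq_along(fr)) {
          up_sum[bins[j]] <- up_sum[bins[j]] + uP[j]
          ut_sum[bins[j]] <- ut_sum[bins[j]] + uT[j]
          e_n[bins[j]] <- e_n[bins[j]] + 1
        }
        # |dU/ds| along the molecule's own path, centred differences
        if (length(fr) >= 3) {
          pall <- t(matrix(traj$coords[i, , fr], nrow = 3))
          seg <- sqrt(rowSums(diff(pall)^2))
          for (j in 2:(length(fr) - 1)) {
            ds <- seg[j - 1] + seg[j]
            if (ds > 0) {
              fp_sum[bins[j]] <- fp_sum[bins[j]] + abs(uP[j + 1] - uP[j - 1]) / ds
              ft_sum[bins[j]] <- ft_sum[bins[j]] + abs(uT[j + 1] - uT[j - 1]) / ds
              f_n[bins[j]] <- f_n[bins[j]] + 1
            }
          }
        }
      }
    }
    res[[dirn]] <- data.frame(
      direction = dirn, z = centers,
      residence_time_density = tsum / (nrow(evd) * bin_width),
      mobility = ifelse(mob_n > 0, mob_sum / mob_n, NA_real_),
      u_protein = ifelse(e_n > 0, up_sum / e_n, NA_real_),
      u_total = ifelse(e_n > 0, ut_sum / e_n, NA_real_),
      force_protein = ifelse(f_n > 0, fp_sum / f_n, NA_real_),
      force_total = ifelse(f_n > 0, ft_sum / f_n, NA_real_))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, mean_tau = mean_tau, bin_width = bin_width,
            class = c("aqp_transit", "data.frame"))
}

# energies of atom i against a set of others at one frame (vectorised)
.pairwise_energies <- function(pos, opos, top, i, others, box, model) {
  d <- sweep(opos, 2, pos)
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  r <- sqrt(rowSums(d * d))
  eps <- sqrt(top$lj_epsilon[i] * top$lj_epsilon[others])
  rmin <- top$lj_rmin_half[i] + top$lj_rmin_half[others]
  u <- numeric(length(r))
  ok <- r < model$cutoff & r > 0
  if (any(ok)) {
    sr6 <- (rmin[ok] / r[ok])^6
    u[ok] <- eps[ok] * (sr6^2 - 2 * sr6) +
      model$coulomb_constant * top$charge[i] * top$charge[others][ok] / r[ok]
  }
  u
}
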