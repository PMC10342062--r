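# Permeation-event detection and permeabilities.
#
# Geometry: two detection planes at z = +/- Delta/2 (Delta = 25 A by
# default), each backed by an entry/exit compartment of thickness delta
# (5 A), so that Delta + delta equals the 30 A membrane span.  A complete
# permeation takes a water from one compartment through the inter-plane
# region to the opposite compartment; apparent crossings through the
# periodic images (bulk wrap-around) are excluded by the zone state machine
# (see src/detect.cpp for the exact rule shared with the test oracle).

#' Slab geometry for permeation detection
#'
#' @param delta_big detection-plane separation Delta, Angstrom.
#' @param delta_small compartment thickness delta, Angstrom.
#' @param z_origin z of the membrane mirror plane after centring (normally 0).
#' @return object of class `aqp_slab`; its `span` (`delta_big + delta_small`)
#'   is the full membrane span a permeating water crosses.
#' @export
slab_geometry <- function(delta_big = 25, delta_small = 5, z_origin = 0) {
  stopifnot(delta_big > 0, delta_small > 0)
  structure(list(delta_big = delta_big, delta_small = delta_small,
                 z_origin = z_origin, span = delta_big + delta_small),
            class = "aqp_slab")
}

# centring precondition: protein CoM z must sit at the slab origin
.check_centered <- function(traj, slab, tol = 0.1) {
  pro <- which(traj$topology$segment == "protein")
  if (length(pro) == 0) return(invisible(TRUE))
  m <- traj$topology$mass[pro]
  zs <- matrix(traj$coords[pro, 3, ], nrow = length(pro))
  com <- colSums(zs * m) / sum(m)
  if (max(abs(com - slab$z_origin)) > tol)
    stop("trajectory is not centred on the protein CoM ",
         "(max |CoM z - origin| = ", signif(max(abs(com - slab$z_origin)), 3),
         " A); run center_on_group() first")
  invisible(TRUE)
}

#' Detect complete water permeation events
#'
#' Scans the (wrapped) z series of each tracked water with the two-plane /
#' two-compartment state machine and returns one row per complete passage in
#' either direction.  `t_star` is the last time the molecule was seen in the
#' source compartment, `tau` the time to its first appearance in the
#' destination compartment, and `confined` records whether every intermediate
#' frame stayed strictly between the detection planes (when `TRUE`, `tau` is
#' exactly the time needed to permeate the distance Delta; otherwise it is an
#' upper bound).
#'
#' @param traj trajectory centred on the protein CoM.
#' @param waters selection of tracked water atoms (one per molecule).
#' @param slab an [slab_geometry()].
#' @return `data.frame` of class `aqp_events` with columns `molecule_id`,
#'   `t_star` (ps), `tau` (ps), `direction` (`"up"`/`"down"`), `confined`;
#'   attributes `duration_ns` and `n_molecules`.
#' @export
detect_permeation_events <- function(traj, waters, slab = slab_geometry()) {
  idx <- .as_indices(traj, waters)
  .check_centered(traj, slab)
  z <- .wrapped_z(traj, idx) - slab$z_origin
  ev <- cpp_detect_events(z, frame_times(traj),
                          slab$delta_big / 2, slab$delta_small)
  out <- data.frame(molecule_id = idx[ev$molecule],
                    t_star = ev$t_star, tau = ev$tau,
                    direction = ifelse(ev$direction > 0, "up", "down"),
                    confined = ev$confined,
                    stringsAsFactors = FALSE)
  attr(out, "duration_ns") <- (traj$n_frames - 1) * traj$dt_frame / 1000
  attr(out, "n_molecules") <- length(idx)
  class(out) <- c("aqp_events", "data.frame")
  out
}

#' Permeation rate per 100 ns
#'
#' @param events an [detect_permeation_events()] table (both directions are
#'   counted).
#' @param window observation window length, ns (defaults to the trajectory
#'   duration recorded on the event table).
#' @return events per 100 ns.
#' @export
permeation_rate <- function(events, window = attr(events, "duration_ns")) {
  if (is.null(window) || window <= 0) stop("permeation_rate: window must be > 0")
  nrow(events) * 100 / window
}

#' Diffusion permeability from the event count
#'
#' `pd = (Nw / 2T) * vw`: the unidirectional event rate (half the
#' bidirectional count per unit time) times the volume of a single water
#' molecule.
#'
#' @param n_events bidirectional event count Nw.
#' @param duration trajectory duration T, ns.
#' @param vw single-water volume, cm^3 (default 3.018e-23, i.e. 30.18 A^3).
#' @return pd in cm^3/s.
#' @export
diffusion_permeability <- function(n_events, duration, vw = 3.018e-23) {
  if (duration <= 0) stop("diffusion_permeability: duration must be > 0")
  (n_events / (2 * duration * 1e-9)) * vw
}

#' Collective permeation coordinate n(t)
#'
#' Cumulative net water displacement through the inter-plane region in units
#' of its length L = Delta: per frame pair, each water contributes
#' `(clamp(z + dz) - clamp(z)) / L`, where `clamp` restricts to
#' `[-Delta/2, Delta/2]` and `dz` is the minimum-image z step.  A water
#' transiting the full region contributes exactly +/-1; same-side excursions
#' and periodic wrap-arounds through the bulk contribute 0.
#'
#' @param traj centred trajectory.
#' @param waters tracked water selection.
#' @param slab an [slab_geometry()].
#' @return object of class `aqp_collective`: list with `times` (ps), `n`
#'   (dimensionless cumulative coordinate) and `channel_length` (A).
#' @export
collective_coordinate <- function(traj, waters, slab = slab_geometry()) {
  idx <- .as_indices(traj, waters)
  .check_centered(traj, slab)
  z <- .wrapped_z(traj, idx) - slab$z_origin
  nf <- traj$n_frames
  L <- slab$delta_big
  half <- L / 2
  bz <- matrix(traj$box[-1, 3], nrow = length(idx), ncol = nf - 1, byrow = TRUE)
  z0 <- z[, -nf, drop = FALSE]
  dz <- z[, -1, drop = FALSE] - z0
  dz <- dz - bz * round(dz / bz)
  contrib <- pmin(pmax(z0 + dz, -half), half) - pmin(pmax(z0, -half), half)
  dn <- colSums(contrib) / L
  structure(list(times = frame_times(traj), n = c(0, cumsum(dn)),
                 channel_length = L, dt_frame = traj$dt_frame),
            class = "aqp_collective")
}

# time-origin-averaged mean square displacement of a scalar series
.msd_1d <- function(x, max_lag) {
  vapply(seq_len(max_lag), function(s) {
    d <- x[(1 + s):length(x)] - x[1:(length(x) - s)]
    mean(d * d)
  }, numeric(1))
}

#' Osmotic permeability from the collective coordinate
#'
#' `pf = vw * Dn`, with `Dn` half the slope of the time-origin-averaged MSD
#' of n(t), fitted by least squares over lag times in
#' `[fit_window/5, fit_window]`.
#'
#' @param series an [collective_coordinate()] result.
#' @param vw single-water volume, cm^3.
#' @param fit_window largest lag time used in the MSD fit, ps.  The series
#'   must cover at least 10 fit windows.
#' @return pf in cm^3/s, with attributes `Dn_per_ps` and `fit`.
#' @export
osmotic_permeability <- function(series, vw = 3.018e-23, fit_window = 100) {
  dt <- series$dt_frame
  total <- (length(series$n) - 1) * dt
  if (total < 10 * fit_window)
    stop("osmotic_permeability: series (", total, " ps) shorter than 10 x ",
         "fit_window; reduce fit_window or extend the run")
  max_lag <- max(2L, floor(fit_window / dt))
  msd <- .msd_1d(series$n, max_lag)
  lag_t <- seq_len(max_lag) * dt
  use <- lag_t >= fit_window / 5 & lag_t <= fit_window
  if (sum(use) < 2) use <- rep(TRUE, max_lag)
  fit <- lm(msd[use] ~ lag_t[use])
  Dn <- coef(fit)[[2]] / 2                      # 1/ps
  pf <- vw * Dn * 1e12                          # 1/ps -> 1/s
  structure(max(pf, 0), Dn_per_ps = Dn,
            fit = c(slope = coef(fit)[[2]], intercept = coef(fit)[[1]]))
}

#' Permeability summary for one trajectory
#'
#' Bundles the event count, the rate per 100 ns, the diffusion and osmotic
#' permeabilities and their ratio.  A ratio below 2 is flagged as a
#' non-single-file transport regime; in a single-file channel holding N
#' waters the ratio approaches N + 1.
#'
#' @param traj centred trajectory.
#' @param waters tracked water selection.
#' @param slab an [slab_geometry()].
#' @param vw single-water volume, cm^3.
#' @param fit_window MSD fit window for pf, ps.
#' @return object of class `aqp_permeability`: list with `n_events`,
#'   `duration` (ns), `nw` (per 100 ns), `pd`, `pf` (cm^3/s), `ratio`,
#'   `vw`, `collective_diffusion` (1/ps), `single_file_regime`.
#' @export
permeability_summary <- function(traj, waters, slab = slab_geometry(),
                                 vw = 3.018e-23, fit_window = 100) {
  ev <- detect_permeation_events(traj, waters, slab)
  dur <- attr(ev, "duration_ns")
  nw <- permeation_rate(ev, dur)
  pd <- diffusion_permeability(nrow(ev), dur, vw)
  series <- collective_coordinate(traj, waters, slab)
  pf <- tryCatch(osmotic_permeability(series, vw, fit_window),
                 error = function(e) NA_real_)
  ratio <- if (!is.na(pf) && pd > 0) as.numeric(pf) / pd else NA_real_
  structure(list(n_events = nrow(ev), duration = dur, nw = nw,
                 pd = pd, pf = as.numeric(pf), ratio = ratio, vw = vw,
                 collective_diffusion =
                   if (!is.na(pf)) attr(pf, "Dn_per_ps") else NA_real_,
                 single_file_regime = if (is.na(ratio)) NA else ratio >= 2,
                 events = ev),
            class = "aqp_permeability")
}

#' @export
print.aqp_permeability <- function(x, ...) {
  cat("<aqp_permeability>\n")
  cat(sprintf("  events Nw        : %d over %.3g ns (nw = %.3g / 100 ns)\n",
              x$n_events, x$duration, x$nw))
  cat(sprintf("  pd               : %.4g cm^3/s\n", x$pd))
  cat(sprintf("  pf               : %.4g cm^3/s\n", x$pf))
  if (!is.na(x$ratio))
    cat(sprintf("  pf/pd            : %.4g (%s)\n", x$ratio,
                if (x$ratio < 2) "non-single-file regime"
                else "consistent with single file, N ~ pf/pd - 1"))
  invisible(x)
}
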