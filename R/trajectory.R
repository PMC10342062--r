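#' Construct an atom topology table
#'
#' The topology carries per-atom metadata consumed downstream: masses for
#' centre-of-mass operations and bead reductions, charges and Lennard-Jones
#' parameters for interaction-energy profiles, segment labels
#' (protein/water/membrane) for selections, and domain labels
#' (bundle/hash/gate) for the coarse-grained domain analysis.
#'
#' @param name atom names (character).
#' @param residue_id integer residue identifiers.
#' @param residue_name residue names.
#' @param segment segment label per atom, e.g. "protein", "water", "membrane".
#' @param mass atomic masses in amu (must be positive).
#' @param charge partial charges in elementary-charge units.
#' @param lj_epsilon Lennard-Jones well depths, kcal/mol.
#' @param lj_rmin_half Lennard-Jones Rmin/2, Angstrom.
#' @param domain_label one of "bundle", "hash", "gate", "none" per atom;
#'   non-"none" labels are only meaningful on protein atoms.
#' @return a `data.frame` of class `aqp_topology`.
#' @export
topology <- function(name, residue_id = seq_along(name),
                     residue_name = "RES", segment = "protein",
                     mass = 12, charge = 0,
                     lj_epsilon = 0, lj_rmin_half = 0,
                     domain_label = "none") {
  n <- length(name)
  top <- data.frame(
    atom_index = seq_len(n),
    name = as.character(name),
    residue_id = as.integer(rep_len(residue_id, n)),
    residue_name = as.character(rep_len(residue_name, n)),
    segment = as.character(rep_len(segment, n)),
    mass = as.numeric(rep_len(mass, n)),
    charge = as.numeric(rep_len(charge, n)),
    lj_epsilon = as.numeric(rep_len(lj_epsilon, n)),
    lj_rmin_half = as.numeric(rep_len(lj_rmin_half, n)),
    domain_label = as.character(rep_len(domain_label, n)),
    stringsAsFactors = FALSE
  )
  validate_topology(top)
  class(top) <- c("aqp_topology", "data.frame")
  top
}

validate_topology <- function(top) {
  stopifnot(is.data.frame(top))
  if (any(!is.finite(top$mass)) || any(top$mass <= 0))
    stop("topology: all masses must be positive and finite")
  if (any(is.na(top$segment)) || any(!nzchar(top$segment)))
    stop("topology: every atom needs a segment label")
  bad <- top$domain_label != "none" & top$segment != "protein"
  if (any(bad))
    stop("topology: domain labels are only allowed on protein atoms")
  invisible(top)
}

#' Construct an in-memory trajectory
#'
#' Coordinates are stored as an `n_atoms x 3 x n_frames` array in Angstrom;
#' boxes are per-frame orthorhombic edge lengths.  The membrane normal is the
#' z axis throughout the package.
#'
#' @param coords numeric array `n_atoms x 3 x n_frames` (Angstrom).
#' @param topology an [topology()] table with one row per atom.
#' @param box per-frame orthorhombic box lengths: either a length-3 vector
#'   (constant box) or an `n_frames x 3` matrix, Angstrom.
#' @param dt_frame time between stored frames, ps.
#' @return object of class `aqp_trajectory` with elements `coords`, `box`,
#'   `topology`, `dt_frame`, `n_frames`, `n_atoms`.
#' @export
trajectory <- function(coords, topology, box, dt_frame = 2) {
  if (length(dim(coords)) == 2) # single frame
    coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (nrow(topology) != n_atoms)
    stop("trajectory: topology rows (", nrow(topology),
         ") do not match atom count (", n_atoms, ")")
  if (is.null(dim(box))) box <- matrix(box, nrow = n_frames, ncol = 3, byrow = TRUE)
  box <- as.matrix(box)
  if (nrow(box) == 1 && n_frames > 1)
    box <- box[rep(1, n_frames), , drop = FALSE]
  stopifnot(nrow(box) == n_frames, ncol(box) == 3)
  if (any(box <= 0)) stop("trajectory: box lengths must be positive")
  if (!is.numeric(dt_frame) || dt_frame <= 0)
    stop("trajectory: dt_frame must be > 0")
  validate_topology(topology)
  structure(list(coords = coords, box = box, topology = topology,
                 dt_frame = dt_frame, n_frames = n_frames, n_atoms = n_atoms),
            class = "aqp_trajectory")
}

#' @export
print.aqp_trajectory <- function(x, ...) {
  cat("<aqp_trajectory> ", x$n_atoms, " atoms, ", x$n_frames, " frames (dt ",
      x$dt_frame, " ps, ", round(x$n_frames * x$dt_frame / 1000, 3), " ns)\n",
      sep = "")
  segs <- table(x$topology$segment)
  cat("  segments:", paste(names(segs), segs, sep = ":", collapse = "  "), "\n")
  cat("  box (first frame):", paste(signif(x$box[1, ], 4), collapse = " x "),
      "Angstrom\n")
  invisible(x)
}

#' Frame times of a trajectory
#'
#' @param traj an `aqp_trajectory`.
#' @return numeric vector of frame times in ps, starting at 0.
#' @export
frame_times <- function(traj) (seq_len(traj$n_frames) - 1) * traj$dt_frame

#' Select atoms by topology attributes
#'
#' Either pass filtering arguments directly or a mini selection string such
#' as `"segment water"`, `"name OH2"`, `"domain bundle"`,
#' `"segment protein and resid 10:40"`; clauses are joined with `and`.
#'
#' @param traj an `aqp_trajectory`.
#' @param string optional selection string (overrides the other filters).
#' @param segment,name,residue_id,domain optional filters; each keeps atoms
#'   whose attribute is in the given set.
#' @param label label stored on the selection.
#' @return object of class `aqp_selection`: list with `indices` and `label`.
#' @export
select_atoms <- function(traj, string = NULL, segment = NULL, name = NULL,
                         residue_id = NULL, domain = NULL, label = NULL) {
  top <- traj$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(string)) {
    clauses <- strsplit(trimws(string), "\\s+and\\s+")[[1]]
    for (cl in clauses) {
      tok <- strsplit(trimws(cl), "\\s+")[[1]]
      if (length(tok) < 2) stop("selection clause needs a key and values: ", cl)
      key <- tok[1]; vals <- tok[-1]
      keep <- keep & switch(key,
        segment = top$segment %in% vals,
        name    = top$name %in% vals,
        domain  = top$domain_label %in% vals,
        resid   = top$residue_id %in% .parse_ranges(vals),
        stop("unknown selection key: ", key))
    }
    if (is.null(label)) label <- string
  } else {
    if (!is.null(segment)) keep <- keep & top$segment %in% segment
    if (!is.null(name)) keep <- keep & top$name %in% name
    if (!is.null(residue_id)) keep <- keep & top$residue_id %in% residue_id
    if (!is.null(domain)) keep <- keep & top$domain_label %in% domain
    if (is.null(label))
      label <- paste(c(segment, name, domain), collapse = " ")
  }
  sel <- which(keep)
  structure(list(indices = sel, label = if (nzchar(label)) label else "all"),
            class = "aqp_selection")
}

.parse_ranges <- function(vals) {
  unlist(lapply(vals, function(v) {
    if (grepl(":", v)) {
      ab <- as.integer(strsplit(v, ":")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(v)
  }))
}

.as_indices <- function(traj, sel) {
  idx <- if (inherits(sel, "aqp_selection")) sel$indices else as.integer(sel)
  if (length(idx) == 0) stop("empty atom selection")
  if (any(idx < 1 | idx > traj$n_atoms)) stop("selection indices out of range")
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  idx
}

#' Centre a trajectory on the z centre of mass of a group
#'
#' Shifts every frame along z so that the mass-weighted centre of mass of the
#' given group (typically the protein) sits at z = 0, the convention used by
#' all z-profiles and the permeation slab geometry.  Lateral coordinates are
#' untouched; relative geometry is preserved.  Idempotent.
#'
#' @param traj an `aqp_trajectory`.
#' @param group an `aqp_selection` or integer atom indices (nonempty).
#' @return the centred trajectory.
#' @export
center_on_group <- function(traj, group) {
  idx <- .as_indices(traj, group)
  m <- traj$topology$mass[idx]
  zs <- matrix(traj$coords[idx, 3, ], nrow = length(idx))
  com_z <- colSums(zs * m) / sum(m)
  zall <- matrix(traj$coords[, 3, ], nrow = traj$n_atoms)
  traj$coords[, 3, ] <- sweep(zall, 2, com_z, "-")
  traj
}

#' Unwrap z coordinates of tracked molecules across the periodic boundary
#'
#' Replaces each tracked atom's z series by the continuous series obtained by
#' accumulating minimum-image steps, so that no frame-to-frame jump of
#' magnitude >= box_z/2 remains.  Unwrapped and wrapped series are congruent
#' modulo box_z.
#'
#' @param traj an `aqp_trajectory`.
#' @param molecules selection of atoms to unwrap (one atom per tracked
#'   molecule, e.g. the water oxygens).
#' @param max_jump_frac frames whose minimum-image step exceeds this fraction
#'   of box_z/2 raise an undersampling error (frame stride too coarse).
#' @return trajectory with unwrapped z for the selected atoms.
#' @export
unwrap_z <- function(traj, molecules, max_jump_frac = 0.99) {
  idx <- .as_indices(traj, molecules)
  if (traj$n_frames < 2) return(traj)
  z <- traj$coords[idx, 3, , drop = FALSE][, 1, , drop = TRUE]
  if (length(idx) == 1) z <- matrix(z, nrow = 1)
  boxz <- traj$box[, 3]
  bz <- matrix(boxz[-1], nrow = length(idx), ncol = traj$n_frames - 1,
               byrow = TRUE)
  dz <- z[, -1, drop = FALSE] - z[, -ncol(z), drop = FALSE]
  dz_mi <- dz - bz * round(dz / bz)
  if (any(abs(dz_mi) >= max_jump_frac * bz / 2))
    stop("unwrap_z: inter-frame displacement approaches box_z/2; ",
         "frame stride too coarse to unwrap (undersampling)")
  zu <- cbind(z[, 1], matrix(0, length(idx), traj$n_frames - 1))
  zu[, -1] <- z[, 1] + t(apply(dz_mi, 1, cumsum))
  traj$coords[idx, 3, ] <- zu
  traj
}

# wrapped z (primary cell, centred on 0) for a set of atoms: n_sel x n_frames
.wrapped_z <- function(traj, idx) {
  z <- traj$coords[idx, 3, , drop = FALSE][, 1, , drop = TRUE]
  if (length(idx) == 1) z <- matrix(z, nrow = 1)
  bz <- matrix(traj$box[, 3], nrow = length(idx), ncol = traj$n_frames,
               byrow = TRUE)
  z - bz * round(z / bz)
}

#' Concatenate two trajectories in time
#'
#' Both trajectories must share the same topology and frame spacing.  Used to
#' assemble multi-window fixtures from independently generated segments.
#'
#' @param a,b `aqp_trajectory` objects with identical atom tables.
#' @return the time-concatenated trajectory.
#' @export
bind_frames <- function(a, b) {
  stopifnot(a$n_atoms == b$n_atoms, isTRUE(all.equal(a$dt_frame, b$dt_frame)))
  if (!identical(a$topology$name, b$topology$name))
    stop("bind_frames: topologies differ")
  trajectory(array(c(a$coords, b$coords),
                   dim = c(a$n_atoms, 3, a$n_frames + b$n_frames)),
             a$topology, rbind(a$box, b$box), a$dt_frame)
}

#' Merge the atoms of two trajectories frame by frame
#'
#' Both trajectories must have the same frame count, frame spacing and boxes;
#' topologies are stacked.  Used to superpose, e.g., a protein bead system on
#' a channel-water system for windowed analyses.
#'
#' @param a,b `aqp_trajectory` objects with equal `n_frames`.
#' @return trajectory containing the atoms of `a` followed by those of `b`.
#' @export
merge_atoms <- function(a, b) {
  stopifnot(a$n_frames == b$n_frames, isTRUE(all.equal(a$dt_frame, b$dt_frame)))
  top <- rbind(as.data.frame(a$topology), as.data.frame(b$topology))
  top$atom_index <- seq_len(nrow(top))
  class(top) <- c("aqp_topology", "data.frame")
  co <- array(0, dim = c(a$n_atoms + b$n_atoms, 3, a$n_frames))
  co[seq_len(a$n_atoms), , ] <- a$coords
  co[a$n_atoms + seq_len(b$n_atoms), , ] <- b$coords
  trajectory(co, top, a$box, a$dt_frame)
}
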