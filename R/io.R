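# Readers and writers.
#
# Topology: PSF (CHARMM/X-PLOR, NATOM block), PDB (via bio3d, masses guessed
# from the element), or the package's plain-CSV table carrying the full
# per-atom record including LJ parameters (which PSF/PDB cannot hold).
# Coordinates: DCD (read via bio3d, written natively with writeBin), multi-
# model PDB, or long-format CSV.  Internal units Angstrom / ps throughout.

#' Read a CHARMM/X-PLOR PSF topology
#'
#' Parses the `!NATOM` section (index, segment, residue id, residue name,
#' atom name, type, charge, mass).  LJ parameters are not stored in PSF and
#' are set to zero; supply them via a CSV topology if energetics are needed.
#'
#' @param path PSF file path.
#' @return an `aqp_topology`.
#' @export
read_psf <- function(path) {
  ln <- readLines(path)
  hdr <- grep("!NATOM", ln)
  if (length(hdr) != 1) stop("read_psf: no !NATOM section in ", path)
  n <- as.integer(strsplit(trimws(ln[hdr]), "\\s+")[[1]][1])
  rows <- ln[(hdr + 1):(hdr + n)]
  f <- strsplit(trimws(rows), "\\s+")
  seg <- vapply(f, `[`, "", 2)
  top <- topology(
    name = vapply(f, `[`, "", 5),
    residue_id = as.integer(vapply(f, `[`, "", 3)),
    residue_name = vapply(f, `[`, "", 4),
    segment = .canonical_segment(seg),
    mass = as.numeric(vapply(f, `[`, "", 8)),
    charge = as.numeric(vapply(f, `[`, "", 7))
  )
  top
}

# map force-field style segment ids onto the package's coarse labels
.canonical_segment <- function(seg) {
  s <- tolower(seg)
  out <- seg
  out[grepl("^(wat|tip|sol|spc)", s)] <- "water"
  out[grepl("^(memb|popc|chl|lip)", s)] <- "membrane"
  out[grepl("^(pro|seg|a$|b$)", s)] <- "protein"
  out
}

#' Write / read the package's CSV topology format
#'
#' A plain-text table with one row per atom and all `aqp_topology` columns,
#' including charges and LJ parameters.
#'
#' @param top an `aqp_topology`.
#' @param path file path.
#' @return `read_topology_csv` returns an `aqp_topology`.
#' @export
write_topology_csv <- function(top, path) {
  write.csv(as.data.frame(top), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology_csv
#' @export
read_topology_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  topology(name = d$name, residue_id = d$residue_id,
           residue_name = d$residue_name, segment = d$segment,
           mass = d$mass, charge = d$charge,
           lj_epsilon = d$lj_epsilon, lj_rmin_half = d$lj_rmin_half,
           domain_label = d$domain_label)
}

#' Load a trajectory from topology + coordinate files
#'
#' Topology formats: `.psf`, `.pdb`, `.csv`.  Coordinate formats: `.dcd`
#' (CHARMM binary, box read from the crystal records), `.pdb` (multi-model),
#' `.csv` (long format as written by [write_coords_csv()]).  Atom counts of
#' the two files must agree.
#'
#' @param topology_path topology file.
#' @param coords_path coordinate file.
#' @param dt_frame time between frames in ps (DCD/PDB do not carry a reliable
#'   stride; default 2 ps, a typical analysis stride).
#' @param box fallback orthorhombic box lengths (length 3) for formats/files
#'   without box information.
#' @return an `aqp_trajectory`.
#' @export
load_trajectory <- function(topology_path, coords_path, dt_frame = 2,
                            box = NULL) {
  top <- switch(tolower(tools::file_ext(topology_path)),
    psf = read_psf(topology_path),
    pdb = .topology_from_pdb(topology_path),
    csv = read_topology_csv(topology_path),
    stop("load_trajectory: unsupported topology format: ", topology_path))
  ext <- tolower(tools::file_ext(coords_path))
  cb <- switch(ext,
    dcd = .read_dcd_coords(coords_path),
    pdb = .read_pdb_coords(coords_path),
    csv = read_coords_csv(coords_path),
    stop("load_trajectory: unsupported coordinate format: ", coords_path))
  if (dim(cb$coords)[1] != nrow(top))
    stop("load_trajectory: atom count mismatch between topology (",
         nrow(top), ") and coordinates (", dim(cb$coords)[1], ")")
  bx <- if (!is.null(cb$box)) cb$box else box
  if (is.null(bx))
    stop("load_trajectory: no box in ", coords_path,
         "; supply one via the box argument")
  trajectory(cb$coords, top, bx, dt_frame)
}

.topology_from_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  mass <- tryCatch(bio3d::atom2mass(at$elety),
                   error = function(e) rep(12, nrow(at)))
  seg <- ifelse(is.na(at$segid) | !nzchar(at$segid), "protein", at$segid)
  topology(name = at$elety, residue_id = at$resno, residue_name = at$resid,
           segment = .canonical_segment(seg), mass = mass, charge = 0)
}

.read_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz                       # n_frames x 3N
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  co <- array(0, c(na, 3, nf))
  for (f in seq_len(nf))
    co[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(coords = co, box = NULL)
}

.read_dcd_coords <- function(path) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  co <- array(0, c(na, 3, nf))
  for (f in seq_len(nf))
    co[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  # cell columns are a, b, c, alpha, beta, gamma (positional)
  box <- if (!is.null(cell)) as.matrix(cell)[, 1:3, drop = FALSE] else NULL
  list(coords = co, box = box)
}

#' Write a trajectory to a CHARMM-format DCD file
#'
#' Writes a standard CHARMM binary DCD (crystal records carrying the
#' orthorhombic box, frame time stored in the header) that external tools and
#' `bio3d::read.dcd` can read back.
#'
#' @param traj an `aqp_trajectory`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  endrec <- function(nbytes) writeBin(as.integer(nbytes), con, size = 4)
  nf <- traj$n_frames
  # header record: 'CORD' + 20 int32 control words (delta stored as float32)
  endrec(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf          # frames
  icntrl[2] <- 1           # first step
  icntrl[3] <- 1           # save frequency
  icntrl[4] <- nf          # total steps
  icntrl[11] <- 1          # crystal records present
  icntrl[20] <- 24         # CHARMM version flag
  writeBin(as.integer(icntrl[1:9]), con, size = 4)
  writeBin(as.numeric(traj$dt_frame / 0.0488882129), con, size = 4) # AKMA time
  writeBin(as.integer(icntrl[11:20]), con, size = 4)
  endrec(84)
  title <- sprintf("%-80s", "written by aquaperm")
  endrec(4 + 80)
  writeBin(1L, con, size = 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  endrec(4 + 80)
  endrec(4); writeBin(as.integer(traj$n_atoms), con, size = 4); endrec(4)
  na <- traj$n_atoms
  for (f in seq_len(nf)) {
    b <- traj$box[f, ]
    # CHARMM xtlabc order: a, cos(gamma), b, cos(beta), cos(alpha), c
    endrec(48)
    writeBin(as.numeric(c(b[1], 0, b[2], 0, 0, b[3])), con, size = 8)
    endrec(48)
    for (d in 1:3) {
      endrec(4 * na)
      writeBin(as.numeric(traj$coords[, d, f]), con, size = 4)
      endrec(4 * na)
    }
  }
  invisible(path)
}

#' Write / read coordinates as long-format CSV
#'
#' Plain-text fallback format: columns `frame, atom, x, y, z, box_x, box_y,
#' box_z`.
#'
#' @param traj an `aqp_trajectory`.
#' @param path file path.
#' @return `read_coords_csv` returns `list(coords, box)`.
#' @export
write_coords_csv <- function(traj, path) {
  nf <- traj$n_frames; na <- traj$n_atoms
  d <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom = rep(seq_len(na), nf),
    x = as.vector(traj$coords[, 1, ]),
    y = as.vector(traj$coords[, 2, ]),
    z = as.vector(traj$coords[, 3, ]),
    box_x = rep(traj$box[, 1], each = na),
    box_y = rep(traj$box[, 2], each = na),
    box_z = rep(traj$box[, 3], each = na))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coords_csv
#' @export
read_coords_csv <- function(path) {
  d <- read.csv(path)
  nf <- max(d$frame); na <- max(d$atom)
  stopifnot(nrow(d) == nf * na)
  d <- d[order(d$frame, d$atom), ]
  co <- array(0, c(na, 3, nf))
  co[, 1, ] <- d$x; co[, 2, ] <- d$y; co[, 3, ] <- d$z
  box <- unique(d[, c("frame", "box_x", "box_y", "box_z")])
  list(coords = co, box = as.matrix(box[order(box$frame), -1]))
}

#' Write a trajectory (topology + coordinates) in one call
#'
#' Dispatches on the file extensions: topology to `.csv` or `.psf`-less
#' formats, coordinates to `.dcd` or `.csv`.
#'
#' @param traj an `aqp_trajectory`.
#' @param topology_path output topology path (`.csv`).
#' @param coords_path output coordinates path (`.dcd` or `.csv`).
#' @return invisibly, the coordinate path.
#' @export
write_trajectory <- function(traj, topology_path, coords_path) {
  write_topology_csv(traj$topology, topology_path)
  switch(tolower(tools::file_ext(coords_path)),
    dcd = write_dcd(traj, coords_path),
    csv = write_coords_csv(traj, coords_path),
    stop("write_trajectory: unsupported coordinate format: ", coords_path))
  invisible(coords_path)
}
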