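# Principal component analysis of coarse-grained domain motion, vibrational
# weights, softness and quasi-harmonic frequencies.
#
# The analysis deliberately removes rigid-body translation exactly (per-frame
# mass-weighted CoM subtraction) but NOT rotation: residual rigid rotation is
# handled statistically by the per-mode vibrational weight wv, which measures
# the fraction of a mode's kinetic energy not attributable to a rigid
# rotation of the reference structure.

#' Bead trajectory for PCA
#'
#' Wraps per-frame bead positions with masses, removes the mass-weighted
#' centre-of-mass translation from every frame, and stores the mean
#' (reference) structure.
#'
#' @param positions numeric array `n_beads x 3 x n_frames`, Angstrom.
#' @param masses bead masses, amu.
#' @param labels optional bead labels.
#' @return object of class `aqp_beads`: list with `positions` (CoM-free),
#'   `masses`, `reference` (mean structure), `labels`, `n_beads`, `n_frames`.
#' @export
bead_trajectory <- function(positions, masses, labels = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[2] == 3,
            length(masses) == dim(positions)[1], all(masses > 0))
  n <- dim(positions)[1]; nf <- dim(positions)[3]
  M <- sum(masses)
  for (d in 1:3) {
    pd <- matrix(positions[, d, ], nrow = n)
    com <- colSums(pd * masses) / M
    positions[, d, ] <- sweep(pd, 2, com)
  }
  ref <- matrix(0, n, 3)
  for (d in 1:3) ref[, d] <- rowMeans(matrix(positions[, d, ], nrow = n))
  structure(list(positions = positions, masses = as.numeric(masses),
                 reference = ref, labels = labels,
                 n_beads = n, n_frames = nf),
            class = "aqp_beads")
}

#' Reduce a trajectory to the four-bead domain model
#'
#' Builds the coarse domain representation: two beads for the bundle domain
#' and two for the hash domain, each bead the centre of mass of the lower or
#' upper (extracellular) half of its domain.  Halves are split at the
#' domain's own CoM z in the reference (time-mean) structure, so the atom
#' assignment is fixed across frames; bead masses are the summed atom
#' masses.
#'
#' @param traj trajectory whose topology carries `domain_label`s `"bundle"`
#'   and `"hash"`.
#' @return an [bead_trajectory()] with beads labelled `bundle_lower`,
#'   `bundle_upper`, `hash_lower`, `hash_upper`.
#' @export
four_bead_reduction <- function(traj) {
  top <- traj$topology
  groups <- list()
  for (dom in c("bundle", "hash")) {
    idx <- which(top$domain_label == dom)
    if (length(idx) < 2)
      stop("four_bead_reduction: domain '", dom,
           "' needs at least two labelled atoms")
    m <- top$mass[idx]
    zmean <- rowMeans(matrix(traj$coords[idx, 3, ], nrow = length(idx)))
    split_z <- sum(zmean * m) / sum(m)
    lower <- idx[zmean < split_z]
    upper <- idx[zmean >= split_z]
    if (length(lower) == 0 || length(upper) == 0)
      stop("four_bead_reduction: degenerate half split for domain '", dom, "'")
    groups[[paste0(dom, "_lower")]] <- lower
    groups[[paste0(dom, "_upper")]] <- upper
  }
  nf <- traj$n_frames
  pos <- array(0, c(4, 3, nf))
  masses <- numeric(4)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    m <- top$mass[idx]
    masses[g] <- sum(m)
    for (d in 1:3)
      pos[g, d, ] <- colSums(matrix(traj$coords[idx, d, ],
                                    nrow = length(idx)) * m) / sum(m)
  }
  bead_trajectory(pos, masses, labels = names(groups))
}

#' PCA of bead fluctuations
#'
#' Covariance of the centred (optionally mass-weighted) bead coordinates,
#' eigendecomposed with eigenvalues in descending order.  Mode stiffness is
#' `kappa_i = kBT / lambda_i` (equipartition); the mass-weighted branch
#' additionally yields quasi-harmonic frequencies
#' `omega_i = sqrt(kBT / lambda_i)` in ps^-1.  Eigenvector signs are fixed
#' so each mode's largest-magnitude component is positive.
#'
#' @param beads an [bead_trajectory()].
#' @param temperature K.
#' @param mass_weighted analyse `sqrt(m) * r` instead of `r`.
#' @return object of class `aqp_pca`: list with `covariance`, `eigenvalues`
#'   (A^2, or amu A^2 when mass-weighted), `eigenvectors` (columns),
#'   `stiffness` (kcal/mol/A^2), `quasi_frequencies` (ps^-1, mass-weighted
#'   only), `kBT`, `masses`, `reference`, `mass_weighted`, `n_zero_modes`.
#' @export
bead_pca <- function(beads, temperature = 303.15, mass_weighted = FALSE) {
  stopifnot(inherits(beads, "aqp_beads"))
  n <- beads$n_beads; nf <- beads$n_frames
  dof <- 3 * n
  if (nf < 10 * dof)
    warning("bead_pca: fewer than 10 frames per degree of freedom (",
            nf, " frames, ", dof, " DoF); eigenvalues will be noisy")
  X <- matrix(0, nf, dof)                 # frames x (bead-major x,y,z)
  for (k in seq_len(n)) for (d in 1:3)
    X[, (k - 1) * 3 + d] <- beads$positions[k, d, ]
  if (mass_weighted)
    X <- sweep(X, 2, rep(sqrt(beads$masses), each = 3), "*")
  X <- sweep(X, 2, colMeans(X))
  C <- crossprod(X) / (nf - 1)
  eg <- eigen(C, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  vec <- eg$vectors
  for (j in seq_len(ncol(vec))) {
    jmax <- which.max(abs(vec[, j]))
    if (vec[jmax, j] < 0) vec[, j] <- -vec[, j]
  }
  kBT <- .kB * temperature
  n_zero <- sum(lam < max(lam) * 1e-12)
  if (nf - 1 < dof)
    warning("bead_pca: rank-deficient covariance (", nf, " frames < ",
            dof, " DoF); ", n_zero, " trailing zero modes flagged")
  structure(list(covariance = C, eigenvalues = lam, eigenvectors = vec,
                 stiffness = ifelse(lam > 0, kBT / lam, Inf),
                 quasi_frequencies = if (mass_weighted)
                   ifelse(lam > 0, sqrt(kBT * .kcal_amu / lam), Inf)
                 else NULL,
                 vib_weights = NULL, kBT = kBT,
                 temperature = temperature,
                 masses = beads$masses, reference = beads$reference,
                 mass_weighted = mass_weighted, n_zero_modes = n_zero),
            class = "aqp_pca")
}

#' Vibrational weight of each PCA mode
#'
#' For mode i with bead displacement field e_ik (eigenvector components per
#' bead, converted back to real displacements in the mass-weighted branch):
#' total kinetic weight `W_tot = 1/2 sum_k m_k |e_ik|^2`, rigid-rotation
#' weight `W_R = |Gamma|^2 / (2 J)` with
#' `Gamma = sum_k m_k (r_k x e_ik)` the angular momentum of the displacement
#' field about the CoM and `J` the moment of inertia about the Gamma axis;
#' `wv_i = (W_tot - W_R) / W_tot`, clamped to [0, 1].  wv = 1 marks a pure
#' vibration, wv = 0 a pure rigid rotation.
#'
#' @param result an [bead_pca()] result.
#' @return the result with `vib_weights` filled in.
#' @export
vibrational_weights <- function(result) {
  stopifnot(inherits(result, "aqp_pca"))
  m <- result$masses
  r <- result$reference
  nmodes <- ncol(result$eigenvectors)
  n <- length(m)
  wv <- numeric(nmodes)
  for (i in seq_len(nmodes)) {
    e <- matrix(result$eigenvectors[, i], ncol = 3, byrow = TRUE)
    if (result$mass_weighted) e <- e / sqrt(m)
    w_tot <- 0.5 * sum(m * rowSums(e * e))
    if (w_tot <= 0) { wv[i] <- 0; next }
    gam <- colSums(m * .cross_rows(r, e))
    gnorm2 <- sum(gam * gam)
    scale <- sum(m * rowSums(r * r)) * sum(m * rowSums(e * e))
    if (gnorm2 <= 1e-20 * max(scale, 1e-300)) {
      wv[i] <- 1
    } else {
      ax <- gam / sqrt(gnorm2)
      J <- sum(m * (rowSums(r * r) - (r %*% ax)^2))
      w_r <- if (J > 0) gnorm2 / (2 * J) else w_tot
      wv[i] <- min(max((w_tot - w_r) / w_tot, 0), 1)
    }
  }
  result$vib_weights <- wv
  result
}

# rowwise cross products of two n x 3 matrices
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Overall softness
#'
#' `sigma = sum_i lambda_i wv_i` in A^2 — the sum of PCA eigenvalues
#' restricted to their vibrational content.  The equivalent per-kBT reading
#' (`sigma / kBT`, A^2 mol/kcal, the sum of reciprocal mode stiffnesses) is
#' attached as attribute `per_kBT`.
#'
#' @param result an [bead_pca()] result with vibrational weights (computed
#'   on demand).
#' @return softness in A^2 with attribute `per_kBT`.
#' @export
softness <- function(result) {
  if (is.null(result$vib_weights)) result <- vibrational_weights(result)
  s <- sum(result$eigenvalues * result$vib_weights)
  structure(s, per_kBT = s / result$kBT)
}

#' Projected softness along a predefined mode
#'
#' Intensity of a predefined motion pattern P (unit vector of bead
#' displacements): `sigma_P = sum_i lambda_i wv_i (P . e_i)^2`.  The squared
#' projection makes sigma_P sign-independent (eigenvector signs are
#' arbitrary) and gives the Parseval property: summing sigma_P over any
#' orthonormal basis of projection vectors recovers sigma.
#'
#' @param result an [bead_pca()] result.
#' @param P projection vector, length `3 n_beads` (normalised with a warning
#'   if needed).
#' @return sigma_P in A^2.
#' @export
projected_softness <- function(result, P) {
  if (is.null(result$vib_weights)) result <- vibrational_weights(result)
  P <- as.numeric(P)
  stopifnot(length(P) == nrow(result$eigenvectors))
  nrm <- sqrt(sum(P * P))
  if (nrm == 0) stop("projected_softness: zero projection vector")
  if (abs(nrm - 1) > 1e-8) {
    warning("projection vector not normalised; normalising")
    P <- P / nrm
  }
  proj <- as.numeric(crossprod(result$eigenvectors, P))
  sum(result$eigenvalues * result$vib_weights * proj^2)
}

#' Reference rocking-bundle projection vectors
#'
#' Builds the two four-bead displacement patterns that modulate the
#' bundle-hash separation: (1) symmetric separation — both bundle beads move
#' against both hash beads along the inter-domain axis; (2) rocking — the
#' upper beads converge while the lower beads diverge.  Both are made free
#' of mass-weighted net translation, mutually orthogonalised (Gram-Schmidt)
#' and normalised.
#'
#' @param beads a four-bead [bead_trajectory()] with labels
#'   `bundle_lower`, `bundle_upper`, `hash_lower`, `hash_upper`.
#' @return list of two unit projection vectors (`separation`, `rocking`).
#' @export
rocking_bundle_vectors <- function(beads) {
  stopifnot(inherits(beads, "aqp_beads"), beads$n_beads == 4)
  lb <- beads$labels
  need <- c("bundle_lower", "bundle_upper", "hash_lower", "hash_upper")
  if (is.null(lb) || !all(need %in% lb))
    stop("rocking_bundle_vectors: beads must carry the four domain labels")
  ord <- match(need, lb)
  r <- beads$reference[ord, , drop = FALSE]
  m <- beads$masses[ord]
  com_b <- colSums(r[1:2, ] * m[1:2]) / sum(m[1:2])
  com_h <- colSums(r[3:4, ] * m[3:4]) / sum(m[3:4])
  u <- com_b - com_h
  nu <- sqrt(sum(u * u))
  if (nu < 1e-8) stop("rocking_bundle_vectors: degenerate bead geometry")
  u <- u / nu
  disp <- function(pattern) {  # pattern: per-bead multiples of u, bead order `need`
    d <- pattern %o% u
    d <- d - matrix(colSums(d * m) / sum(m), 4, 3, byrow = TRUE)  # CoM-free
    v <- numeric(12)                      # back to the bead order of `beads`
    for (j in 1:4) v[(ord[j] - 1) * 3 + 1:3] <- d[j, ]
    v / sqrt(sum(v * v))
  }
  # (1) separation: bundle +u, hash -u;  (2) rocking: upper converge, lower diverge
  v1 <- disp(c(1, 1, -1, -1))
  v2 <- disp(c(1, -1, -1, 1))
  v2 <- v2 - sum(v2 * v1) * v1
  v2 <- v2 / sqrt(sum(v2 * v2))
  list(separation = v1, rocking = v2)
}
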