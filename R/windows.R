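# Windowed statistics and flux / domain-motion correlations.

#' Subset a trajectory by frame indices
#'
#' @param traj an `aqp_trajectory`.
#' @param frames integer frame indices to keep (contiguous for meaningful
#'   time analyses).
#' @return the sub-trajectory.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(all(frames >= 1), all(frames <= traj$n_frames))
  trajectory(traj$coords[, , frames, drop = FALSE], traj$topology,
             traj$box[frames, , drop = FALSE], traj$dt_frame)
}

#' Local water diffusion in a constriction region
#'
#' Fits the 3D mean square displacement of waters over lag times in
#' `lag_range`, using only path segments that stay inside the z region for
#' the whole lag, and returns `D = slope/6` together with `D/L`.
#'
#' @param traj centred trajectory.
#' @param waters tracked water selection.
#' @param region `c(z_lo, z_hi)` of the region, Angstrom (default the
#'   5 A-thick constriction centred at 0).
#' @param lag_range MSD fit range, ps.
#' @param L channel length used for `D/L`, Angstrom (30, the membrane span).
#' @param msd_dims 3 for 3D MSD (default), 1 for the z-only variant.
#' @return list with `D` (A^2/ps), `D_over_L` (1/ps; A/ps per channel
#'   length), `n_segments`; `D` is `NA` if no water ever stays in the region
#'   long enough.
#' @export
local_diffusion <- function(traj, waters, region = c(-2.5, 2.5),
                            lag_range = c(2, 10), L = 30, msd_dims = 3) {
  idx <- .as_indices(traj, waters)
  dt <- traj$dt_frame
  smin <- max(1L, ceiling(lag_range[1] / dt))
  smax <- max(smin, floor(lag_range[2] / dt))
  lags <- smin:smax
  zw <- .wrapped_z(traj, idx)
  box <- traj$box[1, ]
  ssum <- numeric(length(lags)); scount <- numeric(length(lags))
  n_seg <- 0
  for (j in seq_along(idx)) {
    inside <- zw[j, ] > region[1] & zw[j, ] <= region[2]
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths > smin)) {
      fr <- starts[k]:ends[k]
      n_seg <- n_seg + 1
      P <- matrix(traj$coords[idx[j], , fr], nrow = 3)
      if (length(fr) > 1) {
        dP <- P[, -1, drop = FALSE] - P[, -ncol(P), drop = FALSE]
        dP <- dP - box * round(dP / box)      # column-recycled minimum image
        dPc <- if (ncol(dP) == 1) dP else t(apply(dP, 1, cumsum))
        P <- cbind(P[, 1], P[, 1] + dPc)
      }
      dims <- if (msd_dims == 1) 3 else 1:3
      for (si in seq_along(lags)) {
        s <- lags[si]
        if (ncol(P) > s) {
          d <- P[dims, (1 + s):ncol(P), drop = FALSE] -
               P[dims, 1:(ncol(P) - s), drop = FALSE]
          ssum[si] <- ssum[si] + sum(colSums(d * d))
          scount[si] <- scount[si] + ncol(d)
        }
      }
    }
  }
  if (all(scount == 0) || sum(scount > 0) < 2)
    return(list(D = NA_real_, D_over_L = NA_real_, n_segments = n_seg))
  msd <- ssum[scount > 0] / scount[scount > 0]
  lt <- lags[scount > 0] * dt
  D <- coef(lm(msd ~ lt))[[2]] / (2 * msd_dims)
  list(D = D, D_over_L = D / L, n_segments = n_seg)
}

#' Per-window statistics linking water flux to structure and dynamics
#'
#' Splits the trajectory into consecutive windows (default 100 ns) and
#' computes, per window: the permeation rate `nw`, the channel opening
#' `dmin`, the four-bead domain softness `sigma_dmn`, the softness of a
#' selected atom set `sigma_sel`, the local constriction diffusion over the
#' channel length `d_over_l`, and the rocking-bundle projected softness
#' `sigma_rb` (sum over the separation and rocking patterns).  Quantities
#' whose inputs are missing from the trajectory (no domain labels, no
#' selection) are `NA`.
#'
#' @param traj centred trajectory with water (and optionally domain-labelled
#'   protein) atoms.
#' @param waters tracked water selection.
#' @param window_ns window length, ns; the trailing remainder is dropped.
#' @param slab an [slab_geometry()].
#' @param selection_sel optional selection for `sigma_sel` (e.g. channel
#'   residues).
#' @param temperature K.
#' @param constriction_width width of the local-diffusion region, Angstrom,
#'   centred at the window's own `z_at_dmin`.
#' @param span membrane span L, Angstrom.
#' @return `data.frame` of class `aqp_windowstats`: one row per window with
#'   `t0`, `t1` (ns), `nw`, `dmin`, `sigma_dmn`, `sigma_sel`, `d_over_l`,
#'   `sigma_rb`.
#' @export
window_stats <- function(traj, waters, window_ns = 100,
                         slab = slab_geometry(), selection_sel = NULL,
                         temperature = 303.15, constriction_width = 5,
                         span = 30) {
  dur_ns <- traj$n_frames * traj$dt_frame / 1000
  n_win <- floor(dur_ns / window_ns + 1e-9)
  if (n_win < 1) stop("window_stats: trajectory shorter than one window")
  fpw <- round(window_ns * 1000 / traj$dt_frame)
  if (fpw < 10) stop("window_stats: window shorter than 10 frame strides")
  has_domains <- all(c("bundle", "hash") %in% traj$topology$domain_label)
  rows <- lapply(seq_len(n_win), function(w) {
    fr <- ((w - 1) * fpw + 1):min(w * fpw, traj$n_frames)
    sub <- subset_frames(traj, fr)
    ev <- detect_permeation_events(sub, waters, slab)
    nw <- nrow(ev) * 100 / window_ns
    prof <- density_profile(sub, waters, window = NULL, span = span)
    op <- channel_opening(prof)
    sdmn <- ssel <- srb <- NA_real_
    if (has_domains) {
      beads <- four_bead_reduction(sub)
      p <- vibrational_weights(bead_pca(beads, temperature))
      sdmn <- as.numeric(softness(p))
      rb <- rocking_bundle_vectors(beads)
      srb <- projected_softness(p, rb$separation) +
        projected_softness(p, rb$rocking)
    }
    if (!is.null(selection_sel)) {
      sidx <- .as_indices(traj, selection_sel)
      bt <- bead_trajectory(sub$coords[sidx, , , drop = FALSE],
                            traj$topology$mass[sidx])
      ps <- vibrational_weights(bead_pca(bt, temperature))
      ssel <- as.numeric(softness(ps))
    }
    dol <- NA_real_
    if (!op$degenerate && is.finite(op$z_at_dmin)) {
      ld <- local_diffusion(sub, waters,
                            region = op$z_at_dmin +
                              c(-0.5, 0.5) * constriction_width,
                            L = span)
      dol <- ld$D_over_L
    }
    data.frame(t0 = (w - 1) * window_ns, t1 = w * window_ns, nw = nw,
               dmin = op$dmin, sigma_dmn = sdmn, sigma_sel = ssel,
               d_over_l = dol, sigma_rb = srb)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("aqp_windowstats", "data.frame")
  out
}

#' Pearson (or Spearman) correlation with a least-squares line
#'
#' @param xs,ys paired observations; non-finite pairs are dropped listwise.
#' @param method `"pearson"` (default; the panels show linear fits) or
#'   `"spearman"`.
#' @return object of class `aqp_correlation`: list with `r`, `n`, `slope`,
#'   `intercept`.
#' @export
correlate <- function(xs, ys, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(xs) & is.finite(ys)
  xs <- xs[ok]; ys <- ys[ok]
  if (length(xs) < 3)
    stop("correlate: need at least 3 finite pairs")
  if (sd(xs) == 0 || sd(ys) == 0)
    stop("correlate: undefined correlation (zero variance)")
  r <- cor(xs, ys, method = method)
  fit <- lm(ys ~ xs)
  structure(list(r = r, n = length(xs), slope = coef(fit)[[2]],
                 intercept = coef(fit)[[1]], method = method),
            class = "aqp_correlation")
}

#' @export
print.aqp_correlation <- function(x, ...) {
  cat(sprintf("<aqp_correlation> r = %.3f (n = %d, %s), y = %.3g x + %.3g\n",
              x$r, x$n, x$method, x$slope, x$intercept))
  invisible(x)
}

#' Flux / opening / softness correlation report
#'
#' The four standard panels: (A) nw vs dmin, (B) nw/dmin vs the four-bead
#' domain softness, (C) nw/dmin vs the selected-residue softness, (D) D/L vs
#' the rocking-bundle projected softness.  Windows with `dmin = 0` have an
#' undefined `nw/dmin` and are dropped listwise; panels whose inputs are
#' degenerate surface an error rather than a silent `NA`.
#'
#' @param stats an [window_stats()] table (>= 3 windows).
#' @return `data.frame` with one row per computable panel: `panel`,
#'   `x_label`, `y_label`, `r`, `n`, `slope`, `intercept`; attribute
#'   `errors` lists panels that failed and why.
#' @export
flux_opening_report <- function(stats) {
  if (nrow(stats) < 3) stop("flux_opening_report: need at least 3 windows")
  ratio <- ifelse(is.finite(stats$dmin) & stats$dmin > 0,
                  stats$nw / stats$dmin, NA_real_)
  panels <- list(
    A = list(x = stats$dmin, y = stats$nw,
             xl = "dmin", yl = "nw"),
    B = list(x = stats$sigma_dmn, y = ratio,
             xl = "sigma_dmn", yl = "nw/dmin"),
    C = list(x = stats$sigma_sel, y = ratio,
             xl = "sigma_sel", yl = "nw/dmin"),
    D = list(x = stats$sigma_rb, y = stats$d_over_l,
             xl = "sigma_rb", yl = "D/L"))
  rows <- list(); errs <- character(0)
  for (p in names(panels)) {
    pn <- panels[[p]]
    cc <- tryCatch(correlate(pn$x, pn$y), error = function(e) e)
    if (inherits(cc, "error")) {
      errs[p] <- conditionMessage(cc)
    } else {
      rows[[p]] <- data.frame(panel = p, x_label = pn$xl, y_label = pn$yl,
                              r = cc$r, n = cc$n, slope = cc$slope,
                              intercept = cc$intercept)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(panel = character(0))
  rownames(out) <- NULL
  if (length(errs)) attr(out, "errors") <- errs
  out
}
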