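# Accessible dye volumes: simplified single-sphere grid AV with geodesic
# reachability (flood fill from the attachment site), per-frame AV series
# and their auto-/cross-correlations.

#' Accessible-volume parameters
#'
#' Simplified grid AV: the dye is a single sphere of radius `dye_radius` on
#' a linker of length `linker_length`; grid cells within the linker length
#' of the attachment particle that are clash-free (no particle within
#' dye radius + contact radius) and reachable from the attachment site by a
#' 6-connected path of free cells count toward the volume.
#'
#' @param linker_length maximal dye distance from the attachment (Angstrom).
#' @param linker_width linker diameter (Angstrom); retained as metadata for
#'   the dye model, not used by the single-sphere search.
#' @param dye_radius dye sphere radius (Angstrom).
#' @param spacing grid spacing (Angstrom).
#' @param contact_radius per-particle contact radius (Angstrom).
#' @return object of class `av_params`.
#' @export
av_params <- function(linker_length = 20, linker_width = 4.5,
                      dye_radius = 3.5, spacing = 0.9,
                      contact_radius = 2.0) {
  chk(linker_length > 0 && linker_width > 0 && dye_radius > 0 &&
        spacing > 0, "AV geometry must be positive")
  if (spacing > dye_radius) {
    warning("grid spacing exceeds the dye radius; AV will be coarse")
  }
  structure(list(linker_length = linker_length,
                 linker_width = linker_width,
                 dye_radius = dye_radius, spacing = spacing,
                 contact_radius = contact_radius),
            class = "av_params")
}

#' Accessible volume of a dye around an attachment site
#'
#' @param coords particle coordinates (n x 3, Angstrom) of one frame.
#' @param attachment index of the attachment particle.
#' @param params an [av_params()].
#' @return AV scalar (Angstrom^3).
#' @export
accessible_volume <- function(coords, attachment, params = av_params()) {
  chk(attachment >= 1 && attachment <= nrow(coords),
      "attachment particle does not exist")
  p <- params
  att <- coords[attachment, ]
  g1 <- seq(-p$linker_length, p$linker_length, by = p$spacing)
  ng <- length(g1)
  # grid point coordinates relative to the attachment
  gx <- rep(g1, times = ng * ng)
  gy <- rep(rep(g1, each = ng), times = ng)
  gz <- rep(g1, each = ng * ng)
  within <- (gx^2 + gy^2 + gz^2) <= p$linker_length^2
  free <- within
  # clash test against all particles except the attachment itself
  others <- coords[-attachment, , drop = FALSE]
  rcl2 <- (p$dye_radius + p$contact_radius)^2
  for (i in seq_len(nrow(others))) {
    d <- others[i, ] - att
    if (sum(pmax(abs(d) - p$linker_length, 0)^2) > rcl2) next
    free <- free & ((gx - d[1])^2 + (gy - d[2])^2 + (gz - d[3])^2 > rcl2)
  }
  if (!any(free)) return(0)
  # geodesic flood fill (6-connectivity) from the cell nearest the
  # attachment point; if that cell clashes, seed from the nearest free cell
  # within one dye diameter
  ic <- (ng + 1) %/% 2
  seed <- ic + (ic - 1) * ng + (ic - 1) * ng * ng
  if (!free[seed]) {
    d2 <- gx^2 + gy^2 + gz^2
    cand <- which(free & d2 <= (2 * p$dye_radius)^2)
    if (length(cand) == 0) return(0)
    seed <- cand[which.min(d2[cand])]
  }
  nxyz <- ng * ng
  visited <- logical(length(free))
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier) > 0) {
    ix <- ((frontier - 1) %% ng) + 1
    iy <- (((frontier - 1) %/% ng) %% ng) + 1
    iz <- ((frontier - 1) %/% nxyz) + 1
    nb <- c(frontier[ix > 1] - 1L, frontier[ix < ng] + 1L,
            frontier[iy > 1] - ng, frontier[iy < ng] + ng,
            frontier[iz > 1] - nxyz, frontier[iz < ng] + nxyz)
    nb <- unique(nb[free[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  sum(visited) * p$spacing^3
}

#' Accessible-volume time series along a trajectory
#'
#' @param traj a [trajectory()] (usually after [superpose()]).
#' @param attachment attachment particle index.
#' @param params an [av_params()].
#' @return numeric vector of per-frame AVs (Angstrom^3), with the frame
#'   interval attached as an attribute.
#' @export
av_series <- function(traj, attachment, params = av_params()) {
  nf <- dim(traj$coords)[1]
  out <- vapply(seq_len(nf), function(j) {
    accessible_volume(traj$coords[j, , ], attachment, params)
  }, 1)
  attr(out, "frame_interval") <- traj$frame_interval
  out
}

#' Correlation of accessible-volume series with bi-exponential fit
#'
#' Normalized auto- (one series) or cross-correlation (two series) with an
#' unconstrained two-exponential fit of the decay. Components faster than
#' the frame interval are flagged as unresolved.
#'
#' @param series_a,series_b numeric series (series_b = NULL for the ACF);
#'   frame interval (ns) read from the attribute or `frame_interval`.
#' @param frame_interval frame spacing (ns) if not attached to `series_a`.
#' @param lag_max maximal lag in frames.
#' @return object of class `av_correlation`: `lag` (ns), `corr`, fitted
#'   `tau` (ns, sorted), `amplitude`, `unresolved` flags.
#' @export
av_correlation <- function(series_a, series_b = NULL,
                           frame_interval = NULL, lag_max = NULL) {
  dt <- frame_interval %||% attr(series_a, "frame_interval") %||% 1
  n <- length(series_a)
  chk(n >= 2, "need at least 2 frames")
  chk(sd(series_a) > 0, "constant series has no correlation")
  if (is.null(lag_max)) lag_max <- floor(n / 2)
  lag_max <- min(lag_max, n - 1)
  if (is.null(series_b)) {
    corr <- acf_fft(series_a, lag_max)
  } else {
    chk(length(series_b) == n, "series lengths differ")
    chk(sd(series_b) > 0, "constant series has no correlation")
    xa <- series_a - mean(series_a)
    xb <- series_b - mean(series_b)
    m <- nextn(2L * n, 2L)
    fa <- fft(c(xa, rep(0, m - n)))
    fb <- fft(c(xb, rep(0, m - n)))
    s <- Re(fft(fa * Conj(fb), inverse = TRUE)) / m
    corr <- s[seq_len(lag_max + 1)] / (n - 0:lag_max) /
      sqrt(sum(xa^2) / n * sum(xb^2) / n)
  }
  lag <- (0:lag_max) * dt
  ft <- fit_exp_sum(lag, corr, 2, t_range = c(dt, max(lag)))
  structure(list(lag = lag, corr = corr, tau = ft$tau,
                 amplitude = ft$amplitude,
                 unresolved = ft$tau < dt,
                 cross = !is.null(series_b)),
            class = "av_correlation")
}

#' @export
print.av_correlation <- function(x, ...) {
  lab <- ifelse(x$unresolved, " (unresolved: below frame interval)", "")
  cat("<av_correlation> ", if (x$cross) "cross" else "auto",
      "-correlation; components:\n", sep = "")
  for (i in seq_along(x$tau)) {
    cat("  tau = ", format(x$tau[i], digits = 3), " ns, amplitude ",
        format(x$amplitude[i], digits = 3), lab[i], "\n", sep = "")
  }
  invisible(x)
}
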