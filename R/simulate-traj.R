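# Trajectory generators: a rotating-axis series for rotational-ACF analysis
# and a bead-dimer trajectory with Ornstein-Uhlenbeck internal modes
# superimposed on rigid-body translational/rotational diffusion.

#' Trajectory container
#'
#' @param coords array `frames x particles x 3` (Angstrom).
#' @param atoms data.frame with per-particle metadata: `mass` (amu),
#'   `resid`, `chain`, `name`, `backbone` (logical), `ss` (logical,
#'   helix/sheet flag).
#' @param frame_interval frame spacing (ns).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(coords, atoms, frame_interval) {
  chk(length(dim(coords)) == 3 && dim(coords)[3] == 3,
      "coords must be frames x particles x 3")
  chk(nrow(atoms) == dim(coords)[2],
      "atoms metadata must match particle count")
  chk(frame_interval > 0, "frame interval must be positive")
  structure(list(coords = coords, atoms = atoms,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<trajectory> ", d[1], " frames x ", d[2], " particles, dt = ",
      x$frame_interval, " ns\n", sep = "")
  invisible(x)
}

#' Simulate a rotating unit axis
#'
#' Rotational Brownian motion of a body axis (isotropic or per-axis
#' diffusion coefficients), optionally superimposed on a constant rotation
#' about a fixed lab axis. For isotropic diffusion the axis-component
#' autocorrelation decays as exp(-2 D_r t) (rank-1 relaxation), i.e. with
#' time constant 1/(2 D_r).
#'
#' @param config an [orientation_config()].
#' @return object of class `orientation_trajectory`: list with `axis` (list
#'   of `n_frames x 3` unit-vector matrices, one per replica) and
#'   `frame_interval` (ns).
#' @export
simulate_orientation <- function(config) {
  chk(inherits(config, "orientation_config"), "config must be an orientation_config")
  chk(config$n_frames >= 1, "zero frames requested")
  seed_guard(config$seed)
  cf <- config
  dvec <- if (length(cf$D_r) == 1) rep(cf$D_r, 3) else cf$D_r
  dt <- cf$frame_interval
  wmat <- if (cf$omega != 0) {
    rot_about_axis(cf$omega_axis, 2 * pi * cf$omega * dt)
  } else NULL
  start <- cf$start / sqrt(sum(cf$start^2))
  reps <- vector("list", cf$replicas)
  for (r in seq_len(cf$replicas)) {
    u <- matrix(0, cf$n_frames, 3)
    rot <- diag(3)
    sds <- sqrt(2 * dvec * dt)
    for (j in seq_len(cf$n_frames)) {
      u[j, ] <- rot %*% start
      if (any(sds > 0)) {
        dphi <- rnorm(3, sd = sds)
        ang <- sqrt(sum(dphi^2))
        if (ang > 0) rot <- rot_about_axis(dphi, ang) %*% rot
      }
      if (!is.null(wmat)) rot <- wmat %*% rot
    }
    reps[[r]] <- u
  }
  structure(list(axis = reps, frame_interval = dt, config = cf),
            class = "orientation_trajectory")
}

#' Simulate a bead-dimer trajectory with OU internal modes
#'
#' Internal motion is a sum of Ornstein-Uhlenbeck mode projections along
#' fixed displacement vectors; the internal structure then undergoes
#' rigid-body rotational diffusion about its center of mass and
#' translational diffusion.
#'
#' @param config a [bead_dimer_config()].
#' @return a [trajectory()].
#' @export
simulate_bead_dimer <- function(config) {
  chk(inherits(config, "bead_dimer_config"), "config must be a bead_dimer_config")
  seed_guard(config$seed)
  cf <- config
  n <- nrow(cf$coords)
  nf <- cf$n_frames
  dt <- cf$frame_interval

  proj <- lapply(cf$modes, function(m) ou_series(nf, dt, m$tau, m$rms))
  com <- colMeans(cf$coords)
  x0 <- sweep(cf$coords, 2, com)

  trans <- cbind(cumsum(rnorm(nf, sd = sqrt(2 * cf$D_t * dt))),
                 cumsum(rnorm(nf, sd = sqrt(2 * cf$D_t * dt))),
                 cumsum(rnorm(nf, sd = sqrt(2 * cf$D_t * dt))))
  coords <- array(0, c(nf, n, 3))
  rot <- diag(3)
  sdr <- sqrt(2 * cf$D_r * dt)
  for (j in seq_len(nf)) {
    xj <- x0
    for (k in seq_along(cf$modes)) {
      xj <- xj + proj[[k]][j] * cf$modes[[k]]$vector
    }
    coords[j, , ] <- t(rot %*% t(xj)) +
      matrix(com + trans[j, ], n, 3, byrow = TRUE)
    if (sdr > 0) {
      dphi <- rnorm(3, sd = sdr)
      ang <- sqrt(sum(dphi^2))
      if (ang > 0) rot <- rot_about_axis(dphi, ang) %*% rot
    }
  }
  atoms <- data.frame(mass = cf$masses, resid = seq_len(n),
                      chain = cf$chain, name = "CA",
                      backbone = TRUE, ss = TRUE)
  tr <- trajectory(coords, atoms, dt)
  tr$truth <- list(modes = cf$modes, D_t = cf$D_t, D_r = cf$D_r)
  tr
}
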