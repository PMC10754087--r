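# Neutron-observable generators: backscattering spectra S(q, omega) from the
# two-Lorentzian jump model with a diffusion-in-a-sphere EISF, and spin-echo
# intermediate scattering functions I(q, tau) from an explicit stochastic
# simulation of rigid-body rotational diffusion (translation analytic),
# optionally with one internal OU mode.

#' Spherical Bessel function j1 and the diffusion-in-a-sphere EISF
#'
#' `eisf_sphere(q, a)` returns A0(q) = (3 j1(qa) / (qa))^2, the elastic
#' fraction of motion confined to a sphere of radius `a`. A0 -> 1 as a -> 0.
#'
#' @param x,q,a numeric arguments; q in 1/Angstrom, a in Angstrom.
#' @return numeric vector.
#' @export
sphere_j1 <- function(x) {
  out <- ifelse(abs(x) < 1e-4,
                x / 3 - x^3 / 30, # series, avoids 0/0
                sin(x) / x^2 - cos(x) / x)
  out
}

#' @rdname sphere_j1
#' @export
eisf_sphere <- function(q, a) {
  x <- q * a
  ifelse(abs(x) < 1e-8, 1, (3 * sphere_j1(x) / x)^2)
}

lorentz <- function(omega, gamma) gamma / (pi * (gamma^2 + omega^2))

# Convolve a spectrum (uniform omega grid) with a Gaussian resolution of SD
# sigma. Kernel is truncated at 6 sigma and renormalized on the grid.
convolve_resolution <- function(y, omega, sigma) {
  dw <- omega[2] - omega[1]
  m <- ceiling(6 * sigma / dw)
  kx <- (-m:m) * dw
  kern <- exp(-kx^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  full <- convolve(y, rev(kern), type = "open")
  full[(m + 1):(m + length(y))]
}

#' Simulate backscattering (QENS) spectra
#'
#' S(q, omega) = R (x) (A0(q) L(Gamma_g) + (1 - A0(q)) L(Gamma_g +
#' Gamma_int)) + background, with Gamma_g = D_app q^2, A0 the
#' diffusion-in-a-sphere EISF, R a Gaussian resolution, and optional
#' Gaussian noise (SD = `noise` times the per-q peak amplitude).
#'
#' @param config a [qens_config()].
#' @return object of class `qens_spectra`: list with `q`, `omega`, `S`
#'   (matrix omega x q), `err`, `resolution_sigma`, `truth`.
#' @export
simulate_qens <- function(config) {
  chk(inherits(config, "qens_config"), "config must be a qens_config")
  chk(length(config$q) > 0 && length(config$omega) > 1, "empty grids")
  seed_guard(config$seed)
  cf <- config
  nw <- length(cf$omega)
  S <- err <- matrix(0, nw, length(cf$q))
  for (k in seq_along(cf$q)) {
    a0 <- eisf_sphere(cf$q[k], cf$a)
    gg <- cf$D_app * cf$q[k]^2
    clean <- a0 * lorentz(cf$omega, gg) +
      (1 - a0) * lorentz(cf$omega, gg + cf$gamma_int)
    conv <- convolve_resolution(clean, cf$omega, cf$resolution_sigma) +
      cf$background
    sd_k <- cf$noise * max(conv)
    S[, k] <- conv + if (sd_k > 0) rnorm(nw, sd = sd_k) else 0
    err[, k] <- max(sd_k, 1e-12)
  }
  structure(list(q = cf$q, omega = cf$omega, S = S, err = err,
                 resolution_sigma = cf$resolution_sigma,
                 truth = list(D_app = cf$D_app, a = cf$a,
                              gamma_int = cf$gamma_int,
                              background = cf$background)),
            class = "qens_spectra")
}

#' @export
print.qens_spectra <- function(x, ...) {
  cat("<qens_spectra> ", length(x$q), " q values x ", length(x$omega),
      " energy points, resolution sigma = ", x$resolution_sigma,
      " 1/ns\n", sep = "")
  invisible(x)
}

#' Simulate spin-echo intermediate scattering functions
#'
#' I(q, tau) is computed as a Monte Carlo ensemble average over rigid-body
#' rotational-diffusion paths of a bead body (uniform initial orientation,
#' sequential small random rotations along the tau grid), multiplied by the
#' analytic translational factor exp(-D_t q^2 tau), and normalized to
#' I(q, 0) = 1. An optional internal mode adds an OU displacement along a
#' fixed eigenvector, giving a faster-relaxing component whose weight is the
#' mode's scattering amplitude.
#'
#' @param config an [nse_config()].
#' @return object of class `isf`: list with `q`, `tau`, `I` (matrix
#'   tau x q), `err`, `truth`.
#' @export
simulate_nse <- function(config) {
  chk(inherits(config, "nse_config"), "config must be an nse_config")
  seed_guard(config$seed)
  cf <- config
  x0 <- sweep(cf$coords, 2, colSums(cf$coords * cf$b) / sum(cf$b))
  nt <- length(cf$tau)
  nq <- length(cf$q)
  acc <- matrix(0, nt, nq) # sum over samples of Re[F(tau) conj(F(0))]
  norm0 <- rep(0, nq)
  dtau <- diff(cf$tau)
  for (s in seq_len(cf$n_samples)) {
    rot <- quat_to_mat(runif_quat(1)[1, ])
    p <- if (!is.null(cf$mode)) {
      ou_irregular(cf$tau, cf$mode$tau, cf$mode$rms)
    } else NULL
    f0 <- NULL
    for (j in seq_len(nt)) {
      xj <- x0
      if (!is.null(p)) xj <- xj + p[j] * cf$mode$vector
      zc <- (xj %*% t(rot))[, 3] # q along lab z
      for (k in seq_len(nq)) {
        fk <- sum(cf$b * exp(1i * cf$q[k] * zc))
        if (j == 1) {
          f0 <- c(f0, fk)
          norm0[k] <- norm0[k] + Mod(fk)^2
          acc[1, k] <- acc[1, k] + Mod(fk)^2
        } else {
          acc[j, k] <- acc[j, k] + Re(fk * Conj(f0[k]))
        }
      }
      if (j < nt) {
        dphi <- rnorm(3, sd = sqrt(2 * cf$D_r * dtau[j]))
        ang <- sqrt(sum(dphi^2))
        if (ang > 0) rot <- rot_about_axis(dphi, ang) %*% rot
      }
    }
  }
  I <- sweep(acc, 2, norm0, "/") *
    exp(-outer(cf$tau, cf$D_t * cf$q^2))
  if (cf$noise > 0) {
    I <- I + matrix(rnorm(nt * nq, sd = cf$noise), nt, nq) * abs(I)
  }
  err <- pmax(cf$noise * abs(I), 1e-4)
  structure(list(q = cf$q, tau = cf$tau, I = I, err = err,
                 truth = list(D_t = cf$D_t, D_r = cf$D_r, mode = cf$mode)),
            class = "isf")
}

# unit quaternion (x, y, z, w) to rotation matrix
quat_to_mat <- function(q) {
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# stationary OU sampled on a (possibly irregular) sorted grid
ou_irregular <- function(t, tau, sigma) {
  n <- length(t)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sigma)
  if (n > 1) {
    phi <- exp(-diff(t) / tau)
    z <- rnorm(n - 1)
    for (i in 2:n) {
      x[i] <- phi[i - 1] * x[i - 1] + sigma * sqrt(1 - phi[i - 1]^2) * z[i - 1]
    }
  }
  x
}

#' @export
print.isf <- function(x, ...) {
  cat("<isf> I(q, tau): ", length(x$q), " q values x ", length(x$tau),
      " spin-echo times\n", sep = "")
  invisible(x)
}
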