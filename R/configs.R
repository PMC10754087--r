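# Configuration objects for the synthetic-data generators. The default
# configurations carry the fitted values of the reference system (an
# AMPPNP-closed / open Hsp90 dimer) as ground truths, so parameter-recovery
# tests double as end-to-end checks of each analysis stage.

#' Photon-stream generator configuration
#'
#' Describes a confocal single-molecule experiment: freely diffusing labelled
#' molecules crossing a 3D-Gaussian detection volume, with triplet blinking,
#' slow brightness fluctuations (conformational bunching), photon antibunching
#' tied to the fluorescence lifetime, FRET channel partitioning and a
#' hierarchical (dye / local / global) rotational process that sets the
#' polarization statistics.
#'
#' @param duration measurement time (s).
#' @param brightness mean detected count rate of one molecule at the focus
#'   center, orientation-averaged (photons/s).
#' @param background per-channel background rate (photons/s), length 4
#'   (donor par/perp, acceptor par/perp).
#' @param tau_D translational diffusion time through the focus (s).
#' @param kappa focal eccentricity (axial/lateral), dimensionless.
#' @param occupancy mean number of molecules in the effective focal volume.
#' @param n_molecules number of simulated emitters.
#' @param c_T,tau_T triplet bunching contrast and relaxation time (s).
#' @param c_b,tau_b slow brightness-bunching contrast and correlation time (s).
#' @param bunching_process "telegraph" (symmetric two-state) or "ou"
#'   (Ornstein-Uhlenbeck brightness modulation).
#' @param tau_ab antibunching (fluorescence-lifetime) time (s).
#' @param tau_0 detection delay applied to perpendicular channels (s).
#' @param states data.frame with columns `E` (true FRET efficiency) and
#'   `occupancy` (species fractions summing to 1).
#' @param alpha,delta,gamma_f,beta_f,G correction factors: crosstalk, direct
#'   excitation, detection/quantum-yield ratio, excitation ratio,
#'   polarization balance (detected perpendicular/parallel efficiency).
#' @param rho_dye,rho_local,rho_global rotational correlation times (s) of
#'   dye wobble, local segment motion, and whole-molecule rotation.
#' @param A_dye,A_local cone plateau amplitudes in [0, 1].
#' @param photoselection excitation photoselection depth in [0, 1]: the
#'   excitation rate scales as (1 - eps) + 3 eps cos^2(theta). 1 = full
#'   linear photoselection; values < 1 model excitation saturation at high
#'   cw power, which compresses the orientation dependence of the rate.
#' @param r0 fundamental anisotropy, in (0, 0.4].
#' @param lifetime,lifetime_a donor / acceptor fluorescence lifetimes (s).
#' @param mode "cw" (continuous green excitation) or "pie" (pulsed
#'   interleaved excitation; microtimes recorded).
#' @param pie_period excitation period in PIE mode (s).
#' @param occupancy_update diffusion position update interval (s).
#' @param max_photons resource cap on generated photons.
#' @param seed RNG seed (integer) or NULL.
#' @return object of class `photon_stream_config`.
#' @export
photon_stream_config <- function(duration = 30,
                                 brightness = 3e5,
                                 background = rep(250, 4),
                                 tau_D = 1e-3,
                                 kappa = 5,
                                 occupancy = 0.3,
                                 n_molecules = 4,
                                 c_T = 0.15, tau_T = 2.5e-6,
                                 c_b = 0.2, tau_b = 149e-9,
                                 bunching_process = c("telegraph", "ou"),
                                 tau_ab = 3e-9,
                                 tau_0 = 3e-9,
                                 states = data.frame(E = 0.6, occupancy = 1),
                                 alpha = 0.04, delta = 0,
                                 gamma_f = 1, beta_f = 1, G = 1,
                                 rho_dye = 0.35e-9, rho_local = 3e-9,
                                 rho_global = 52e-9,
                                 A_dye = 0.2, A_local = 0.05,
                                 photoselection = 0.3,
                                 r0 = 0.4,
                                 lifetime = 3e-9, lifetime_a = 3.8e-9,
                                 mode = c("cw", "pie"),
                                 pie_period = 50e-9,
                                 occupancy_update = tau_D / 50,
                                 max_photons = 2e7,
                                 seed = NULL) {
  bunching_process <- match.arg(bunching_process)
  mode <- match.arg(mode)
  cfg <- list(
    duration = duration, brightness = brightness, background = background,
    tau_D = tau_D, kappa = kappa, occupancy = occupancy,
    n_molecules = as.integer(n_molecules),
    c_T = c_T, tau_T = tau_T, c_b = c_b, tau_b = tau_b,
    bunching_process = bunching_process,
    tau_ab = tau_ab, tau_0 = tau_0, states = states,
    alpha = alpha, delta = delta, gamma_f = gamma_f, beta_f = beta_f, G = G,
    rho_dye = rho_dye, rho_local = rho_local, rho_global = rho_global,
    A_dye = A_dye, A_local = A_local, photoselection = photoselection,
    r0 = r0,
    lifetime = lifetime, lifetime_a = lifetime_a,
    mode = mode, pie_period = pie_period,
    occupancy_update = occupancy_update, max_photons = max_photons,
    seed = seed
  )
  class(cfg) <- "photon_stream_config"
  validate_photon_stream_config(cfg)
  cfg
}

validate_photon_stream_config <- function(cfg) {
  with(cfg, {
    chk(duration > 0, "duration must be positive")
    chk(brightness > 0, "brightness must be positive")
    chk(all(background >= 0) && length(background) == 4,
        "background must be 4 nonnegative rates")
    chk(all(c(tau_D, tau_T, tau_b, tau_ab, rho_dye, rho_local,
              rho_global, lifetime, lifetime_a, pie_period) > 0),
        "all time constants must be positive")
    chk(all(c(c_T, c_b, alpha, delta) >= 0), "amplitudes must be >= 0")
    chk(all(c(gamma_f, beta_f, G) > 0), "gamma, beta, G must be positive")
    chk(kappa > 0, "kappa must be positive")
    chk(occupancy > 0, "occupancy must be positive")
    chk(n_molecules >= 1, "need at least one molecule")
    chk(is.data.frame(states) && all(c("E", "occupancy") %in% names(states)),
        "states needs columns E and occupancy")
    chk(all(states$E >= 0 & states$E <= 1), "E must lie in [0, 1]")
    chk(abs(sum(states$occupancy) - 1) < 1e-8, "occupancies must sum to 1")
    chk(all(c(A_dye, A_local) >= 0 & c(A_dye, A_local) <= 1),
        "cone amplitudes must lie in [0, 1]")
    chk(photoselection >= 0 && photoselection <= 1,
        "photoselection depth must lie in [0, 1]")
    chk(r0 > 0 && r0 <= 0.4, "r0 must lie in (0, 0.4]")
  })
  invisible(cfg)
}

#' Default nsFCS configurations for the closed-A and open states
#'
#' Ground truths follow the fitted values of the reference measurements:
#' closed-A bunching time 149 ns (substate E = 0.4-0.8); open-state bunching
#' time 187 ns with the open species at E ~ 0.17 (substate E = 0.1-0.4)
#' coexisting with a residual closed-A fraction. The default duration and
#' molecular brightness are chosen so that a set of six measurements
#' determines the bunching time with a spread comparable to the reference
#' study, at desk-scale runtime.
#'
#' @param duration measurement time (s).
#' @param brightness molecular brightness (photons/s).
#' @param occupancy,background see [photon_stream_config()].
#' @param seed RNG seed.
#' @param ... overrides passed to [photon_stream_config()].
#' @return a `photon_stream_config`.
#' @export
closed_a_config <- function(duration = 60, brightness = 4.5e5,
                            seed = NULL, ...) {
  photon_stream_config(duration = duration, brightness = brightness,
                       tau_b = 149e-9,
                       states = data.frame(E = 0.6, occupancy = 1),
                       seed = seed, ...)
}

#' @rdname closed_a_config
#' @export
open_config <- function(duration = 150, brightness = 1e6,
                        occupancy = 0.05, background = rep(150, 4),
                        seed = NULL, ...) {
  # substate-specific measurement: low occupancy (a few hundred pM) so the
  # DeltaT criterion separates single-molecule bursts, low background, and
  # high molecular brightness / longer acquisition to offset the pair
  # statistics lost to the dilution
  photon_stream_config(duration = duration, brightness = brightness,
                       tau_b = 187e-9, occupancy = occupancy,
                       background = background,
                       states = data.frame(E = c(0.17, 0.63),
                                           occupancy = c(0.8, 0.2)),
                       seed = seed, ...)
}

#' Time-resolved anisotropy (TRA) decay generator configuration
#'
#' Describes subpopulation acceptor anisotropy decays under pulsed
#' excitation. Times are in nanoseconds. Ground truths follow the fitted
#' cone-in-cone values of the reference system: shared dye rotation
#' 0.35 ns, shared global rotation 52 ns, population-dependent local times
#' near 3 ns, r0 = 0.4. Cone amplitudes are not printed in the reference
#' and default to plausible tethered-dye values.
#'
#' @param populations data.frame with one row per FRET population: columns
#'   `label`, `rho_local` (ns), `A_local`, `counts` (total photons).
#' @param rho_dye,rho_global shared rotation times (ns).
#' @param A_dye shared dye cone amplitude.
#' @param r0 fundamental anisotropy.
#' @param lifetime acceptor fluorescence lifetime (ns).
#' @param bin_width microtime bin width (ns).
#' @param window pulse period / histogram span (ns).
#' @param G,l1,l2 polarization balance and objective depolarization factors.
#' @param seed RNG seed.
#' @return object of class `tra_config`.
#' @export
tra_config <- function(populations = data.frame(
                         label = c("open", "closedA", "closedB"),
                         rho_local = c(2.5, 3.0, 3.5),
                         A_local = c(0.5, 0.5, 0.5),
                         counts = rep(2e7, 3)),
                       rho_dye = 0.35, rho_global = 52,
                       A_dye = 0.7, r0 = 0.4,
                       lifetime = 3.8,
                       bin_width = 0.016, window = 50,
                       G = 1, l1 = 0.0308, l2 = 0.0368,
                       seed = NULL) {
  cfg <- list(populations = populations, rho_dye = rho_dye,
              rho_global = rho_global, A_dye = A_dye, r0 = r0,
              lifetime = lifetime, bin_width = bin_width, window = window,
              G = G, l1 = l1, l2 = l2, seed = seed)
  chk(all(c(rho_dye, rho_global, lifetime, bin_width, window) > 0),
      "times must be positive")
  chk(r0 > 0 && r0 <= 0.4, "r0 must lie in (0, 0.4]")
  chk(all(populations$rho_local > 0), "rho_local must be positive")
  chk(all(populations$A_local >= 0 & populations$A_local <= 1) &&
        A_dye >= 0 && A_dye <= 1, "cone amplitudes must lie in [0, 1]")
  class(cfg) <- "tra_config"
  cfg
}

#' Isotropic-rotor trajectory configuration
#'
#' Defaults reproduce the reference MD analysis: an axis autocorrelation
#' decay time of 81 ns sampled at 0.1 ns over 1e4 frames, five replicas.
#' For an isotropic rotor the axis (rank-1) ACF decays with 1/(2 D_r), so
#' the default D_r is 1/(2 x 81 ns).
#'
#' @param D_r rotational diffusion coefficient(s) (1/ns); length 1 or 3.
#' @param omega constant angular velocity about `omega_axis` (1/ns; turns
#'   per ns of the phase 2*pi*omega*t in the rotational ACF model).
#' @param omega_axis lab axis of the constant rotation.
#' @param frame_interval frame spacing (ns).
#' @param n_frames frames per replica.
#' @param replicas number of independent replicas.
#' @param start starting axis orientation (unit 3-vector).
#' @param seed RNG seed.
#' @return object of class `orientation_config`.
#' @export
orientation_config <- function(D_r = 1 / (2 * 81), omega = 0,
                               omega_axis = c(0, 0, 1),
                               frame_interval = 0.1, n_frames = 1e4,
                               replicas = 5, start = c(1, 0, 0),
                               seed = NULL) {
  chk(all(D_r >= 0), "D_r must be >= 0")
  chk(length(D_r) %in% c(1, 3), "D_r must have length 1 or 3")
  chk(frame_interval > 0, "frame interval must be positive")
  chk(n_frames >= 1, "need at least one frame")
  cfg <- list(D_r = D_r, omega = omega, omega_axis = omega_axis,
              frame_interval = frame_interval,
              n_frames = as.integer(n_frames),
              replicas = as.integer(replicas), start = start, seed = seed)
  class(cfg) <- "orientation_config"
  cfg
}

#' Bead-dimer trajectory configuration
#'
#' A desk-scale stand-in for all-atom trajectories of a two-chain protein:
#' two bead lobes joined at a dimer interface, internal Ornstein-Uhlenbeck
#' modes superimposed on rigid-body translational/rotational diffusion.
#'
#' @param coords n x 3 bead coordinates (Angstrom); default builds a
#'   32-bead elongated dimer.
#' @param masses per-bead masses (amu).
#' @param chain chain identifier per bead.
#' @param modes list of internal modes, each `list(vector = n x 3
#'   displacement (Angstrom), tau = OU relaxation (ns), rms = amplitude
#'   (Angstrom))`.
#' @param D_t translational diffusion (Angstrom^2/ns).
#' @param D_r rotational diffusion (1/ns).
#' @param frame_interval frame spacing (ns).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return object of class `bead_dimer_config`.
#' @export
bead_dimer_config <- function(coords = NULL, masses = NULL, chain = NULL,
                              modes = list(),
                              D_t = 4.71, D_r = 1.64e-3,
                              frame_interval = 0.1, n_frames = 5000,
                              seed = NULL) {
  if (is.null(coords)) {
    geom <- default_dimer_geometry()
    coords <- geom$coords
    chain <- geom$chain
  }
  n <- nrow(coords)
  chk(n >= 4, "need at least 4 beads")
  if (is.null(masses)) masses <- rep(110, n)
  if (is.null(chain)) chain <- rep("A", n)
  chk(all(is.finite(coords)), "coordinates must be finite")
  for (m in modes) {
    chk(all(is.finite(m$vector)) && nrow(m$vector) == n,
        "mode vectors must be finite with one row per bead")
    chk(m$tau > 0 && m$rms >= 0, "mode tau > 0 and rms >= 0 required")
  }
  chk(frame_interval > 0, "frame interval must be positive")
  cfg <- list(coords = coords, masses = masses, chain = chain, modes = modes,
              D_t = D_t, D_r = D_r, frame_interval = frame_interval,
              n_frames = as.integer(n_frames), seed = seed)
  class(cfg) <- "bead_dimer_config"
  cfg
}

# Two-lobe 32-bead dimer, ~100 Angstrom end to end, mimicking an elongated
# closed dimer with M/N lobes.
default_dimer_geometry <- function() {
  set.seed(20)
  lobe <- function(center, n = 16) {
    sweep(matrix(rnorm(n * 3, sd = 9), n, 3), 2, center, "+")
  }
  coords <- rbind(lobe(c(0, 0, 28)), lobe(c(0, 0, -28)))
  list(coords = coords, chain = rep(c("A", "B"), each = 16))
}

#' Backscattering (QENS) spectra generator configuration
#'
#' Spectra follow a two-Lorentzian jump model: a global component of width
#' D_app q^2 and a confined internal component (diffusion-in-a-sphere EISF
#' with radius `a`), convolved with a Gaussian resolution. Ground truths
#' default to the reference fit: D_app = 3.27 Angstrom^2/ns, a = 1.95
#' Angstrom.
#'
#' @param q scattering vectors (1/Angstrom).
#' @param omega energy-transfer grid (1/ns).
#' @param resolution_sigma Gaussian resolution SD (1/ns).
#' @param D_app apparent global diffusion coefficient (Angstrom^2/ns).
#' @param a confinement radius (Angstrom).
#' @param gamma_int internal relaxation linewidth (1/ns, HWHM).
#' @param background flat background level.
#' @param noise relative Gaussian noise level.
#' @param seed RNG seed.
#' @return object of class `qens_config`.
#' @export
qens_config <- function(q = seq(0.2, 1.8, length.out = 15),
                        omega = seq(-45, 45, by = 0.25),
                        resolution_sigma = 0.6,
                        D_app = 3.27, a = 1.95, gamma_int = 15,
                        background = 1e-4, noise = 0.01, seed = NULL) {
  chk(all(q > 0), "q must be positive")
  chk(length(omega) > 1, "omega grid required")
  chk(resolution_sigma > 0, "resolution width must be positive")
  chk(a >= 0, "confinement radius must be >= 0")
  chk(D_app > 0 && gamma_int >= 0, "D_app > 0 and gamma_int >= 0 required")
  cfg <- list(q = q, omega = omega, resolution_sigma = resolution_sigma,
              D_app = D_app, a = a, gamma_int = gamma_int,
              background = background, noise = noise, seed = seed)
  class(cfg) <- "qens_config"
  cfg
}

#' Spin-echo intermediate-scattering generator configuration
#'
#' I(q, tau) is computed from an explicit stochastic simulation of
#' rigid-body rotational diffusion of a bead body (translation enters
#' analytically as exp(-D_t q^2 tau)), optionally with one internal
#' Ornstein-Uhlenbeck mode along a displacement eigenvector.
#'
#' @param coords bead coordinates (Angstrom); default = built-in dimer.
#' @param b per-bead scattering lengths.
#' @param q scattering vectors (1/Angstrom).
#' @param tau spin-echo times (ns), starting at 0.
#' @param D_t translational diffusion (Angstrom^2/ns).
#' @param D_r rotational diffusion (1/ns, scalar).
#' @param mode optional internal mode: `list(vector = n x 3, tau = ns,
#'   rms = Angstrom)`.
#' @param n_samples Monte Carlo samples for the orientation ensemble.
#' @param noise relative noise added to I(q, tau) (0 = none).
#' @param seed RNG seed.
#' @return object of class `nse_config`.
#' @export
nse_config <- function(coords = NULL, b = NULL,
                       q = seq(0.03, 0.16, length.out = 12),
                       tau = seq(0, 40, by = 2),
                       D_t = 4.71 / 3^(1 / 3), D_r = 1.64e-3 / 3,
                       mode = NULL, n_samples = 400, noise = 0,
                       seed = NULL) {
  if (is.null(coords)) coords <- default_dimer_geometry()$coords
  if (is.null(b)) b <- rep(1, nrow(coords))
  chk(all(is.finite(b)) && length(b) == nrow(coords),
      "b must be finite, one per bead")
  chk(min(tau) >= 0, "tau grid must start at >= 0")
  chk(all(q > 0), "q must be positive")
  if (!is.null(mode)) {
    chk(nrow(mode$vector) == nrow(coords),
        "mode vector length must match coordinates")
  }
  cfg <- list(coords = coords, b = b, q = q, tau = tau, D_t = D_t, D_r = D_r,
              mode = mode, n_samples = as.integer(n_samples), noise = noise,
              seed = seed)
  class(cfg) <- "nse_config"
  cfg
}
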