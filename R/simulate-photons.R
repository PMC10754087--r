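# Photon-stream generator: inhomogeneous Poisson emission from diffusing
# molecules with triplet blinking, slow brightness bunching, antibunching and
# polarization from a hierarchical rotational process.
#
# Exactness notes. Candidate photons are drawn from a piecewise-constant
# envelope rate (diffusion occupancy at its update grid, times the maximum of
# the fluctuation factors) and thinned by the instantaneous factors. The
# two-state telegraphs (triplet, brightness) are sampled *exactly* at the
# candidate times via uniformization; the dye/local/global orientation
# hierarchy is a nested jump-renewal process whose rank-2 orientational ACF is
# exactly (A + (1-A) e^(-t/rho)) per level, so the ensemble anisotropy decay
# is exactly the cone-in-cone product. Antibunching is a renewal suppression
# 1 - exp(-dt/tau_ab) applied per molecule. Photoselection and emission use
# the same dipole realization, so the fundamental anisotropy and the
# photon-pair polarization correlations emerge from the simulated process
# rather than being imposed.

CHANNELS <- c("D_par", "D_perp", "A_par", "A_perp")

#' Simulate a confocal single-molecule photon stream
#'
#' @param config a [photon_stream_config()].
#' @return object of class `photon_stream`: a data.frame with columns
#'   `t` (macrotime, integer picoseconds stored as double), `channel`
#'   (1 = D_par, 2 = D_perp, 3 = A_par, 4 = A_perp), `source` (1 = donor
#'   excitation, 2 = acceptor excitation), `microtime` (ps; NA in cw mode),
#'   `mol` (emitter id, 0 = background) and `species` (ground-truth FRET
#'   state index, 0 = background), sorted by macrotime.
#' @export
simulate_photon_stream <- function(config) {
  validate_photon_stream_config(config)
  seed_guard(config$seed)
  cf <- config

  est <- cf$brightness * cf$occupancy * cf$duration * 1.5 +
    sum(cf$background) * cf$duration
  if (est > cf$max_photons) {
    stop("expected photon count ", format(est, digits = 3),
         " exceeds max_photons cap", call. = FALSE)
  }

  s_b <- sqrt(cf$c_b)
  b_max <- if (cf$bunching_process == "telegraph") 1 + s_b else 1 + 3 * s_b
  p_on_T <- 1 / (1 + cf$c_T)

  # geometry: lateral MDF sigma = 1, axial = kappa. The box volume is set
  # so that the *realized* mean occupancy (box-truncated MDF integral)
  # matches the configured value.
  v_eff <- (2 * pi)^1.5 * cf$kappa
  occ_of <- function(s) {
    lx <- s; lz <- cf$kappa * s
    i_box <- (sqrt(2 * pi) * (2 * stats::pnorm(lx / 2) - 1))^2 *
      sqrt(2 * pi) * cf$kappa * (2 * stats::pnorm(lz / (2 * cf$kappa)) - 1)
    cf$n_molecules * i_box / (lx^2 * lz)
  }
  lx0 <- (cf$n_molecules * v_eff / cf$occupancy / cf$kappa)^(1 / 3)
  if (cf$occupancy >= occ_of(0.1)) {
    # occupancy at (or beyond) the molecule count: molecules effectively
    # pinned at the focus center
    lx <- 0.1
  } else {
    lx <- stats::uniroot(function(s) occ_of(s) - cf$occupancy,
                         c(0.1, max(4 * lx0, 50)))$root
  }
  lz <- cf$kappa * lx
  D <- 1 / cf$tau_D # sigma^2 per s
  h <- min(cf$occupancy_update, cf$duration / 10)
  n_seg <- ceiling(cf$duration / h)

  species_of <- sample.int(nrow(cf$states), cf$n_molecules, replace = TRUE,
                           prob = cf$states$occupancy)

  per_mol <- vector("list", cf$n_molecules)
  eps <- cf$photoselection
  for (m in seq_len(cf$n_molecules)) {
    # Brownian positions at segment boundaries, periodic box; the
    # occupancy is interpolated linearly inside each segment so the
    # emission-rate ACF is smooth (a piecewise-constant rate would leave a
    # spurious correlation ramp at lags up to the update interval)
    sdh <- sqrt(2 * D * h)
    x <- cumsum(c(runif(1, -lx / 2, lx / 2), rnorm(n_seg, sd = sdh)))
    y <- cumsum(c(runif(1, -lx / 2, lx / 2), rnorm(n_seg, sd = sdh)))
    z <- cumsum(c(runif(1, -lz / 2, lz / 2), rnorm(n_seg, sd = sdh)))
    x <- x - lx * round(x / lx)
    y <- y - lx * round(y / lx)
    z <- z - lz * round(z / lz)
    omega_b <- exp(-(x^2 + y^2) / 2 - z^2 / (2 * cf$kappa^2))
    om_lo <- omega_b[-length(omega_b)]
    om_hi <- omega_b[-1]
    om_max <- pmax(om_lo, om_hi)

    env <- cf$brightness * om_max * (1 + 2 * eps) * b_max
    k <- rpois(n_seg, env * h)
    tot <- sum(k)
    if (tot == 0) {
      per_mol[[m]] <- NULL
      next
    }
    seg <- rep.int(seq_len(n_seg), k)
    frac <- runif(tot)
    tt <- (seg - 1) * h + frac * h
    om_t <- (om_lo[seg] + (om_hi[seg] - om_lo[seg]) * frac) / om_max[seg]
    acc0 <- runif(tot) < om_t
    ord0 <- order(tt[acc0])
    tt <- tt[acc0][ord0]
    tt <- tt[tt < cf$duration]

    # thin by triplet and brightness fluctuation
    acc <- rep(TRUE, length(tt))
    if (cf$c_T > 0) acc <- telegraph_at(tt, cf$tau_T, p_on_T)
    if (cf$c_b > 0) {
      if (cf$bunching_process == "telegraph") {
        up <- telegraph_at(tt, cf$tau_b, 0.5)
        bfac <- ifelse(up, 1 + s_b, 1 - s_b)
      } else {
        bfac <- pmin(pmax(1 + s_b * ou_at(tt, cf$tau_b, rnorm(length(tt))), 0),
                     b_max)
      }
      acc <- acc & (runif(length(tt)) < bfac / b_max)
    }
    tt <- tt[acc]
    if (length(tt) == 0) {
      per_mol[[m]] <- NULL
      next
    }

    # shared global rotation stream for both dyes of this molecule
    gid <- renewal_intervals(tt, cf$rho_global)
    qg <- runif_quat(max(gid))
    dip_d <- dipole_at(tt, cf, gid, qg)

    # photoselection via the donor absorption dipole (excitation along x),
    # compressed by the saturation depth eps
    fsel <- (1 - eps) + 3 * eps * dip_d$abs[, 1]^2
    sel <- runif(length(tt)) < fsel / (1 + 2 * eps)
    tt <- tt[sel]
    if (length(tt) == 0) {
      per_mol[[m]] <- NULL
      next
    }
    mu_d <- dip_d$em[sel, , drop = FALSE]
    # acceptor emission dipole: independent dye/local renewal streams on the
    # same global frame (a renewal snapshot is exact on any subset of times)
    mu_a <- dipole_at(tt, cf, gid[sel], qg)$em
    # channel assignment is per-molecule (no cross-molecule dependence), so
    # only times and channel labels need to survive the merge
    ev_m <- rep(cf$states$E[species_of[m]], length(tt))
    out_m <- if (cf$mode == "cw") {
      assign_channels_cw(tt, ev_m, mu_d, mu_a, cf)
    } else {
      assign_channels_pie(tt, ev_m, cf)
    }
    per_mol[[m]] <- list(t = out_m$t, channel = out_m$channel,
                         source = out_m$source,
                         microtime = out_m$microtime)
  }

  mids <- which(!vapply(per_mol, is.null, TRUE))
  per_mol <- per_mol[mids]
  lens <- vapply(per_mol, function(p) length(p$t), 1L)
  t_all <- unlist(lapply(per_mol, `[[`, "t"), use.names = FALSE)
  if (is.null(t_all)) t_all <- numeric(0)
  channel <- unlist(lapply(per_mol, `[[`, "channel"), use.names = FALSE)
  source <- unlist(lapply(per_mol, `[[`, "source"), use.names = FALSE)
  micro <- unlist(lapply(per_mol, `[[`, "microtime"), use.names = FALSE)
  if (is.null(channel)) channel <- source <- integer(0)
  if (is.null(micro)) micro <- numeric(0)
  mol <- rep.int(mids, lens)
  rm(per_mol)

  n <- length(t_all)
  if (n > 0) {
    ord <- order(t_all)
    t_all <- t_all[ord]
    mol <- mol[ord]
    channel <- channel[ord]
    source <- source[ord]
    micro <- micro[ord]

    keep <- antibunch_keep(t_all, mol, cf$tau_ab, runif(n))
    t_all <- t_all[keep]
    mol <- mol[keep]
    channel <- channel[keep]
    source <- source[keep]
    micro <- micro[keep]
    n <- length(t_all)
  }
  spec <- species_of[mol]

  # perpendicular-channel detection delay
  tt <- t_all + ifelse(channel %in% c(2L, 4L), cf$tau_0, 0)

  df <- data.frame(t = tt, channel = channel, source = source,
                   microtime = micro, mol = mol, species = spec)

  # background: uniform, source = 1, per-channel rates
  nb <- rpois(4, cf$background * cf$duration)
  if (sum(nb) > 0) {
    bg <- data.frame(
      # two-stage draw: R uniforms carry 32-bit granularity, too coarse
      # for nanosecond lags over a full measurement
      t = (floor(runif(sum(nb), 0, cf$duration) * 1e3) +
             runif(sum(nb))) * 1e-3,
      channel = rep.int(1:4, nb),
      source = 1L,
      microtime = if (cf$mode == "pie") {
        runif(sum(nb), 0, cf$pie_period)
      } else NA_real_,
      mol = 0L, species = 0L
    )
    df <- rbind(df, bg)
  }

  df$t <- round(df$t * 1e12) # ps ticks
  df$microtime <- round(df$microtime * 1e12)
  df <- df[order(df$t), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("photon_stream", "data.frame"),
            duration = cf$duration, config = cf)
}

# Orientation of one dye at sorted times `tt`: nested jump-renewal hierarchy
# (dye cone inside local cone inside the global frame). `gid` indexes global
# renewal intervals into the quaternion table `qg`. Returns absorption and
# emission dipoles: for r0 < 0.4 a fraction 1 - r0/0.4 of emissions use an
# isotropic independent dipole (non-collinear transition moments), which
# scales the fundamental anisotropy to r0.
dipole_at <- function(tt, cf, gid, qg) {
  n <- length(tt)
  c_d <- cap_from_amplitude(cf$A_dye)
  c_l <- cap_from_amplitude(cf$A_local)
  id_d <- renewal_intervals(tt, cf$rho_dye)
  id_l <- renewal_intervals(tt, cf$rho_local)
  nu_d <- cap_sample(max(id_d), c_d)[id_d, , drop = FALSE]
  nu_l <- cap_sample(max(id_l), c_l)[id_l, , drop = FALSE]
  w <- rotate_z_to(nu_d, nu_l)
  dir <- quat_rotate(qg[gid, , drop = FALSE], w)
  em <- dir
  p_iso <- 1 - cf$r0 / 0.4
  if (p_iso > 0) {
    iso <- runif(n) < p_iso
    n_iso <- sum(iso)
    if (n_iso > 0) {
      u <- cbind(rnorm(n_iso), rnorm(n_iso), rnorm(n_iso))
      em[iso, ] <- u / sqrt(rowSums(u^2))
    }
  }
  list(abs = dir, em = em)
}

# Detected-photon channel partition for continuous green excitation.
# Detected-count fractions follow the corrected-FRET forward model:
# F_DD : F_DA = (1 - E) : (gamma E + alpha (1 - E)).
assign_channels_cw <- function(tt, ev, mu_d, mu_a, cf) {
  n <- length(tt)
  p_dd <- (1 - ev)
  p_da <- cf$gamma_f * ev + cf$alpha * (1 - ev)
  a_band <- runif(n) < p_da / (p_dd + p_da)
  mu <- mu_d
  if (any(a_band)) mu[a_band, ] <- mu_a[a_band, , drop = FALSE]
  w_par <- mu[, 1]^2
  w_perp <- cf$G * mu[, 2]^2
  par <- runif(n) < w_par / (w_par + w_perp)
  channel <- ifelse(a_band, ifelse(par, 3L, 4L), ifelse(par, 1L, 2L))
  list(t = tt, channel = channel, source = rep(1L, n),
       microtime = rep(NA_real_, n))
}

# Pulsed interleaved excitation: red-slot acceptor photons, green-slot
# FRET partition with crosstalk and direct excitation; microtimes from the
# fluorescence lifetime; polarization from the analytic anisotropy decay
# r(m) = r0 * C(m) at the photon's microtime m.
assign_channels_pie <- function(tt, ev, cf) {
  n <- length(tt)
  half <- cf$pie_period / 2
  p_red <- (cf$gamma_f / cf$beta_f) / (1 + cf$gamma_f / cf$beta_f)
  red <- runif(n) < p_red
  # green-slot partition: direct-excitation photons are delta * F_AA extra
  # counts in the acceptor band
  p_dd <- (1 - ev)
  p_da <- cf$gamma_f * ev + cf$alpha * (1 - ev) +
    cf$delta * p_red / (1 - p_red)
  a_band <- red | (runif(n) < p_da / (p_dd + p_da))
  lt <- ifelse(a_band, cf$lifetime_a, cf$lifetime)
  micro_raw <- rexp(n, 1 / lt) %% half
  micro <- ifelse(red, half + micro_raw, micro_raw)
  # anisotropy at the emission delay
  cc <- cic_factor(micro_raw, cf$rho_dye, cf$rho_local, cf$rho_global,
                   cf$A_dye, cf$A_local)
  r <- cf$r0 * cc
  w_par <- 1 + 2 * r
  w_perp <- cf$G * (1 - r)
  par <- runif(n) < w_par / (w_par + w_perp)
  channel <- ifelse(a_band, ifelse(par, 3L, 4L), ifelse(par, 1L, 2L))
  t_q <- floor(tt / cf$pie_period) * cf$pie_period + micro
  list(t = t_q, channel = channel, source = ifelse(red, 2L, 1L),
       microtime = micro)
}

# Cone-in-cone orientational correlation factor (times in the same unit).
cic_factor <- function(t, rho_dye, rho_local, rho_global, A_dye, A_local) {
  ((1 - A_dye) * exp(-t / rho_dye) + A_dye) *
    ((1 - A_local) * exp(-t / rho_local) + A_local) *
    exp(-t / rho_global)
}

#' @export
print.photon_stream <- function(x, ...) {
  cf <- attr(x, "config")
  cat("<photon_stream> ", nrow(x), " photons over ",
      format(attr(x, "duration"), digits = 4), " s (",
      cf$mode, " mode)\n", sep = "")
  tab <- table(factor(x$channel, levels = 1:4, labels = CHANNELS))
  print(tab)
  invisible(x)
}
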