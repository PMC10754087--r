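# Single-molecule burst analysis: DeltaT burst search, route-correction
# matrix, corrected FRET efficiency / stoichiometry / anisotropy per burst,
# and conformational-substate selection.

#' Burst-search parameters
#'
#' @param delta_t maximal inter-photon gap within a burst (s).
#' @param n_min,n_max retained burst size range (photon counts).
#' @param dual_channel if TRUE, the DeltaT criterion must hold independently
#'   in both excitation-source photon subsets; the burst is the intersection
#'   of the per-source burst intervals.
#' @return object of class `burst_search_params`.
#' @export
burst_search_params <- function(delta_t = 100e-6, n_min = 35, n_max = 10000,
                                dual_channel = FALSE) {
  chk(delta_t > 0, "delta_t must be positive")
  chk(n_min > 0 && n_min <= n_max, "need 0 < n_min <= n_max")
  structure(list(delta_t = delta_t, n_min = n_min, n_max = n_max,
                 dual_channel = dual_channel),
            class = "burst_search_params")
}

#' Correction factors for FRET, stoichiometry and anisotropy
#'
#' @param alpha spectral crosstalk (donor emission in the acceptor channel).
#' @param delta direct acceptor excitation.
#' @param gamma_f detection-efficiency/quantum-yield ratio (gamma).
#' @param beta_f excitation-power/cross-section ratio (beta).
#' @param G polarization balance factor.
#' @param l1,l2 objective depolarization mixing factors.
#' @param rcm 4x4 route correction matrix applied to raw channel counts.
#' @return object of class `correction_factors`.
#' @export
correction_factors <- function(alpha = 0, delta = 0, gamma_f = 1,
                               beta_f = 1, G = 1,
                               l1 = 0.0308, l2 = 0.0368,
                               rcm = diag(4)) {
  chk(alpha >= 0 && delta >= 0, "alpha, delta must be >= 0")
  chk(gamma_f > 0 && beta_f > 0 && G > 0, "gamma, beta, G must be positive")
  chk(is.matrix(rcm) && all(dim(rcm) == 4) && all(rcm >= 0),
      "rcm must be a nonnegative 4x4 matrix")
  structure(list(alpha = alpha, delta = delta, gamma_f = gamma_f,
                 beta_f = beta_f, G = G, l1 = l1, l2 = l2, rcm = rcm),
            class = "correction_factors")
}

# maximal runs with all gaps <= delta_t; returns start/stop indices
delta_t_runs <- function(t, delta_t) {
  n <- length(t)
  if (n == 0) return(cbind(start = integer(0), stop = integer(0)))
  brk <- which(diff(t) > delta_t)
  cbind(start = c(1L, brk + 1L), stop = c(brk, n))
}

#' DeltaT burst search
#'
#' A burst is a maximal run of consecutive photons in which every
#' inter-photon gap is at most `delta_t`; bursts outside the size window
#' `[n_min, n_max]` are discarded. In dual-channel mode the search runs
#' independently on the two excitation-source subsets and the retained
#' bursts are intersections of overlapping per-source burst intervals.
#'
#' @param stream a `photon_stream` (or data.frame with `t` in ps and
#'   `source`).
#' @param params a [burst_search_params()].
#' @return data.frame of class `burst_set`: one row per burst with start/stop
#'   photon indices (into `stream`), start/stop times (ps), photon count and
#'   duration (s).
#' @export
delta_t_burst_search <- function(stream, params = burst_search_params()) {
  t <- stream$t
  chk(!is.unsorted(t), "photon stream must be sorted by macrotime")
  dt_ps <- params$delta_t * 1e12
  if (!params$dual_channel) {
    runs <- delta_t_runs(t, dt_ps)
    size <- runs[, "stop"] - runs[, "start"] + 1L
    keep <- size >= params$n_min & size <= params$n_max
    runs <- runs[keep, , drop = FALSE]
    out <- data.frame(start = runs[, "start"], stop = runs[, "stop"])
  } else {
    out_list <- list()
    idx1 <- which(stream$source == 1L)
    idx2 <- which(stream$source == 2L)
    chk(length(idx1) > 0 && length(idx2) > 0,
        "dual-channel search needs photons from both excitation sources")
    r1 <- delta_t_runs(t[idx1], dt_ps)
    r2 <- delta_t_runs(t[idx2], dt_ps)
    f1 <- (r1[, "stop"] - r1[, "start"] + 1L) >= params$n_min &
      (r1[, "stop"] - r1[, "start"] + 1L) <= params$n_max
    f2 <- (r2[, "stop"] - r2[, "start"] + 1L) >= params$n_min &
      (r2[, "stop"] - r2[, "start"] + 1L) <= params$n_max
    r1 <- r1[f1, , drop = FALSE]
    r2 <- r2[f2, , drop = FALSE]
    # interval intersection on times
    i <- 1L
    for (a in seq_len(nrow(r1))) {
      ta0 <- t[idx1[r1[a, "start"]]]
      ta1 <- t[idx1[r1[a, "stop"]]]
      for (b in seq_len(nrow(r2))) {
        tb0 <- t[idx2[r2[b, "start"]]]
        tb1 <- t[idx2[r2[b, "stop"]]]
        lo <- max(ta0, tb0)
        hi <- min(ta1, tb1)
        if (lo <= hi) {
          sel <- range(which(t >= lo & t <= hi))
          out_list[[i]] <- c(start = sel[1], stop = sel[2])
          i <- i + 1L
        }
      }
    }
    out <- if (length(out_list)) {
      as.data.frame(do.call(rbind, out_list))
    } else {
      data.frame(start = integer(0), stop = integer(0))
    }
  }
  out$t_start <- t[out$start]
  out$t_stop <- t[out$stop]
  out$n_photons <- out$stop - out$start + 1L
  out$duration <- (out$t_stop - out$t_start) * 1e-12
  class(out) <- c("burst_set", "data.frame")
  attr(out, "params") <- params
  out
}

#' Apply the route correction matrix to raw 4-channel counts
#'
#' Linear correction of the per-channel photon counts (D_par, D_perp,
#' A_par, A_perp). Negative corrected counts are clamped to zero with a
#' warning.
#'
#' @param counts numeric length-4 vector (or 4-column matrix, one row per
#'   burst) of raw counts.
#' @param rcm 4x4 route correction matrix.
#' @return corrected counts, same shape as input.
#' @export
apply_rcm <- function(counts, rcm) {
  chk(is.matrix(rcm) && all(dim(rcm) == 4), "rcm must be 4x4")
  single <- is.null(dim(counts))
  m <- if (single) matrix(counts, 1, 4) else counts
  chk(ncol(m) == 4, "counts must have 4 channels")
  out <- m %*% t(rcm)
  if (any(out < 0)) {
    warning("negative corrected counts clamped to zero")
    out[out < 0] <- 0
  }
  if (single) drop(out) else out
}

#' Corrected FRET efficiency
#'
#' E = F_c / (gamma F_DD + F_c) with
#' F_c = G F_DA - alpha F_DD - delta F_AA. Returns NaN (with an attribute
#' noting the degenerate denominator) instead of raising, so stream-scale
#' processing is uninterrupted.
#'
#' @param f_dd,f_da,f_aa detected intensities: donor emission after donor
#'   excitation, acceptor emission after donor excitation, acceptor
#'   emission after acceptor excitation. Vectorized.
#' @param cf a [correction_factors()].
#' @return numeric vector of corrected efficiencies.
#' @export
fret_efficiency <- function(f_dd, f_da, f_aa = 0, cf = correction_factors()) {
  fc <- cf$G * f_da - cf$alpha * f_dd - cf$delta * f_aa
  den <- cf$gamma_f * f_dd + fc
  out <- ifelse(den > 0, fc / den, NaN)
  out
}

#' Corrected stoichiometry
#'
#' S = (gamma F_DD + F_DA - alpha F_DD - delta F_AA) /
#'     (gamma F_DD + F_DA - alpha F_DD - delta F_AA + beta F_AA).
#'
#' @inheritParams fret_efficiency
#' @return numeric vector of stoichiometries (NaN on zero denominator).
#' @export
stoichiometry <- function(f_dd, f_da, f_aa = 0, cf = correction_factors()) {
  num <- cf$gamma_f * f_dd + f_da - cf$alpha * f_dd - cf$delta * f_aa
  den <- num + cf$beta_f * f_aa
  ifelse(den != 0, num / den, NaN)
}

#' Polarization-corrected anisotropy from intensities
#'
#' r = (G F_par - F_perp) / ((1 - 3 l2) G F_par + (2 - 3 l1) F_perp).
#'
#' @param f_par,f_perp parallel / perpendicular detected intensities.
#' @param cf a [correction_factors()].
#' @return numeric vector (NaN on zero denominator).
#' @export
burst_anisotropy <- function(f_par, f_perp, cf = correction_factors()) {
  num <- cf$G * f_par - f_perp
  den <- (1 - 3 * cf$l2) * cf$G * f_par + (2 - 3 * cf$l1) * f_perp
  ifelse(den != 0, num / den, NaN)
}

#' Per-burst channel counts and corrected features
#'
#' Tabulates per-burst photon counts by detection channel and excitation
#' source, applies the route correction matrix, and computes corrected
#' FRET efficiency, stoichiometry and (acceptor-excitation) anisotropy.
#'
#' @param stream a `photon_stream`.
#' @param bursts a `burst_set` from [delta_t_burst_search()].
#' @param cf a [correction_factors()].
#' @return the burst table with columns `f_dd`, `f_da`, `f_aa`, `f_par`,
#'   `f_perp`, `E`, `S`, `r` (and `species`, the majority ground-truth
#'   label, when the stream carries one).
#' @export
burst_features <- function(stream, bursts, cf = correction_factors()) {
  n <- nrow(bursts)
  cnt <- matrix(0, n, 4)
  f_aa <- f_par <- f_perp <- numeric(n)
  spec <- integer(n)
  for (i in seq_len(n)) {
    idx <- bursts$start[i]:bursts$stop[i]
    ch <- stream$channel[idx]
    src <- stream$source[idx]
    cnt[i, ] <- tabulate(ch[src == 1L], 4)
    f_aa[i] <- sum(src == 2L & ch >= 3L)
    # anisotropy from direct acceptor excitation when available, else all
    pol_src <- if (any(src == 2L)) 2L else 1L
    f_par[i] <- sum(src == pol_src & ch %in% c(1L, 3L))
    f_perp[i] <- sum(src == pol_src & ch %in% c(2L, 4L))
    if (!is.null(stream$species)) {
      tt <- table(stream$species[idx])
      spec[i] <- as.integer(names(tt)[which.max(tt)])
    }
  }
  cnt <- apply_rcm(cnt, cf$rcm)
  bursts$f_dd <- cnt[, 1] + cnt[, 2]
  bursts$f_da <- cnt[, 3] + cnt[, 4]
  bursts$f_aa <- f_aa
  bursts$f_par <- f_par
  bursts$f_perp <- f_perp
  bursts$E <- fret_efficiency(bursts$f_dd, bursts$f_da, bursts$f_aa, cf)
  bursts$S <- stoichiometry(bursts$f_dd, bursts$f_da, bursts$f_aa, cf)
  bursts$r <- burst_anisotropy(f_par, f_perp, cf)
  if (!is.null(stream$species)) bursts$species <- spec
  bursts
}

#' Select bursts belonging to a conformational substate
#'
#' Keeps bursts whose corrected FRET efficiency (and optionally
#' stoichiometry) lies inside closed intervals. Order-preserving.
#'
#' @param bursts burst table with feature columns (see [burst_features()]).
#' @param e_range closed interval for E.
#' @param s_range optional closed interval for S.
#' @return the selected subset of `bursts`.
#' @export
select_substate <- function(bursts, e_range, s_range = NULL) {
  chk(length(e_range) == 2 && e_range[1] <= e_range[2],
      "e_range must be an ordered interval")
  keep <- !is.na(bursts$E) & bursts$E >= e_range[1] & bursts$E <= e_range[2]
  if (!is.null(s_range)) {
    chk(length(s_range) == 2 && s_range[1] <= s_range[2],
        "s_range must be an ordered interval")
    keep <- keep & !is.na(bursts$S) & bursts$S >= s_range[1] &
      bursts$S <= s_range[2]
  }
  bursts[keep, , drop = FALSE]
}
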