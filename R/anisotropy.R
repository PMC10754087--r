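# Subpopulation time-resolved anisotropy: polarized microtime histograms
# from selected bursts, binwise anisotropy with Poisson error propagation,
# and the cone-in-cone / multi-exponential rotation fits.

#' Polarized microtime histograms from selected bursts
#'
#' Histograms the microtimes of all photons inside the given bursts into
#' parallel and perpendicular decays, for one excitation source. Counts are
#' conserved: the two histograms sum to the number of selected photons of
#' that source. Times are reported in nanoseconds from the exciting pulse.
#'
#' @param stream a `photon_stream` in PIE mode.
#' @param bursts a `burst_set` (typically substate-selected).
#' @param source "A" (acceptor/red pulse, default: acceptor anisotropy on
#'   direct excitation) or "D" (donor/green pulse).
#' @param bin_width microtime bin width (ns).
#' @param label substate label attached to the decay.
#' @return a `polarized_decay` (see [simulate_polarized_decay()]).
#' @export
decay_from_bursts <- function(stream, bursts, source = c("A", "D"),
                              bin_width = 0.128, label = NULL) {
  source <- match.arg(source)
  chk(nrow(bursts) > 0, "empty substate: no bursts selected")
  cf <- attr(stream, "config")
  chk(!is.null(stream$microtime) && any(is.finite(stream$microtime)),
      "stream carries no microtimes (need PIE mode)")
  period_ns <- (cf$pie_period %||% 50e-9) * 1e9
  half <- period_ns / 2
  src <- if (source == "A") 2L else 1L

  idx <- unlist(lapply(seq_len(nrow(bursts)), function(i) {
    bursts$start[i]:bursts$stop[i]
  }))
  idx <- idx[stream$source[idx] == src & is.finite(stream$microtime[idx])]
  chk(length(idx) > 0, "no photons of requested source in substate")
  micro <- stream$microtime[idx] * 1e-3 # ps -> ns
  if (src == 2L) micro <- micro - half
  ch <- stream$channel[idx]
  par <- ch %in% c(1L, 3L)

  edges <- seq(0, half, by = bin_width)
  if (edges[length(edges)] < half) edges <- c(edges, half)
  cut_idx <- findInterval(pmin(pmax(micro, 0), half - 1e-9), edges)
  nb <- length(edges) - 1
  f_par <- tabulate(cut_idx[par], nb)
  f_perp <- tabulate(cut_idx[!par], nb)
  structure(list(time = (edges[-1] + edges[-(nb + 1)]) / 2,
                 f_par = f_par, f_perp = f_perp, bin_width = bin_width,
                 label = label %||% "substate", source = source),
            class = "polarized_decay")
}

#' Time-resolved anisotropy from a polarized decay
#'
#' Applies the polarization-corrected anisotropy formula per microtime bin:
#' r(t) = (G F_par - F_perp) / ((1 - 3 l2) G F_par + (2 - 3 l1) F_perp),
#' masking bins without counts. Per-bin errors are first-order Poisson
#' propagation through the formula.
#'
#' @param pd a `polarized_decay`.
#' @param cf a [correction_factors()] supplying G, l1, l2.
#' @return data.frame of class `anisotropy_curve` with `time` (ns), `r`,
#'   `err`.
#' @export
anisotropy_decay <- function(pd, cf = correction_factors()) {
  p <- pd$f_par
  q <- pd$f_perp
  g <- cf$G
  a <- 1 - 3 * cf$l2
  b <- 2 - 3 * cf$l1
  num <- g * p - q
  den <- a * g * p + b * q
  r <- ifelse(p + q > 0 & den != 0, num / den, NA_real_)
  drdp <- g * (den - a * num) / den^2
  drdq <- (-den - b * num) / den^2
  err <- ifelse(is.finite(r), sqrt(drdp^2 * p + drdq^2 * q), NA_real_)
  out <- data.frame(time = pd$time, r = r, err = err, n = p + q)
  class(out) <- c("anisotropy_curve", "data.frame")
  attr(out, "label") <- pd$label
  out
}

#' Evaluate the cone-in-cone anisotropy model
#'
#' r(t) = r0 ((1 - A_dye) e^(-t/rho_dye) + A_dye)
#'           ((1 - A_local) e^(-t/rho_local) + A_local) e^(-t/rho_global)
#'
#' @param t times (ns).
#' @param r0 fundamental anisotropy.
#' @param A_dye,rho_dye dye-wobble cone amplitude and time (ns).
#' @param A_local,rho_local local-motion cone amplitude and time (ns).
#' @param rho_global global rotation time (ns).
#' @return model values.
#' @export
cone_in_cone <- function(t, r0, A_dye, rho_dye, A_local, rho_local,
                         rho_global) {
  r0 * cic_factor(t, rho_dye, rho_local, rho_global, A_dye, A_local)
}

#' Global cone-in-cone fit over FRET subpopulations
#'
#' Fits [cone_in_cone()] to one anisotropy curve per population with the
#' dye and global rotation times (and by default the dye cone amplitude)
#' shared globally across populations; local time and amplitude are
#' population-specific. r0 is held fixed. The fit starts after the
#' instrument-response region (`fit_start`), so no reconvolution is
#' performed.
#'
#' @param curves list of `anisotropy_curve` objects (one per population).
#' @param r0 fixed fundamental anisotropy.
#' @param fit_start,fit_end fitted time window (ns); `fit_end = NULL` uses
#'   the full curve.
#' @param share character vector from `c("rho_dye", "rho_global",
#'   "A_dye")`: parameters shared across populations.
#' @param rho_local_bounds bounds (ns) preventing exchange of the local
#'   time with the dye time.
#' @param min_counts bins with fewer total photons are excluded: at low
#'   counts the binwise anisotropy is a ratio of small numbers and its
#'   Poisson-estimated weight correlates with its own noise, which biases
#'   a weighted fit.
#' @return object of class `cic_fit`: shared estimates with standard
#'   errors, per-population table, and fit diagnostics.
#' @export
fit_cone_in_cone <- function(curves, r0 = 0.4, fit_start = 0.5,
                             fit_end = NULL,
                             share = c("rho_dye", "rho_global", "A_dye"),
                             rho_local_bounds = c(0.1, 20),
                             min_counts = 100) {
  if (inherits(curves, "anisotropy_curve")) curves <- list(curves)
  np <- length(curves)
  chk(np >= 1, "need at least one curve")
  dat <- lapply(curves, function(cu) {
    sel <- cu$time >= fit_start & is.finite(cu$r) & is.finite(cu$err) &
      cu$err > 0
    if (!is.null(fit_end)) sel <- sel & cu$time <= fit_end
    if (!is.null(cu$n)) sel <- sel & cu$n >= min_counts
    list(t = cu$time[sel], r = cu$r[sel], w = 1 / cu$err[sel])
  })
  chk(all(vapply(dat, function(d) length(d$t), 1L) >= 6),
      "too few usable anisotropy bins")

  sh <- list(rho_dye = "rho_dye" %in% share,
             rho_global = "rho_global" %in% share,
             A_dye = "A_dye" %in% share)
  n_of <- function(flag) if (flag) 1L else np
  lens <- c(rho_dye = n_of(sh$rho_dye), rho_global = n_of(sh$rho_global),
            A_dye = n_of(sh$A_dye), A_local = np, rho_local = np)
  idx <- split(seq_len(sum(lens)), rep(names(lens), lens))
  pick <- function(v, p, flags) if (length(v) == 1) v else v[p]

  unpack <- function(par) {
    list(rho_dye = exp(par[idx$rho_dye]),
         rho_global = exp(par[idx$rho_global]),
         A_dye = par[idx$A_dye],
         A_local = par[idx$A_local],
         rho_local = exp(par[idx$rho_local]))
  }
  resid_fn <- function(par) {
    u <- unpack(par)
    unlist(lapply(seq_len(np), function(p) {
      m <- cone_in_cone(dat[[p]]$t, r0,
                        pick(u$A_dye, p), pick(u$rho_dye, p),
                        u$A_local[p], u$rho_local[p],
                        pick(u$rho_global, p))
      (dat[[p]]$r - m) * dat[[p]]$w
    }))
  }
  mk_start <- function(rg) {
    par <- numeric(sum(lens))
    par[idx$rho_dye] <- log(0.4)
    par[idx$rho_global] <- log(rg)
    par[idx$A_dye] <- 0.6
    par[idx$A_local] <- 0.5
    par[idx$rho_local] <- log(3)
    par
  }
  lower <- numeric(sum(lens))
  upper <- numeric(sum(lens))
  lower[idx$rho_dye] <- log(0.01); upper[idx$rho_dye] <- log(5)
  lower[idx$rho_global] <- log(1); upper[idx$rho_global] <- log(1e4)
  lower[idx$A_dye] <- 0; upper[idx$A_dye] <- 1
  lower[idx$A_local] <- 0; upper[idx$A_local] <- 1
  lower[idx$rho_local] <- log(rho_local_bounds[1])
  upper[idx$rho_local] <- log(rho_local_bounds[2])
  fit <- lm_multistart(resid_fn, lapply(c(10, 30, 60, 150), mk_start),
                       lower = lower, upper = upper)
  u <- unpack(fit$par)
  se <- lm_se(fit)
  se_of <- function(nm, logscale = TRUE) {
    v <- se[idx[[nm]]]
    if (logscale) v * exp(fit$par[idx[[nm]]]) else v
  }
  per_pop <- data.frame(
    A_local = u$A_local, rho_local = u$rho_local,
    rho_local_se = se_of("rho_local"),
    label = vapply(curves, function(cu) attr(cu, "label") %||% "", "")
  )
  yobs <- unlist(lapply(dat, `[[`, "r"))
  yhat <- yobs - unlist(lapply(seq_len(np), function(p) {
    dat[[p]]$r - cone_in_cone(dat[[p]]$t, r0, pick(u$A_dye, p),
                              pick(u$rho_dye, p), u$A_local[p],
                              u$rho_local[p], pick(u$rho_global, p))
  }))
  structure(list(r0 = r0, rho_dye = u$rho_dye,
                 rho_dye_se = se_of("rho_dye"),
                 rho_global = u$rho_global,
                 rho_global_se = se_of("rho_global"),
                 A_dye = u$A_dye, A_dye_se = se_of("A_dye", FALSE),
                 per_pop = per_pop, share = share,
                 r_squared = r_squared(yobs, yhat),
                 deviance = fit$deviance, fit = fit),
            class = "cic_fit")
}

#' @export
print.cic_fit <- function(x, ...) {
  cat("<cic_fit> r0 = ", x$r0, " (fixed)\n",
      "  rho_dye    = ", format(x$rho_dye, digits = 3), " +/- ",
      format(x$rho_dye_se, digits = 2), " ns",
      if ("rho_dye" %in% x$share) " (shared)", "\n",
      "  rho_global = ", format(x$rho_global, digits = 3), " +/- ",
      format(x$rho_global_se, digits = 2), " ns",
      if ("rho_global" %in% x$share) " (shared)", "\n",
      "  A_dye      = ", format(x$A_dye, digits = 3), "\n", sep = "")
  print(x$per_pop, digits = 3)
  invisible(x)
}

#' @export
coef.cic_fit <- function(object, ...) {
  c(rho_dye = object$rho_dye, rho_global = object$rho_global,
    A_dye = object$A_dye)
}

#' Multi-exponential anisotropy fit
#'
#' r(t) = r0 sum_i A_i exp(-t/rho_i) with 1 to 3 rotational components;
#' reports the Bayesian information criterion for model comparison.
#'
#' @param curve an `anisotropy_curve`.
#' @param n_comp number of rotational components (1..3).
#' @param r0 fundamental anisotropy scale.
#' @param fit_start start of the fitted window (ns).
#' @return list with `rho` (ns), `amplitude`, `bic`, `r_squared`.
#' @export
fit_multiexp <- function(curve, n_comp = 1, r0 = 0.4, fit_start = 0.5) {
  chk(n_comp %in% 1:3, "n_comp must be 1, 2 or 3")
  sel <- curve$time >= fit_start & is.finite(curve$r) & is.finite(curve$err) &
    curve$err > 0
  t <- curve$time[sel]
  y <- curve$r[sel] / r0
  w <- 1 / (curve$err[sel] / r0)
  fit <- fit_exp_sum(t, y, n_comp, weights = w,
                     t_range = c(max(min(t), 0.05), max(t)))
  n <- length(t)
  k <- 2 * n_comp
  bic <- n * log(fit$deviance / n) + k * log(n)
  list(rho = fit$tau, amplitude = fit$amplitude, bic = bic,
       r_squared = r_squared(y, y - fit$fit$fvec / w))
}
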