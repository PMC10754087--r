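# End-to-end orchestration: fluorescence run (simulate/load -> bursts ->
# substate -> correlations -> global nsFCS fit), neutron run (I(q,tau) fits
# vs rigid-body/mode models; S(q,omega) global fit), and the two-sample
# state comparison.

#' Run the fluorescence pipeline on one or more photon streams
#'
#' For each replica: simulate (or take) a photon stream, optionally select
#' a FRET substate via burst search, correlate the three channel pairs on
#' the linear nanosecond grid, and fit the bunching/antibunching model
#' globally. Reports the per-replica and mean bunching times.
#'
#' @param config a `photon_stream_config`; its `seed` seeds replica 1,
#'   replica k uses `seed + k - 1`.
#' @param n_replicas number of independent streams.
#' @param e_range optional FRET substate selection interval; NULL
#'   correlates the full stream.
#' @param burst_params a [burst_search_params()] used when `e_range` is
#'   given.
#' @param cf a [correction_factors()] for burst features; defaults to the
#'   generator's own correction factors.
#' @param edges linear lag grid (s).
#' @param streams optional list of pre-simulated/loaded `photon_stream`
#'   objects (overrides simulation).
#' @param fix_triplet determine the effective triplet envelope of each
#'   stream from its microsecond-range correlation ([triplet_envelope()])
#'   and fix it in the nanosecond fit, mirroring the "beforehand
#'   determined" triplet workflow.
#' @param dip_guard width (s) of the antibunching-dip region excluded from
#'   the same-band (D x D, A x A) curves: their crossed-polarization dips
#'   carry dye/local depolarization beyond the single-exponential lifetime
#'   term of the nanosecond model. 0 disables the guard.
#' @return object of class `fluorescence_run`: per-replica fits, `tau_b`
#'   vector (s), mean and SD.
#' @export
run_fluorescence <- function(config, n_replicas = 6, e_range = NULL,
                             burst_params = burst_search_params(),
                             cf = NULL, edges = lag_grid_linear(),
                             streams = NULL, fix_triplet = TRUE,
                             dip_guard = 12e-9) {
  simulate_k <- NULL
  if (is.null(streams)) {
    chk(!is.null(config$seed), "config needs a seed for reproducible runs")
    # streams are simulated one at a time and discarded after fitting to
    # keep the peak memory at a single measurement's worth
    simulate_k <- function(k) {
      cfg <- config
      cfg$seed <- config$seed + k - 1
      simulate_photon_stream(cfg)
    }
    streams <- vector("list", n_replicas)
  }
  n_rep <- length(streams)
  fit_one <- function(s) {
    bursts <- NULL
    if (!is.null(e_range)) {
      bs <- delta_t_burst_search(s, burst_params)
      bs <- burst_features(s, bs, cf)
      bursts <- select_substate(bs, e_range)
      chk(nrow(bursts) > 0, "substate selection removed all bursts")
    }
    curves <- lapply(c("DxD", "AxA", "AxD"), function(p) {
      correlate(s, p, edges, bursts = bursts)
    })
    names(curves) <- c("DxD", "AxA", "AxD")
    if (dip_guard > 0) {
      for (i in c("DxD", "AxA")) {
        curves[[i]]$err[abs(curves[[i]]$lag - 3e-9) < dip_guard] <- Inf
      }
    }
    trip <- if (fix_triplet) triplet_envelope(s, bursts = bursts) else NULL
    fit_ns(curves, triplet = trip)
  }
  fits <- vector("list", n_rep)
  for (k in seq_len(n_rep)) {
    s <- if (is.null(simulate_k)) streams[[k]] else simulate_k(k)
    if (is.null(cf)) {
      g <- attr(s, "config")
      cf <- correction_factors(alpha = g$alpha, delta = g$delta,
                               gamma_f = g$gamma_f, beta_f = g$beta_f,
                               G = g$G)
    }
    fits[[k]] <- fit_one(s)
    rm(s)
    gc(FALSE)
  }
  tau_b <- vapply(fits, function(f) f$tau_b, 1)
  structure(list(fits = fits, tau_b = tau_b,
                 tau_b_mean = mean(tau_b), tau_b_sd = sd(tau_b),
                 e_range = e_range, n_replicas = n_rep,
                 seed = config$seed),
            class = "fluorescence_run")
}

#' Determine the effective triplet envelope of a stream
#'
#' Fits the logarithmic FCS model on the microsecond-to-millisecond lag
#' range (where the nanosecond bunching has fully decayed) to measure the
#' effective triplet contrast and relaxation time of the measured
#' correlation, for use as a fixed envelope in the nanosecond fit
#' ("beforehand determined" triplet parameters).
#'
#' @param stream a `photon_stream`.
#' @param fit_range lag window (s); the lower edge must sit well above the
#'   bunching time.
#' @param bursts optional `burst_set`: measure the envelope on the same
#'   (substate-selected) photon set that the nanosecond curves use -- the
#'   effective triplet contrast depends on the selection.
#' @return `list(c_T =, tau_T =)`, or NULL when no triplet contrast is
#'   detected.
#' @export
triplet_envelope <- function(stream, fit_range = c(1e-6, 1.2e-5),
                             tau_T_bounds = c(5e-7, 8e-6), bursts = NULL) {
  cu <- correlate(stream, "AxD",
                  edges = lag_grid_log(fit_range[1] * 0.8,
                                       fit_range[2] * 1.25, 24),
                  branch = "pq", bursts = bursts)
  sel <- cu$lag >= fit_range[1] & cu$lag <= fit_range[2] &
    is.finite(cu$G) & cu$npairs > 0
  lag <- cu$lag[sel]
  g <- cu$G[sel]
  w <- 1 / pmax(cu$err[sel], 1e-12)
  if (length(lag) < 6) return(NULL)
  # The window sits above the nanosecond bunching (fully decayed) and below
  # the diffusion decay (~1% variation, absorbed into the envelope), so a
  # bare multiplicative scale x triplet model suffices; bounding the
  # triplet time to its physical range keeps it off slower structure.
  resid <- function(p) (g - p[1] * (1 + p[2] * exp(-lag / exp(p[3])))) * w
  fit <- tryCatch(
    lm_multistart(resid,
                  list(c(min(g), 0.08, log(2.5e-6)),
                       c(min(g), 0.02, log(1e-6))),
                  lower = c(1e-3, 0, log(tau_T_bounds[1])),
                  upper = c(Inf, 1, log(tau_T_bounds[2]))),
    error = function(e) NULL)
  if (is.null(fit) || fit$par[2] < 1e-4) return(NULL)
  list(c_T = fit$par[2], tau_T = exp(fit$par[3]))
}

#' @export
print.fluorescence_run <- function(x, ...) {
  cat("<fluorescence_run> ", x$n_replicas, " replicas",
      if (!is.null(x$e_range)) {
        paste0(", substate E in [", x$e_range[1], ", ", x$e_range[2], "]")
      },
      "\n  tau_b = ", paste(format(x$tau_b * 1e9, digits = 4),
                            collapse = ", "), " ns",
      "\n  mean ", format(x$tau_b_mean * 1e9, digits = 4), " +/- ",
      format(x$tau_b_sd * 1e9, digits = 3), " ns (SD)\n", sep = "")
  invisible(x)
}

#' Run the neutron pipeline
#'
#' Simulates (or takes) spin-echo and backscattering data, extracts
#' D_eff(q) from the initial decays, overlays the rigid-body (optionally
#' oligomer-rescaled) model, computes the combined PCA-mode amplitude
#' function when modes are supplied, and runs the global backscattering
#' fit.
#'
#' @param nse a [nse_config()] or a precomputed `isf`.
#' @param qens a [qens_config()] or precomputed `qens_spectra` (NULL skips
#'   the backscattering stage).
#' @param modes optional `pca_model` for the amplitude-function overlay.
#' @param n_dimers oligomer rescaling factor applied to the rigid-body
#'   overlay (1 = none).
#' @param tau_max,i_min initial-decay cuts passed to
#'   [fit_initial_decay()].
#' @return object of class `neutron_run` with elements `deff_exp`,
#'   `deff_rigid`, `aq`, `nbs`, and the cut bookkeeping per q.
#' @export
run_neutron <- function(nse, qens = NULL, modes = NULL, n_dimers = 1,
                        tau_max = 30, i_min = 0.3) {
  isf <- if (inherits(nse, "isf")) nse else simulate_nse(nse)
  deff_exp <- fit_initial_decay(isf, tau_max = tau_max, i_min = i_min)
  cfg <- if (inherits(nse, "nse_config")) nse else NULL
  deff_rigid <- NULL
  if (!is.null(cfg)) {
    sc <- oligomer_rescale(cfg$D_t, cfg$D_r, n_dimers)
    deff_rigid <- rigid_body_deff(
      list(coords = cfg$coords, b = cfg$b, D_t = sc$D_t, D_r = sc$D_r),
      deff_exp$q)
  }
  aq <- if (!is.null(modes)) {
    amplitude_function(modes, q_grid = deff_exp$q)
  }
  nbs <- NULL
  if (!is.null(qens)) {
    sp <- if (inherits(qens, "qens_spectra")) qens else simulate_qens(qens)
    nbs <- nbs_fit(sp)
  }
  structure(list(deff_exp = deff_exp, deff_rigid = deff_rigid, aq = aq,
                 nbs = nbs,
                 cuts = data.frame(q = deff_exp$q, n_used = deff_exp$n_used,
                                   tau_max = tau_max, i_min = i_min)),
            class = "neutron_run")
}

#' @export
print.neutron_run <- function(x, ...) {
  print(x$deff_exp)
  if (!is.null(x$deff_rigid)) print(x$deff_rigid)
  if (!is.null(x$nbs)) print(x$nbs)
  invisible(x)
}

#' Two-sample comparison of bunching times between states
#'
#' Student's t-test (equal variance by default; Welch selectable) on two
#' groups of per-measurement correlation times.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param var_equal equal-variance Student's test (TRUE) or Welch (FALSE).
#' @param alpha significance level for the flag.
#' @return object of class `state_comparison`: t statistic, two-sided
#'   p-value, significance flag, group summaries.
#' @export
compare_states <- function(group_a, group_b, var_equal = TRUE,
                           alpha = 0.05) {
  chk(length(group_a) >= 2 && length(group_b) >= 2,
      "need at least 2 values per group")
  tt <- t.test(group_a, group_b, var.equal = var_equal)
  structure(list(t = unname(tt$statistic), p_value = tt$p.value,
                 significant = tt$p.value < alpha, alpha = alpha,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b),
                 var_equal = var_equal),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("<state_comparison> t = ", format(x$t, digits = 4), ", p = ",
      format(x$p_value, digits = 4),
      if (x$significant) paste0(" (significant at ", x$alpha, ")") else
        " (not significant)",
      "\n  group means: ", format(x$mean_a, digits = 4), " (n=", x$n_a,
      ") vs ", format(x$mean_b, digits = 4), " (n=", x$n_b, ")\n",
      sep = "")
  invisible(x)
}
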