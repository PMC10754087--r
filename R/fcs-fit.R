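# Global nsFCS and full-FCS model fits.
#
# Linear nanosecond window:
#   G(tau) = a (1 - c_ab exp(-|tau - tau0|/tau_ab))
#              (1 + c_b  exp(-|tau - tau0|/tau_b))
# with the bunching time tau_b (and the channel delay tau0) shared globally
# across the D x D, A x A and A x D curves.
#
# Logarithmic window (ps to s):
#   G(tau) = n (1 - c_ab e^(-tau/tau_ab)) (1 + c_b e^(-tau/tau_b))
#              (1 + c_T e^(-tau/tau_T)) /
#              ((1 + tau/tau_D) sqrt(1 + tau/(kappa^2 tau_D)))

#' Evaluate the linear nsFCS model
#'
#' @param lag lag times (s).
#' @param a,c_ab,tau_ab,c_b,tau_b,tau_0 model parameters (times in s).
#' @return model values.
#' @export
ns_model <- function(lag, a, c_ab, tau_ab, c_b, tau_b, tau_0 = 0) {
  d <- abs(lag - tau_0)
  a * (1 - c_ab * exp(-d / tau_ab)) * (1 + c_b * exp(-d / tau_b))
}

#' Global fit of the nsFCS bunching/antibunching model
#'
#' Weighted Levenberg-Marquardt fit of [ns_model()] to several correlation
#' curves with the bunching time `tau_b` (and channel delay `tau_0`) shared
#' globally; per-curve scale `a`, antibunching contrast/time and bunching
#' contrast. Multi-start over bunching-time decades (10 ns to 1 us) guards
#' against local minima.
#'
#' @param curves list of `correlation_curve` objects on a common linear
#'   grid (e.g. the D x D, A x A, A x D nsFCS curves).
#' @param share_tau0 fit one global channel delay; by default each curve
#'   gets its own tau_0 (different detector pairings have different net
#'   delays).
#' @param tau_b_starts bunching-time start values (s).
#' @param triplet optional triplet envelope `list(tau_T =, c_T =)` (times
#'   in s) multiplying the model as (1 + c_T exp(-|tau - tau0|/tau_T)).
#'   Triplet kinetics are slower than the nanosecond window but tilt it
#'   measurably; with the relaxation time fixed to a beforehand-determined
#'   value the envelope amplitude is well separated from the bunching term
#'   and is fitted per curve when `c_T` is NULL (the measured contrast is
#'   diluted by background and molecule-number statistics, so fitting it
#'   is preferred over fixing the molecular value).
#' @return object of class `nsfcs_fit` with elements `tau_b`, `tau_b_se`,
#'   `tau_0`, `per_curve` (data.frame of a, c_ab, tau_ab, c_b), `r_squared`
#'   and the underlying `nls.lm` fit.
#' @export
fit_ns <- function(curves, share_tau0 = FALSE,
                   tau_b_starts = c(2e-8, 5e-8, 1.5e-7, 4e-7, 1e-6),
                   triplet = NULL) {
  if (inherits(curves, "correlation_curve")) curves <- list(curves)
  nc <- length(curves)
  chk(nc >= 1, "need at least one curve")
  lag <- lapply(curves, function(cu) cu$lag)
  gv <- lapply(curves, function(cu) cu$G)
  wt <- lapply(curves, function(cu) 1 / pmax(cu$err, 1e-12))
  ok <- lapply(seq_len(nc), function(i) is.finite(gv[[i]]) & is.finite(wt[[i]]))

  fit_trip <- !is.null(triplet) && is.null(triplet$c_T)
  npc <- if (fit_trip) 5 else 4
  nt0 <- if (share_tau0) 1L else nc
  # parameters: log(tau_b), tau_0 (one value, or one per curve), then per
  # curve a, c_ab, log(tau_ab), c_b (and the triplet-envelope contrast c_T
  # when it is being fitted)
  unpack <- function(p) {
    nm <- c("a", "c_ab", "ltau_ab", "c_b", if (fit_trip) "c_T")
    list(tau_b = exp(p[1]), tau_0 = rep_len(p[1 + seq_len(nt0)], nc),
         pc = matrix(p[-seq_len(1 + nt0)], nc, npc, byrow = TRUE,
                     dimnames = list(NULL, nm)))
  }
  trip_fac <- function(lag_i, tau_0, c_t) {
    if (is.null(triplet)) return(1)
    1 + c_t * exp(-abs(lag_i - tau_0) / triplet$tau_T)
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    unlist(lapply(seq_len(nc), function(i) {
      li <- lag[[i]][ok[[i]]]
      ct <- if (fit_trip) u$pc[i, "c_T"] else triplet$c_T
      m <- ns_model(li, u$pc[i, "a"], u$pc[i, "c_ab"],
                    exp(u$pc[i, "ltau_ab"]), u$pc[i, "c_b"], u$tau_b,
                    u$tau_0[i]) * trip_fac(li, u$tau_0[i], ct)
      (gv[[i]][ok[[i]]] - m) * wt[[i]][ok[[i]]]
    }))
  }
  a0 <- vapply(seq_len(nc), function(i) {
    stats::median(gv[[i]][ok[[i]]], na.rm = TRUE)
  }, 1)
  starts <- lapply(tau_b_starts, function(tb) {
    pc0 <- cbind(a0, 0.3, log(3e-9), 0.2)
    if (fit_trip) pc0 <- cbind(pc0, 0.1)
    c(log(tb), rep(0, nt0), as.vector(t(pc0)))
  })
  # the antibunching time is the fluorescence-lifetime dip; common dyes
  # have lifetimes of 1-6 ns, and bounding it there keeps the term from
  # trading against the bunching component on noisy curves
  pc_lo <- c(1e-8, 0, log(1e-9), 0)
  pc_hi <- c(Inf, 1.5, log(6e-9), 3)
  if (fit_trip) {
    pc_lo <- c(pc_lo, 0)
    pc_hi <- c(pc_hi, 1)
  }
  lower <- c(log(1e-9), rep(-5e-8, nt0), rep(pc_lo, nc))
  upper <- c(log(1e-5), rep(5e-8, nt0), rep(pc_hi, nc))
  fit <- lm_multistart(resid_fn, starts, lower = lower, upper = upper)
  u <- unpack(fit$par)
  se <- lm_se(fit)
  pc <- data.frame(a = u$pc[, "a"], c_ab = u$pc[, "c_ab"],
                   tau_ab = exp(u$pc[, "ltau_ab"]), c_b = u$pc[, "c_b"])
  if (fit_trip) pc$c_T <- u$pc[, "c_T"]
  nm <- names(curves) %||%
    vapply(curves, function(cu) attr(cu, "pair") %||% "curve", "")
  rownames(pc) <- make.unique(nm)
  yhat <- unlist(lapply(seq_len(nc), function(i) {
    li <- lag[[i]][ok[[i]]]
    ct <- if (fit_trip) pc$c_T[i] else triplet$c_T
    ns_model(li, pc$a[i], pc$c_ab[i], pc$tau_ab[i],
             pc$c_b[i], u$tau_b, u$tau_0[i]) * trip_fac(li, u$tau_0[i], ct)
  }))
  yobs <- unlist(lapply(seq_len(nc), function(i) gv[[i]][ok[[i]]]))
  structure(list(tau_b = u$tau_b, tau_b_se = u$tau_b * se[1],
                 tau_0 = u$tau_0, share_tau0 = share_tau0, per_curve = pc,
                 r_squared = r_squared(yobs, yhat),
                 deviance = fit$deviance, fit = fit),
            class = "nsfcs_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nsfcs_fit <- function(x, ...) {
  cat("<nsfcs_fit> global bunching time tau_b = ",
      format(x$tau_b * 1e9, digits = 4), " +/- ",
      format(x$tau_b_se * 1e9, digits = 2), " ns (tau_0 = ",
      paste(format(unique(x$tau_0) * 1e9, digits = 3), collapse = "/"),
      " ns, R^2 = ",
      format(x$r_squared, digits = 3), ")\n", sep = "")
  print(x$per_curve, digits = 3)
  invisible(x)
}

#' @export
coef.nsfcs_fit <- function(object, ...) {
  c(tau_b = object$tau_b, tau_0 = mean(object$tau_0))
}

#' Evaluate the logarithmic full-FCS model
#'
#' @param lag lag times (s).
#' @param n scale (contains mean intensity, background and molecule number).
#' @param c_ab,tau_ab,c_b,tau_b,c_T,tau_T antibunching, bunching and
#'   triplet contrasts and times (s).
#' @param tau_D diffusion time (s); `kappa` the focal eccentricity.
#' @return model values.
#' @export
log_model <- function(lag, n, c_ab, tau_ab, c_b, tau_b, c_T, tau_T,
                      tau_D, kappa) {
  n * (1 - c_ab * exp(-lag / tau_ab)) * (1 + c_b * exp(-lag / tau_b)) *
    (1 + c_T * exp(-lag / tau_T)) /
    ((1 + lag / tau_D) * sqrt(1 + lag / (kappa^2 * tau_D)))
}

#' Fit the full logarithmic FCS model
#'
#' Weighted fit of [log_model()] to a log-binned correlation curve.
#' Any parameter can be fixed to a predetermined value via `fixed` (the
#' bunching and triplet times are commonly fixed to the nsFCS results);
#' for cross-correlations the triplet term is excluded by fixing
#' `c_T = 0`.
#'
#' @param curve a `correlation_curve` on a log grid (positive lags).
#' @param fixed named list of parameters to fix, e.g.
#'   `list(tau_b = 150e-9, c_T = 0)`.
#' @param fit_range lag range (s) used in the fit.
#' @param baseline value subtracted from the curve before fitting: the
#'   model describes the fluctuation correlation, which decays to zero,
#'   while normalized photon correlations decay to 1. Set 0 to decompose
#'   the raw correlation multiplicatively instead.
#' @return object of class `logfcs_fit` with the parameter estimates,
#'   standard errors and fixing flags.
#' @export
fit_log <- function(curve, fixed = list(), fit_range = c(1e-9, 1),
                    baseline = 1) {
  sel <- curve$lag >= fit_range[1] & curve$lag <= fit_range[2] &
    is.finite(curve$G) & curve$npairs > 0
  lag <- curve$lag[sel]
  g <- curve$G[sel] - baseline
  w <- 1 / pmax(curve$err[sel], 1e-12)
  chk(length(lag) >= 5, "too few usable lag bins")

  p_names <- c("n", "c_ab", "tau_ab", "c_b", "tau_b", "c_T", "tau_T",
               "tau_D", "kappa")
  logpar <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  defaults <- c(n = max(max(g, na.rm = TRUE), 1e-2), c_ab = 0.3,
                tau_ab = 3e-9,
                c_b = 0.2, tau_b = 1.5e-7, c_T = 0.2, tau_T = 2e-6,
                tau_D = 1e-3, kappa = 5)
  free <- setdiff(p_names, names(fixed))
  chk(length(free) > 0, "all parameters fixed")

  mk_full <- function(pfree) {
    full <- defaults
    full[names(fixed)] <- unlist(fixed)
    full[free] <- ifelse(logpar[match(free, p_names)], exp(pfree), pfree)
    full
  }
  resid_fn <- function(pfree) {
    q <- mk_full(pfree)
    m <- log_model(lag, q["n"], q["c_ab"], q["tau_ab"], q["c_b"],
                   q["tau_b"], q["c_T"], q["tau_T"], q["tau_D"], q["kappa"])
    (g - m) * w
  }
  start_of <- function(td) {
    s <- defaults
    s["tau_D"] <- td
    vapply(free, function(nm) {
      if (logpar[match(nm, p_names)]) log(s[[nm]]) else s[[nm]]
    }, 1)
  }
  starts <- lapply(c(1e-4, 1e-3, 1e-2), start_of)
  lower <- vapply(free, function(nm) {
    switch(nm, n = 1e-8, c_ab = 0, c_b = 0, c_T = 0, kappa = 0.5,
           log(1e-11))
  }, 1)
  upper <- vapply(free, function(nm) {
    switch(nm, n = Inf, c_ab = 1.5, c_b = 5, c_T = 5, kappa = 50,
           log(10))
  }, 1)
  fit <- lm_multistart(resid_fn, starts, lower = lower, upper = upper)
  est <- mk_full(fit$par)
  se_raw <- lm_se(fit)
  se <- setNames(rep(NA_real_, length(p_names)), p_names)
  se[free] <- ifelse(logpar[match(free, p_names)],
                     est[free] * se_raw, se_raw)
  yhat <- log_model(lag, est["n"], est["c_ab"], est["tau_ab"], est["c_b"],
                    est["tau_b"], est["c_T"], est["tau_T"], est["tau_D"],
                    est["kappa"])
  structure(list(estimate = est, se = se, fixed = fixed,
                 r_squared = r_squared(g, yhat),
                 deviance = fit$deviance, fit = fit),
            class = "logfcs_fit")
}

#' @export
print.logfcs_fit <- function(x, ...) {
  cat("<logfcs_fit> tau_D = ", format(x$estimate["tau_D"] * 1e3, digits = 4),
      " ms, kappa = ", format(x$estimate["kappa"], digits = 3),
      ", R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  fx <- if (length(x$fixed)) paste(names(x$fixed), collapse = ", ") else "none"
  cat("  fixed:", fx, "\n")
  print(x$estimate, digits = 4)
  invisible(x)
}

#' @export
coef.logfcs_fit <- function(object, ...) object$estimate
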