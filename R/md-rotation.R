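# Rotational analysis of trajectories: principal inertia axis series, the
# component-averaged rotational autocorrelation, and its fit by an
# exponential decay plus a persistent-rotation cosine.

#' Principal inertia-axis series of a trajectory
#'
#' Per frame, the eigenvector of the smallest moment of inertia (the long
#' axis of the ellipsoid approximating the particle cloud), normalized and
#' sign-corrected: the sign of the axis is flipped whenever any cartesian
#' component changes by more than `flip_threshold` between consecutive
#' frames (eigenvectors carry no intrinsic sign).
#'
#' @param traj a [trajectory()].
#' @param flip_threshold component-jump threshold triggering a sign flip.
#' @return object of class `principal_axis_series`: list with `axis`
#'   (frames x 3 unit vectors), `flips` (frame indices where the sign was
#'   flipped), `frame_interval` (ns).
#' @export
principal_axis_series <- function(traj, flip_threshold = 0.5) {
  co <- traj$coords
  m <- traj$atoms$mass
  nf <- dim(co)[1]
  ax <- matrix(0, nf, 3)
  warned <- FALSE
  for (j in seq_len(nf)) {
    x <- sweep(co[j, , ], 2, colSums(co[j, , ] * m) / sum(m))
    r2 <- rowSums(x^2)
    # I = sum_a m_a (|r_a|^2 I3 - r_a r_a^T)
    inert <- diag(rep(sum(m * r2), 3)) - crossprod(sweep(x, 1, sqrt(m), "*"))
    e <- eigen(inert, symmetric = TRUE)
    vals <- e$values # decreasing
    if (!warned && (vals[2] - vals[3]) < 1e-8 * vals[1]) {
      warning("near-degenerate inertia tensor; axis chosen by continuity")
      warned <- TRUE
    }
    ax[j, ] <- e$vectors[, 3] # smallest moment = long axis
  }
  flips <- integer(0)
  for (j in 2:max(nf, 2)) {
    if (j > nf) break
    if (any(abs(ax[j, ] - ax[j - 1, ]) > flip_threshold)) {
      ax[j, ] <- -ax[j, ]
      flips <- c(flips, j)
    }
  }
  structure(list(axis = ax, flips = flips,
                 frame_interval = traj$frame_interval),
            class = "principal_axis_series")
}

axis_matrices <- function(x) {
  if (inherits(x, "principal_axis_series")) {
    list(mats = list(x$axis), dt = x$frame_interval)
  } else if (inherits(x, "orientation_trajectory")) {
    list(mats = x$axis, dt = x$frame_interval)
  } else if (is.matrix(x)) {
    list(mats = list(x), dt = attr(x, "frame_interval") %||% 1)
  } else if (is.list(x)) {
    list(mats = x, dt = attr(x, "frame_interval") %||% 1)
  } else {
    stop("cannot interpret axis series input", call. = FALSE)
  }
}

#' Rotational autocorrelation of an axis series
#'
#' Mean-subtracted, variance-normalized autocorrelation averaged over the
#' three cartesian components of the axis:
#' G(tau) = (1/3) sum_i <dI_i(t + tau) dI_i(t)> / sigma_i^2,
#' with the time average running over all frame pairs that overlap at the
#' given shift (per-lag unbiased normalization), so G(0) = 1 exactly.
#' Replicas are averaged.
#'
#' @param x a `principal_axis_series`, `orientation_trajectory`, a frames
#'   x 3 matrix, or a list of such matrices (replicas).
#' @param lag_max maximal lag in frames (default half the series).
#' @details With several replicas the component means and variances are
#'   pooled over all replicas (the ensemble estimate); this avoids the
#'   downward bias that per-replica sample means introduce when the
#'   trajectory is only ~10 correlation times long.
#' @return data.frame of class `rot_acf` with `lag` (ns), `G` and
#'   `n_overlap` (number of frame pairs entering each lag).
#' @export
rotation_acf <- function(x, lag_max = NULL) {
  ax <- axis_matrices(x)
  nmin <- min(vapply(ax$mats, nrow, 1L))
  chk(nmin >= 2, "need at least 2 frames")
  if (is.null(lag_max)) lag_max <- floor(nmin / 2)
  lag_max <- min(lag_max, nmin - 1)
  mu <- colMeans(do.call(rbind, ax$mats))
  sig2 <- vapply(1:3, function(i) {
    mean(unlist(lapply(ax$mats, function(m) (m[, i] - mu[i])^2)))
  }, 1)
  chk(all(sig2 > 0), "zero variance in axis component (constant series)")
  acc <- numeric(lag_max + 1)
  nov <- numeric(lag_max + 1)
  for (m in ax$mats) {
    n <- nrow(m)
    lm_i <- min(lag_max, n - 1)
    comp <- vapply(1:3, function(i) {
      x0 <- m[, i] - mu[i]
      mf <- nextn(2L * n, 2L)
      f <- fft(c(x0, rep(0, mf - n)))
      s <- Re(fft(f * Conj(f), inverse = TRUE)) / mf
      c(s[seq_len(lm_i + 1)] / (n - 0:lm_i) / sig2[i],
        rep(NA_real_, lag_max - lm_i))
    }, numeric(lag_max + 1))
    w <- c(n - 0:lm_i, rep(0, lag_max - lm_i))
    acc <- acc + ifelse(w > 0, rowMeans(comp) * w, 0)
    nov <- nov + w
  }
  out <- data.frame(lag = (0:lag_max) * ax$dt, G = acc / nov,
                    n_overlap = nov)
  class(out) <- c("rot_acf", "data.frame")
  attr(out, "frame_interval") <- ax$dt
  attr(out, "replicas") <- length(ax$mats)
  out
}

#' Fit the rotational ACF with exponential and exponential-plus-cosine models
#'
#' Fits both a single exponential A exp(-tau/tau1) and the extended model
#' G(tau) = A exp(-tau/tau1) + B cos(2 pi omega tau + theta), which absorbs
#' contributions of persistent (continuous) rotation; reports both R^2
#' values and prefers the extended model when it improves R^2 by more than
#' `delta_r2`.
#'
#' @param acf a `rot_acf`.
#' @param fit_range lag range (ns); default from lag 0 to where G first
#'   drops below 0.02 (at least 20 points).
#' @param delta_r2 R^2 improvement required to prefer the extended model.
#' @return object of class `rot_fit` with `A`, `tau1` (ns), `B`, `omega`
#'   (1/ns), `theta`, `r_squared`, the single-exponential alternative and
#'   the preferred model id.
#' @export
fit_rotation <- function(acf, fit_range = NULL, delta_r2 = 0.05) {
  lag <- acf$lag
  g <- acf$G
  if (is.null(fit_range)) {
    # fit the informative part of the decay: the tail of a short-trajectory
    # ACF is noise with strongly correlated errors
    below <- which(g < 0.05)
    imax <- if (length(below)) max(below[1], 20) else length(g)
    fit_range <- c(0, lag[min(imax, length(g))])
  }
  sel <- lag >= fit_range[1] & lag <= fit_range[2]
  t <- lag[sel]
  y <- g[sel]
  w <- if (!is.null(acf$n_overlap)) sqrt(acf$n_overlap[sel]) else
    rep(1, sum(sel))
  w <- w / mean(w)
  tspan <- max(t) - min(t) + acf$lag[2]

  # single exponential
  r1 <- function(p) (y - p[1] * exp(-t / exp(p[2]))) * w
  f1 <- lm_multistart(r1, list(c(1, log(tspan / 5)), c(1, log(tspan / 50))))
  tau_single <- exp(f1$par[2])
  y1 <- f1$par[1] * exp(-t / tau_single)

  # exponential + cosine, multi-start over omega to avoid aliasing
  r2fn <- function(p) {
    (y - (p[1] * exp(-t / exp(p[2])) +
            p[3] * cos(2 * pi * p[4] * t + p[5]))) * w
  }
  starts <- list()
  for (om in c(0.25, 0.5, 1, 2, 4) / tspan) {
    starts[[length(starts) + 1]] <- c(1, log(tspan / 5), 0.1, om, 0)
  }
  f2 <- lm_multistart(r2fn, starts,
                      lower = c(0, log(1e-3), 0, 0, -pi),
                      upper = c(Inf, log(1e5), Inf, Inf, pi))
  y2 <- f2$par[1] * exp(-t / exp(f2$par[2])) +
    f2$par[3] * cos(2 * pi * f2$par[4] * t + f2$par[5])

  rsq1 <- r_squared(y, y1)
  rsq2 <- r_squared(y, y2)
  se2 <- lm_se(f2)
  structure(list(A = f2$par[1], tau1 = exp(f2$par[2]),
                 tau1_se = exp(f2$par[2]) * se2[2],
                 B = f2$par[3], omega = f2$par[4], theta = f2$par[5],
                 r_squared = rsq2,
                 single = list(tau = tau_single, A = f1$par[1],
                               r_squared = rsq1),
                 preferred = if (rsq2 - rsq1 > delta_r2) "exp+cos" else
                   "single",
                 fit_range = fit_range),
            class = "rot_fit")
}

#' @export
print.rot_fit <- function(x, ...) {
  cat("<rot_fit> tau1 = ", format(x$tau1, digits = 4), " ns (A = ",
      format(x$A, digits = 3), ", B = ", format(x$B, digits = 3),
      ", R^2 = ", format(x$r_squared, digits = 3), ")\n",
      "  single exponential: tau = ", format(x$single$tau, digits = 4),
      " ns (R^2 = ", format(x$single$r_squared, digits = 3), ")",
      "  preferred: ", x$preferred, "\n", sep = "")
  invisible(x)
}

#' @export
coef.rot_fit <- function(object, ...) {
  c(A = object$A, tau1 = object$tau1, B = object$B, omega = object$omega,
    theta = object$theta)
}
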