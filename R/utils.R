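# Shared numerical helpers: unit conversions, sphere sampling, ACF via FFT,
# two-state telegraph sampling at irregular times, multi-exponential fitting.

chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Unit conversions between cm^2/s and Angstrom^2/ns
#'
#' @param x diffusion coefficient(s).
#' @return converted value.
#' @export
cm2s_to_A2ns <- function(x) x * 1e7

#' @rdname cm2s_to_A2ns
#' @export
A2ns_to_cm2s <- function(x) x * 1e-7

#' Quasi-uniform directions on the unit sphere (Fibonacci lattice)
#'
#' Used for orientation averages in scattering models.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  chk(n >= 1, "n must be >= 1")
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Normalized autocorrelation of a numeric series via FFT.
# Mean is subtracted; normalization is per-lag unbiased (divides by the
# number of overlapping terms) and scaled so acf[1] (lag 0) equals 1.
acf_fft <- function(x, lag_max = length(x) - 1, demean = TRUE) {
  n <- length(x)
  chk(n >= 2, "need at least 2 points")
  if (demean) x <- x - mean(x)
  v <- sum(x^2) / n
  chk(v > 0, "zero variance series")
  m <- nextn(2L * n, 2L)
  f <- fft(c(x, rep(0, m - n)))
  s <- Re(fft(f * Conj(f), inverse = TRUE)) / m
  lag_max <- min(lag_max, n - 1)
  raw <- s[seq_len(lag_max + 1)]
  raw / (n - 0:lag_max) / v
}

# Sample one telegraph (two-state Markov chain) at sorted times.
# tau is the relaxation time 1/(k_on + k_off); p_on the stationary
# probability of state 1. Exact via uniformization: after at least one
# uniformization event (rate 1/tau) the state is a fresh stationary draw.
telegraph_at <- function(times, tau, p_on) {
  n <- length(times)
  if (n == 0) return(logical(0))
  gaps <- diff(c(-Inf, times))
  ev <- runif(n) < -expm1(-gaps / tau) # gap -Inf => prob 1, fresh initial draw
  fresh <- runif(n) < p_on
  idx <- cummax(seq_len(n) * ev)
  fresh[idx]
}

# Renewal fill-forward: for events at sorted `times` and renewal rate 1/rho,
# return for each time the index of the renewal "interval" it belongs to
# (intervals numbered consecutively; a fresh draw should be attached to each
# unique interval id). First time always opens interval 1.
renewal_intervals <- function(times, rho) {
  n <- length(times)
  if (n == 0) return(integer(0))
  if (!is.finite(rho)) return(rep(1L, n))
  gaps <- diff(c(-Inf, times))
  ev <- runif(n) < -expm1(-gaps / rho)
  cummax(seq_len(n) * ev)
}

# Uniform unit vectors in the spherical cap cos(theta) >= c0 about +z.
cap_sample <- function(n, c0) {
  z <- runif(n, c0, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# Cap opening from a cone-plateau amplitude A in [0, 1]:
# <P2>_cap = c0 (1 + c0) / 2 and the plateau is <P2>^2 = A.
cap_from_amplitude <- function(A) {
  chk(all(A >= 0 & A <= 1), "cone amplitude must be in [0, 1]")
  (-1 + sqrt(1 + 8 * sqrt(A))) / 2
}

# Rotate row-vectors `v` (n x 3) so that +z maps onto the row-unit-vectors
# `axis` (n x 3): minimal rotation (Rodrigues), vectorized.
rotate_z_to <- function(v, axis) {
  az <- axis[, 3]
  # rotation axis = z x axis = (-a_y, a_x, 0), angle t: cos t = a_z
  kx <- -axis[, 2]; ky <- axis[, 1]
  kn <- sqrt(kx^2 + ky^2)
  small <- kn < 1e-12
  kxn <- ifelse(small, 1, kx / pmax(kn, 1e-300))
  kyn <- ifelse(small, 0, ky / pmax(kn, 1e-300))
  ct <- az
  st <- kn # |z x axis| = sin t
  # Rodrigues: v' = v ct + (k x v) st + k (k.v)(1 - ct)
  kdv <- kxn * v[, 1] + kyn * v[, 2]
  cx <- kyn * v[, 3]
  cy <- -kxn * v[, 3]
  cz <- kxn * v[, 2] - kyn * v[, 1]
  out <- cbind(
    v[, 1] * ct + cx * st + kxn * kdv * (1 - ct),
    v[, 2] * ct + cy * st + kyn * kdv * (1 - ct),
    v[, 3] * ct + cz * st
  )
  flip <- small & az < 0 # axis = -z: rotate by pi about x
  if (any(flip)) {
    out[flip, 2] <- -v[flip, 2]
    out[flip, 3] <- -v[flip, 3]
    out[flip, 1] <- v[flip, 1]
  }
  out
}

# n uniform random rotations as unit quaternions (n x 4).
runif_quat <- function(n) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )
}

# Apply row-quaternions q (n x 4, order x,y,z,w) to row-vectors v (n x 3).
quat_rotate <- function(q, v) {
  qv <- q[, 1:3, drop = FALSE]
  w <- q[, 4]
  tx <- 2 * (qv[, 2] * v[, 3] - qv[, 3] * v[, 2])
  ty <- 2 * (qv[, 3] * v[, 1] - qv[, 1] * v[, 3])
  tz <- 2 * (qv[, 1] * v[, 2] - qv[, 2] * v[, 1])
  cbind(
    v[, 1] + w * tx + qv[, 2] * tz - qv[, 3] * ty,
    v[, 2] + w * ty + qv[, 3] * tx - qv[, 1] * tz,
    v[, 3] + w * tz + qv[, 1] * ty - qv[, 2] * tx
  )
}

# Rotation matrix for angle theta about unit axis k (3-vector).
rot_about_axis <- function(k, theta) {
  k <- k / sqrt(sum(k^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Exact discrete Ornstein-Uhlenbeck path: stationary, relaxation time tau,
# stationary SD sigma, n points at interval dt.
ou_series <- function(n, dt, tau, sigma) {
  phi <- exp(-dt / tau)
  innov <- rnorm(n, sd = sigma * sqrt(1 - phi^2))
  innov[1] <- rnorm(1, sd = sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# Weighted multi-start Levenberg-Marquardt on a residual function.
# starts: list of named numeric start vectors. Returns the best nls.lm fit.
lm_multistart <- function(res_fn, starts, lower = NULL, upper = NULL,
                          control = nls.lm.control(maxiter = 200)) {
  best <- NULL
  best_ss <- Inf
  errs <- character(0)
  for (s in starts) {
    fit <- tryCatch(
      nls.lm(par = s, fn = res_fn, lower = lower, upper = upper,
             control = control),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errs <- c(errs, conditionMessage(fit))
      next
    }
    ss <- fit$deviance
    if (is.finite(ss) && ss < best_ss) {
      best <- fit
      best_ss <- ss
    }
  }
  if (is.null(best)) {
    stop("fit failed to converge from any start (",
         paste(unique(errs), collapse = "; "), ")", call. = FALSE)
  }
  best
}

# Standard errors from an nls.lm fit via pseudo-inverse of the curvature.
# The Hessian is rescaled to unit diagonal first: parameters can live on
# wildly different scales (times in seconds next to unitless contrasts),
# and a raw singular-value cutoff would discard everything but the
# stiffest direction. Tolerates parameters pinned at bounds.
lm_se <- function(fit) {
  p <- length(fit$par)
  n <- length(fit$fvec)
  se <- rep(NA_real_, p)
  if (n > p) {
    h <- fit$hessian
    d0 <- sqrt(pmax(diag(h), 1e-300))
    hs <- h / outer(d0, d0)
    sv <- svd(hs)
    pos <- sv$d > max(sv$d) * 1e-10
    hinv <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    s2 <- fit$deviance / (n - p)
    se <- sqrt(pmax(0, diag(hinv)) / d0^2 * 2 * s2) # hessian = 2 J'J
  }
  names(se) <- names(fit$par)
  se
}

# Fit sum of decaying exponentials  y = sum_i A_i exp(-t / T_i) (+ offset)
# by variable projection: the nonlinear search runs over the time
# constants only and the amplitudes are solved by weighted linear least
# squares at every step, which keeps components with very different
# amplitudes from collapsing onto each other. Multi-start over log-spaced
# time-constant grids.
fit_exp_sum <- function(t, y, n_comp, weights = NULL, offset = FALSE,
                        t_range = range(t[t > 0])) {
  chk(n_comp >= 1, "need at least one component")
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  design <- function(tc) {
    x <- vapply(tc, function(ti) exp(-t / ti), numeric(length(t)))
    if (offset) x <- cbind(x, 1)
    x
  }
  beta_of <- function(tc) {
    x <- design(tc)
    qr.coef(qr(x * w), y * w)
  }
  make_res <- function(par) {
    tc <- exp(par)
    x <- design(tc)
    beta <- qr.coef(qr(x * w), y * w)
    beta[is.na(beta)] <- 0
    (y - drop(x %*% beta)) * w
  }
  span <- log(t_range)
  base_tc <- seq(span[1], span[2],
                 length.out = max(n_comp, 2))[seq_len(n_comp)]
  starts <- lapply(c(-0.7, 0, 0.7), function(sh) base_tc + sh)
  fit <- lm_multistart(make_res, starts,
                       lower = rep(span[1] - 3, n_comp),
                       upper = rep(span[2] + 2, n_comp))
  tc <- exp(fit$par)
  beta <- beta_of(tc)
  beta[is.na(beta)] <- 0
  ord <- order(tc)
  list(
    tau = tc[ord], amplitude = beta[seq_len(n_comp)][ord],
    offset = if (offset) beta[n_comp + 1] else 0,
    deviance = fit$deviance, fit = fit
  )
}

# R^2 of a model against data.
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

seed_guard <- function(seed) {
  if (!is.null(seed)) {
    chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
        "seed must be a single number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
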