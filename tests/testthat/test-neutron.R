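# Neutron observables: geometry, spin-echo initial decays, rigid-body first
# cumulants, mode amplitude functions, backscattering fits.

test_that("momentum transfer follows the scattering geometry", {
  expect_equal(q_from_geometry(180, 4 * pi), 1)
  expect_equal(q_from_geometry(9.5, 10), 0.1041, tolerance = 1e-3)
  expect_lt(q_from_geometry(1e-4, 10), 2e-6)
  expect_error(q_from_geometry(190, 10), "angle")
})

test_that("peak length converts q-space features to real space", {
  expect_equal(peak_length(2 * pi), 1)
  expect_equal(peak_length(0.13) / 10, 4.8, tolerance = 0.05) # nm
  expect_equal(peak_length(0.07), 89.8, tolerance = 0.1)
  expect_error(peak_length(-1), "positive")
})

test_that("rotational times from diffusion coefficients", {
  expect_equal(tau_r_from_Dr(1 / 6), 1)
  expect_equal(tau_r_from_Dr(1.64e-3), 101, tolerance = 2 / 101) # printed +/-2 ns
  pa <- tau_r_from_Dr(1 / (6 * c(72, 125, 125)))
  expect_equal(pa$per_axis, c(72, 125, 125))
  expect_equal(pa$mean, 100.4, tolerance = 0.1)
  expect_lt(abs(pa$mean - tau_r_from_Dr(1.64e-3)), 2)
})

test_that("oligomer rescaling divides by n^(1/3) and n", {
  id <- oligomer_rescale(4.71, 1.64e-3, 1)
  expect_equal(id$D_t, 4.71)
  hex <- oligomer_rescale(4.71, 1.64e-3, 3)
  expect_equal(hex$D_t, 4.71 / 3^(1 / 3))
  expect_equal(hex$D_t, 3.266, tolerance = 1e-3)
  expect_equal(hex$D_r, 1.64e-3 / 3)
})

test_that("sphere EISF obeys its small-q expansion and limits", {
  qa <- 0.01
  expect_equal(eisf_sphere(qa, 1), 1 - qa^2 / 5, tolerance = qa^4)
  expect_equal(eisf_sphere(0.5, 0), 1)
  expect_true(all(diff(eisf_sphere(seq(0.1, 1.5, by = 0.1), 1.95)) < 0))
})

test_that("initial-decay fit applies the documented cuts", {
  tau <- c(5, 10, 20, 40, 60)
  ii <- c(0.9, 0.8, 0.5, 0.25, 0.1)
  isf <- list(q = 0.1, tau = tau, I = matrix(ii, ncol = 1),
              err = matrix(0.01, 5, 1))
  expect_warning(de <- fit_initial_decay(isf), NA)
  expect_equal(de$n_used, 3) # tau < 30 AND I > 0.3 keeps exactly 3 points

  # exact exponential recovered to numerical precision
  tau2 <- seq(0, 25, by = 2.5)
  i2 <- exp(-4 * 0.1^2 * tau2)
  isf2 <- list(q = 0.1, tau = tau2, I = matrix(i2, ncol = 1),
               err = matrix(1e-4, length(tau2), 1))
  de2 <- fit_initial_decay(isf2)
  expect_equal(de2$D_eff, 4, tolerance = 1e-8)

  # two-exponential decay: effective rate lies between the two rates
  i3 <- 0.5 * exp(-2 * 0.01 * tau2) + 0.5 * exp(-8 * 0.01 * tau2)
  isf3 <- list(q = 0.1, tau = tau2, I = matrix(i3, ncol = 1),
               err = matrix(1e-4, length(tau2), 1))
  de3 <- fit_initial_decay(isf3)
  expect_gt(de3$D_eff, 2)
  expect_lt(de3$D_eff, 8)
})

test_that("rigid-body D_eff has the correct limits and pair-sum value", {
  set.seed(21)
  body <- list(coords = matrix(rnorm(15, sd = 20), 5, 3), b = runif(5, 0.5, 2),
               D_t = 4, D_r = 2e-3)
  de <- rigid_body_deff(body, c(1e-4, 0.05, 0.1, 0.2))
  expect_equal(de$D_eff[1], 4, tolerance = 4 * 1e-3)
  expect_true(all(de$D_eff >= 4 - 1e-9))

  # single point scatterer: no rotational lever arm
  pt <- list(coords = matrix(0, 1, 3), b = 1, D_t = 3, D_r = 5e-3)
  expect_equal(rigid_body_deff(pt, c(0.05, 0.3))$D_eff, c(3, 3))

  # independent brute-force pair sum over a dense quadrature
  qv <- 0.12
  u <- nanodyn:::fibonacci_sphere(1024)
  x <- sweep(body$coords, 2, colSums(body$coords * body$b) / sum(body$b))
  num <- den <- 0
  for (d in seq_len(nrow(u))) {
    qvec <- qv * u[d, ]
    cr <- t(apply(x, 1, function(r) c(qvec[2] * r[3] - qvec[3] * r[2],
                                      qvec[3] * r[1] - qvec[1] * r[3],
                                      qvec[1] * r[2] - qvec[2] * r[1])))
    for (a in 1:5) for (bb in 1:5) {
      ph <- cos(sum(qvec * (x[a, ] - x[bb, ])))
      num <- num + body$b[a] * body$b[bb] * ph *
        (body$D_t * qv^2 + body$D_r * sum(cr[a, ] * cr[bb, ]))
      den <- den + body$b[a] * body$b[bb] * ph * qv^2
    }
  }
  oracle <- num / den
  fast <- rigid_body_deff(body, qv, n_dir = 256)$D_eff
  expect_equal(fast, oracle, tolerance = 0.005)
})

test_that("amplitude function: isotropic average, oracle, hinge peak", {
  # single particle with unit mode: <(qhat.v)^2> = 1/3 at every q
  a1 <- amplitude_function(list(matrix(c(0, 0, 1), 1, 3)),
                           coords = matrix(0, 1, 3),
                           q_grid = c(0.05, 0.1), evals = 1, n_dir = 512)
  expect_equal(a1$A, c(1 / 3, 1 / 3), tolerance = 2e-3)

  # fixed direction vs direct double sum
  set.seed(22)
  co <- matrix(rnorm(15, sd = 10), 5, 3)
  v <- matrix(rnorm(15), 5, 3)
  b <- runif(5, 0.5, 2)
  qs <- 0.15
  af <- amplitude_function(list(v), coords = co, b = b, q_grid = qs,
                           evals = 1, n_dir = 1)
  u <- nanodyn:::fibonacci_sphere(1)[1, ]
  x <- sweep(co, 2, colSums(co * b) / sum(b))
  s <- 0
  for (a in 1:5) for (bb in 1:5) {
    s <- s + b[a] * b[bb] * cos(qs * sum(u * (x[a, ] - x[bb, ]))) *
      sum(u * v[a, ]) * sum(u * v[bb, ])
  }
  expect_equal(af$A, s, tolerance = 1e-12)

  # two-blob hinge mode peaks near q = 2 pi / separation
  d <- 45
  n <- 20
  set.seed(23)
  co2 <- rbind(sweep(matrix(rnorm(n / 2 * 3, sd = 2), n / 2, 3), 2,
                     c(0, 0, d / 2), "+"),
               sweep(matrix(rnorm(n / 2 * 3, sd = 2), n / 2, 3), 2,
                     c(0, 0, -d / 2), "+"))
  v2 <- rbind(matrix(rep(c(0, 0, 1), n / 2), ncol = 3, byrow = TRUE),
              matrix(rep(c(0, 0, -1), n / 2), ncol = 3, byrow = TRUE))
  aq <- amplitude_function(list(v2 / sqrt(n)), coords = co2,
                           q_grid = seq(0.04, 0.3, by = 0.005), evals = 1)
  qpk <- aq$q[which.max(aq$A)]
  # orientation averaging shifts the hinge signature below 2 pi / d
  expect_gt(qpk, 2 * pi / d * 0.45)
  expect_lt(qpk, 2 * pi / d * 1.3)

  # nonnegativity at random orientations (perfect-square identity)
  expect_true(all(aq$A >= -1e-12))
})

test_that("QENS generator: sphere limit, positivity, normalization", {
  cfg0 <- qens_config(a = 1e-9, noise = 0, seed = 1,
                      q = c(0.4, 1.0), background = 0)
  sp <- simulate_qens(cfg0)
  # a -> 0: both components share the global width -> a single Lorentzian
  ref <- nanodyn:::convolve_resolution(
    nanodyn:::lorentz(cfg0$omega, cfg0$D_app * 0.4^2),
    cfg0$omega, cfg0$resolution_sigma)
  expect_equal(sp$S[, 1], ref, tolerance = 1e-10)
  expect_true(all(sp$S >= 0))

  # wide grid integrates to ~1 per q before noise
  cfgw <- qens_config(q = c(0.4, 0.8), omega = seq(-900, 900, by = 0.5),
                      noise = 0, background = 0, seed = 1)
  spw <- simulate_qens(cfgw)
  dw <- diff(cfgw$omega)[1]
  ints <- colSums(spw$S) * dw
  expect_equal(ints, c(1, 1), tolerance = 0.01)
})

test_that("global backscattering fit recovers D_app and a", {
  sp <- simulate_qens(qens_config(seed = 7))
  fit <- nbs_fit(sp)
  expect_equal(fit$D_app, 3.27, tolerance = 0.05)
  expect_equal(fit$a, 1.95, tolerance = 0.05)
  expect_equal(fit$Gamma_g, fit$D_app * sp$q^2)
})

test_that("per-q Lorentzian widths are linear in q^2 with slope D_app", {
  cfg <- qens_config(a = 1e-9, noise = 0, background = 0, seed = 2,
                     q = seq(0.4, 1.4, length.out = 6))
  sp <- simulate_qens(cfg)
  widths <- vapply(seq_along(sp$q), function(k) {
    y <- sp$S[, k]
    res <- function(p) y - exp(p[2]) * nanodyn:::convolve_resolution(
      nanodyn:::lorentz(sp$omega, exp(p[1])), sp$omega,
      sp$resolution_sigma)
    f <- minpack.lm::nls.lm(c(log(1), 0), fn = res)
    exp(f$par[1])
  }, 1)
  lf <- lm(widths ~ I(sp$q^2))
  expect_gt(summary(lf)$r.squared, 0.99)
  expect_equal(unname(coef(lf)[2]), cfg$D_app, tolerance = 0.02)
})

test_that("spin-echo simulation is normalized and matches the rigid model", {
  cfg <- nse_config(seed = 3, n_samples = 500, tau = seq(0, 30, by = 2))
  isf <- simulate_nse(cfg)
  expect_equal(unname(isf$I[1, ]), rep(1, length(cfg$q)), tolerance = 1e-12)
  de <- fit_initial_decay(isf)
  rb <- rigid_body_deff(list(coords = cfg$coords, b = cfg$b,
                             D_t = cfg$D_t, D_r = cfg$D_r), de$q)
  expect_equal(de$D_eff, rb$D_eff, tolerance = 0.06)
})

test_that("an internal mode raises D_eff near its amplitude-function peak", {
  geom <- nanodyn:::default_dimer_geometry()
  n <- nrow(geom$coords)
  v <- cbind(0, 0, c(rep(1, n / 2), rep(-1, n / 2))) # +/- 1 A per unit proj
  cfg <- nse_config(mode = list(vector = v, tau = 15, rms = 6),
                    q = seq(0.04, 0.24, by = 0.02),
                    tau = seq(0, 24, by = 2), n_samples = 500, seed = 5)
  isf <- simulate_nse(cfg)
  de <- fit_initial_decay(isf, tau_max = 25)
  rb <- rigid_body_deff(list(coords = cfg$coords, b = cfg$b,
                             D_t = cfg$D_t, D_r = cfg$D_r), de$q)
  excess <- de$D_eff - rb$D_eff
  aq <- amplitude_function(list(v), coords = cfg$coords, q_grid = de$q,
                           evals = 1)
  q_excess <- de$q[which.max(excess)]
  q_amp <- aq$q[which.max(aq$A)]
  expect_lt(abs(q_excess - q_amp), 0.08)
  expect_gt(max(excess), 0.1)
})
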