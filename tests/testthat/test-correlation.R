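# Photon-pair correlator against brute-force oracles, and the nsFCS /
# full-FCS model fits.

test_that("correlator equals the brute-force pair histogram exactly", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(40:100, 1)
    t_s <- sort(runif(n, 0, 1e-3))
    ch <- sample(1:4, n, TRUE)
    s <- toy_stream(t_s, channel = ch, duration = 1.2e-3)
    edges <- seq(-5e-5, 5e-5, length.out = sample(10:40, 1))
    cu <- correlate(s, "DxD", edges = edges, split = Inf)
    orc <- pair_oracle(s$t[s$channel == 1], s$t[s$channel == 2],
                       edges * 1e12)
    expect_equal(cu$npairs, orc)
    # same normalization formula applied to the oracle counts
    t_tot <- 1.2e-3 * 1e12
    centers <- (edges[-1] + edges[-length(edges)]) / 2
    na <- sum(s$channel == 1)
    nb <- sum(s$channel == 2)
    den <- na * nb * diff(edges * 1e12) *
      (1 - abs(centers) * 1e12 / t_tot) / t_tot
    expect_equal(cu$G, orc / den, tolerance = 1e-12)
  }
})

test_that("burst-restricted correlation matches a per-burst oracle", {
  set.seed(32)
  t1 <- sort(runif(60, 0, 2e-4))
  t2 <- sort(runif(80, 5e-4, 8e-4))
  s <- toy_stream(c(t1, t2), channel = sample(1:2, 140, TRUE),
                  duration = 1e-3)
  bursts <- data.frame(start = c(1L, 61L), stop = c(60L, 140L))
  bursts$t_start <- s$t[bursts$start]
  bursts$t_stop <- s$t[bursts$stop]
  edges <- seq(-2e-5, 2e-5, length.out = 21)
  cu <- correlate(s, "DxD", edges = edges, bursts = bursts)
  orc <- numeric(20)
  den <- numeric(20)
  centers <- (edges[-1] + edges[-21]) / 2
  for (i in 1:2) {
    idx <- bursts$start[i]:bursts$stop[i]
    ta <- s$t[idx][s$channel[idx] == 1]
    tb <- s$t[idx][s$channel[idx] == 2]
    orc <- orc + pair_oracle(ta, tb, edges * 1e12)
    ti <- bursts$t_stop[i] - bursts$t_start[i]
    den <- den + length(ta) * length(tb) * diff(edges * 1e12) *
      pmax(ti - abs(centers) * 1e12, 0) / ti^2
  }
  expect_equal(cu$npairs, orc)
  expect_equal(cu$G, orc / den, tolerance = 1e-12)
})

test_that("a stationary Poisson stream is uncorrelated (G = 1)", {
  set.seed(33)
  # fine-grained times: two-stage draw beats the 32-bit runif granularity
  n <- 3e5
  t_s <- sort((floor(runif(n, 0, 5) * 1e3) + runif(n)) * 1e-3)
  s <- toy_stream(t_s, channel = sample(1:4, n, TRUE), duration = 5)
  cu <- correlate(s, "AxD", edges = seq(-1e-6, 1e-6, by = 2e-8))
  z <- (cu$G - 1) / cu$err
  expect_lt(mean(abs(z) > 3), 0.02)
  expect_lt(abs(mean(cu$G) - 1), 3 * mean(cu$err) / sqrt(nrow(cu)))
})

test_that("telegraph brightness gives the analytic zero-lag contrast", {
  cfg <- photon_stream_config(
    duration = 6, brightness = 2.5e5, occupancy = 1, n_molecules = 1,
    tau_D = 50, occupancy_update = 1e-4, c_T = 0, c_b = 0.25,
    tau_b = 200e-9, tau_ab = 1e-10, tau_0 = 1e-15, alpha = 0,
    photoselection = 0, rho_dye = 1e-12, rho_local = 1e-12,
    rho_global = 1e-12, background = rep(0, 4),
    states = data.frame(E = 0.5, occupancy = 1), seed = 21)
  s <- simulate_photon_stream(cfg)
  cu <- correlate(s, "AxD", edges = seq(-4e-7, 4e-7, by = 1e-9))
  short <- abs(cu$lag) > 2e-9 & abs(cu$lag) < 3e-8
  # G(tau << tau_b) -> 1 + c_b within sampling error
  expect_equal(mean(cu$G[short]), 1.25, tolerance = 0.04)
  long <- abs(cu$lag) > 3.5e-7
  expect_equal(mean(cu$G[long]), 1 + 0.25 * exp(-375 / 200),
               tolerance = 0.04)
})

test_that("nsFCS model obeys its substitution identities", {
  expect_equal(ns_model(5e-9, a = 2, c_ab = 0.4, tau_ab = 3e-9,
                        c_b = 0.2, tau_b = 1.5e-7, tau_0 = 5e-9),
               2 * (1 - 0.4) * (1 + 0.2))
  expect_equal(ns_model(1, 2, 0.4, 3e-9, 0.2, 1.5e-7, 0), 2)
})

test_that("global nsFCS fit recovers noiseless parameters < 1%", {
  lag <- seq(-1e-6, 1e-6, by = 1e-9)
  lag <- (head(lag, -1) + tail(lag, -1)) / 2
  mk <- function(a) {
    g <- ns_model(lag, a, 0.5, 3e-9, 0.2, 150e-9, 2e-9)
    cu <- data.frame(lag = lag, G = g, err = 1e-4, npairs = 1e4)
    class(cu) <- c("correlation_curve", "data.frame")
    cu
  }
  f <- fit_ns(list(mk(1.8), mk(2.0), mk(2.2)))
  expect_equal(f$tau_b, 150e-9, tolerance = 0.01)
  expect_equal(f$per_curve$c_b, rep(0.2, 3), tolerance = 0.01)
  expect_equal(f$per_curve$tau_ab, rep(3e-9, 3), tolerance = 0.01)
  expect_equal(f$per_curve$a, c(1.8, 2.0, 2.2), tolerance = 0.01)
  expect_equal(unname(f$tau_0), rep(2e-9, 3), tolerance = 0.05)
})

test_that("log FCS model identities and factorization", {
  # tau -> 0: n (1 - c_ab)(1 + c_b)(1 + c_T)
  expect_equal(log_model(1e-15, 2, 0.4, 3e-9, 0.2, 1.5e-7, 0.1, 2e-6,
                         1e-3, 5),
               2 * 0.6 * 1.2 * 1.1, tolerance = 1e-6)
  # at tau = tau_D with kappa -> infinity the diffusion factor halves
  expect_equal(log_model(1e-3, 1, 0, 1e-9, 0, 1e-7, 0, 1e-6, 1e-3, 1e9),
               0.5, tolerance = 1e-6)
  # for tau << tau_T, tau_D the model reduces to the bunching structure
  lag <- 10^seq(-9, -7.2, length.out = 20)
  full <- log_model(lag, 2, 0.5, 3e-9, 0.2, 1.5e-7, 0.15, 1e-5, 1e-2, 5)
  nsred <- 2 * 1.15 * (1 - 0.5 * exp(-lag / 3e-9)) *
    (1 + 0.2 * exp(-lag / 1.5e-7))
  expect_equal(full, nsred, tolerance = 0.005)
})

test_that("diffusion time is recovered from a pure-diffusion curve", {
  # fit machinery: noiseless model curve round-trips within 2%
  lag <- 10^seq(-7, -0.5, length.out = 80)
  g <- log_model(lag, 0.8, 0, 1e-9, 0, 1e-7, 0, 1e-6, 3e-4, 5) + 1
  cu <- data.frame(lag = lag, G = g, err = 1e-4, npairs = 1e4)
  class(cu) <- c("correlation_curve", "data.frame")
  fl0 <- fit_log(cu, fixed = list(c_ab = 0, tau_ab = 3e-9, c_b = 0,
                                  tau_b = 1e-7, c_T = 0, tau_T = 1e-6))
  expect_equal(unname(fl0$estimate["tau_D"]), 3e-4, tolerance = 0.02)
  expect_equal(unname(fl0$estimate["kappa"]), 5, tolerance = 0.05)

  # full stream route (dilute box; counting noise and finite-box effects
  # allow a wider band)
  cfg <- photon_stream_config(
    duration = 60, brightness = 3.5e5, occupancy = 0.03, n_molecules = 16,
    tau_D = 3e-4, kappa = 5, c_T = 0, c_b = 0, alpha = 0,
    background = rep(0, 4), states = data.frame(E = 0.5, occupancy = 1),
    seed = 22)
  s <- simulate_photon_stream(cfg)
  cu2 <- correlate(s, "AxD", edges = lag_grid_log(1e-7, 0.3, 12),
                   branch = "pq")
  fl <- fit_log(cu2, fixed = list(c_ab = 0, tau_ab = 3e-9, c_b = 0,
                                  tau_b = 1e-7, c_T = 0, tau_T = 1e-6,
                                  kappa = 5),
                fit_range = c(2e-7, 1.5e-3))
  expect_equal(unname(fl$estimate["tau_D"]), 3e-4, tolerance = 0.05)
})

test_that("branch subtraction is null for identical/unpolarized input", {
  set.seed(34)
  t_s <- sort(runif(5000, 0, 0.5))
  s <- toy_stream(t_s, channel = sample(1:2, 5000, TRUE), duration = 0.5)
  pq <- correlate(s, "DxD", edges = lag_grid_linear(5e-7, 5e-9),
                  branch = "pq", normalization = "none")
  d0 <- branch_difference(pq, pq)
  expect_true(all(d0$delta == 0))
  qp <- correlate(s, "DxD", edges = lag_grid_linear(5e-7, 5e-9),
                  branch = "qp", normalization = "none")
  d1 <- branch_difference(pq, qp, fit_range = c(5e-9, 5e-7))
  expect_lt(max(abs(d1$delta), na.rm = TRUE), 6 * max(d1$err, na.rm = TRUE))
})

test_that("branch subtraction resolves fast and slow relaxations", {
  # the two branches share a base shape; their difference carries a fast
  # (lifetime) and a slow (rotational) relaxation with a 5:1 amplitude gap
  set.seed(35)
  lag <- seq(1e-9, 1e-6, by = 1e-9)
  base <- 2e5 * (1 - 0.6 * exp(-lag / 3e-9))
  delta <- 5000 * exp(-lag / 3e-9) + 1000 * exp(-lag / 60e-9)
  mk <- function(sign) {
    g <- base + sign * delta / 2 + rnorm(length(lag), 0, 25)
    cu <- data.frame(lag = lag, G = g, err = 25, npairs = 1e4)
    class(cu) <- c("correlation_curve", "data.frame")
    attr(cu, "normalization") <- "none"
    cu
  }
  bd <- branch_difference(mk(1), mk(-1), fit_range = c(1e-9, 8e-7))
  taus <- sort(bd$tau_ns)
  expect_equal(taus[1], 3, tolerance = 0.25)
  expect_equal(taus[2], 60, tolerance = 0.25)
})
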