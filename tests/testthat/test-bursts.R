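# Burst search, route correction, and per-burst FRET observables.

test_that("DeltaT burst search finds the documented toy segmentation", {
  # 10 photons at 1 us gaps, one 1 ms gap, 40 photons at 1 us gaps
  t_s <- c(seq(0, by = 1e-6, length.out = 10),
           10e-6 + 1e-3 + seq(0, by = 1e-6, length.out = 40))
  s <- toy_stream(t_s)
  b <- delta_t_burst_search(s, burst_search_params(delta_t = 100e-6,
                                                   n_min = 35))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_photons, 40)
})

test_that("size window excludes bursts above n_max and sparse streams", {
  t_s <- seq(0, by = 2e-4, length.out = 50) # all gaps above DeltaT
  s <- toy_stream(t_s)
  b <- delta_t_burst_search(s, burst_search_params(delta_t = 100e-6,
                                                   n_min = 2))
  expect_equal(nrow(b), 0)

  t2 <- seq(0, by = 1e-6, length.out = 40)
  s2 <- toy_stream(t2)
  b2 <- delta_t_burst_search(s2, burst_search_params(delta_t = 100e-6,
                                                     n_min = 2, n_max = 30))
  expect_equal(nrow(b2), 0)
})

test_that("segmentation matches a brute-force oracle on random streams", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(50:400, 1)
    t_ps <- sort(round(cumsum(rexp(n, rate = 1 / 10^runif(1, 3, 6)))))
    t_ps <- t_ps + seq_len(n) # enforce strict ordering
    dt <- 10^runif(1, 3, 6)
    n_min <- sample(2:20, 1)
    n_max <- sample(25:200, 1)
    s <- toy_stream(t_ps * 1e-12)
    b <- delta_t_burst_search(s, burst_search_params(dt * 1e-12, n_min,
                                                     n_max))
    orc <- burst_oracle(s$t, dt, n_min, n_max)
    if (is.null(orc)) {
      expect_equal(nrow(b), 0)
    } else {
      expect_equal(cbind(b$start, b$stop), unname(orc))
    }
  }
})

test_that("dual-channel search intersects per-source burst intervals", {
  # source-1 burst spans 0-1 ms, source-2 burst spans 0.5-1.5 ms
  t1 <- seq(0, 1e-3, by = 2e-5)
  t2 <- seq(0.5e-3, 1.5e-3, by = 2e-5)
  df <- rbind(data.frame(t = round(t1 * 1e12), source = 1L),
              data.frame(t = round(t2 * 1e12), source = 2L))
  df <- df[order(df$t), ]
  s <- structure(
    data.frame(t = df$t, channel = 1L, source = df$source,
               microtime = NA_real_, mol = 1L, species = 1L),
    class = c("photon_stream", "data.frame"), duration = 2e-3,
    config = NULL)
  b <- delta_t_burst_search(
    s, burst_search_params(1e-4, n_min = 10, dual_channel = TRUE))
  expect_equal(nrow(b), 1)
  expect_gte(b$t_start * 1e-12, 0.5e-3 - 1e-9)
  expect_lte(b$t_stop * 1e-12, 1.0e-3 + 1e-9)
})

test_that("route correction matrix acts linearly and clamps negatives", {
  x <- c(100, 100, 50, 50)
  expect_equal(apply_rcm(x, diag(4)), x)
  perm <- diag(4)[c(2, 1, 4, 3), ]
  expect_equal(apply_rcm(x, perm), x[c(2, 1, 4, 3)])
  expect_equal(apply_rcm(x, diag(c(1.1, 0.9, 1, 1))), c(110, 90, 50, 50))
  over <- diag(4); over[1, 2] <- -2 # over-subtraction goes negative
  expect_warning(out <- apply_rcm(c(10, 100, 5, 5), over), "clamped")
  expect_equal(out[1], 0)
})

test_that("corrected FRET efficiency follows the correction algebra", {
  expect_equal(fret_efficiency(60, 40), 0.4)
  cf <- correction_factors(alpha = 0.05, delta = 0.05, gamma_f = 1.2)
  # F_c = 50 - 5 - 4 = 41; E = 41 / (120 + 41)
  expect_equal(fret_efficiency(100, 50, 80, cf), 41 / 161)
  # F_c = 0 gives E = 0; zero denominator gives NaN, not an error
  expect_equal(fret_efficiency(100, 0, 0, correction_factors()), 0)
  expect_true(is.nan(fret_efficiency(0, 0, 0)))
})

test_that("stoichiometry reduces to the documented ratios", {
  expect_equal(stoichiometry(50, 50, 100), 0.5)
  expect_equal(stoichiometry(50, 50, 0), 1)
  expect_equal(stoichiometry(50, 50, 100, correction_factors(beta_f = 2)),
               100 / 300)
})

test_that("E and S are scale-invariant ratios for neutral crosstalk", {
  cf <- correction_factors(gamma_f = 1.3, beta_f = 0.8)
  for (k in c(0.5, 2, 17)) {
    expect_equal(fret_efficiency(60, 40, 10, cf),
                 fret_efficiency(60 * k, 40 * k, 10 * k, cf))
    expect_equal(stoichiometry(60, 40, 10, cf),
                 stoichiometry(60 * k, 40 * k, 10 * k, cf))
  }
})

test_that("burst anisotropy matches hand evaluation", {
  cf0 <- correction_factors(l1 = 0, l2 = 0)
  expect_equal(burst_anisotropy(2, 1, cf0), 0.25)
  expect_equal(burst_anisotropy(5, 5, cf0), 0)
  cf <- correction_factors(G = 1.1, l1 = 0.0308, l2 = 0.0368)
  num <- 1.1 * 1000 - 600
  den <- (1 - 3 * 0.0368) * 1.1 * 1000 + (2 - 3 * 0.0308) * 600
  expect_equal(burst_anisotropy(1000, 600, cf), num / den)
})

test_that("substate selection is pure on well-separated synthetic states", {
  cfg <- photon_stream_config(
    duration = 8, brightness = 4e5, occupancy = 0.05, n_molecules = 4,
    c_T = 0, c_b = 0, alpha = 0, tau_0 = 1e-15,
    states = data.frame(E = c(0.2, 0.75), occupancy = c(0.5, 0.5)),
    background = rep(50, 4), seed = 7)
  s <- simulate_photon_stream(cfg)
  b <- delta_t_burst_search(s, burst_search_params())
  b <- burst_features(s, b)
  expect_gt(nrow(b), 20)
  sel <- select_substate(b, c(0.4, 0.8))
  expect_gt(nrow(sel), 5)
  # ground-truth labels: selected bursts should be the E = 0.75 species
  expect_gt(mean(sel$species == 2), 0.95)
  # full range keeps everything with finite E
  expect_equal(nrow(select_substate(b, c(-1, 2))),
               sum(is.finite(b$E)))
  # order preserved
  expect_true(!is.unsorted(sel$start))
  expect_error(select_substate(b, c(0.8, 0.4)), "interval")
})
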