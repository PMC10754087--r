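# Polarized decays, binwise anisotropy, cone-in-cone and multi-exponential
# rotation fits.

test_that("binwise anisotropy hits the textbook limits", {
  pd <- structure(list(time = c(1, 2), f_par = c(10, 30),
                       f_perp = c(10, 10), bin_width = 1,
                       label = "x", source = "A"),
                  class = "polarized_decay")
  cf0 <- correction_factors(l1 = 0, l2 = 0)
  ac <- anisotropy_decay(pd, cf0)
  expect_equal(ac$r[1], 0)           # F_par = F_perp
  expect_equal(ac$r[2], 0.4)         # F_par = 3 F_perp: limiting anisotropy
  # zero-count bins are masked, not an error
  pd$f_par <- c(0, 30); pd$f_perp <- c(0, 10)
  expect_true(is.na(anisotropy_decay(pd, cf0)$r[1]))
})

test_that("the decay generator and Eq.-8 inversion are mutually exact", {
  cfg <- tra_config(seed = 2, G = 1.07)
  dec <- simulate_polarized_decay(cfg)
  cf <- correction_factors(G = cfg$G, l1 = cfg$l1, l2 = cfg$l2)
  cu <- anisotropy_decay(dec$closedA, cf)
  truth <- cone_in_cone(cu$time, cfg$r0, cfg$A_dye, cfg$rho_dye,
                        0.5, 3.0, cfg$rho_global)
  sel <- is.finite(cu$r) & cu$n > 200 & cu$time < 20
  z <- (cu$r[sel] - truth[sel]) / cu$err[sel]
  # Poisson-consistent: standardized residuals ~ N(0, 1)
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.25)
})

test_that("cone-in-cone model has the documented limits", {
  expect_equal(cone_in_cone(0, 0.4, 0.7, 0.35, 0.5, 3, 52), 0.4)
  expect_lt(cone_in_cone(1e4, 0.4, 0.7, 0.35, 0.5, 3, 52), 1e-10)
})

test_that("cone-in-cone global fit recovers noiseless parameters < 2%", {
  cfg <- tra_config(seed = 1)
  dec <- simulate_polarized_decay(cfg)
  # replace counts by expectations
  for (p in seq_along(dec)) {
    tc <- dec[[p]]$time
    r <- cone_in_cone(tc, cfg$r0, cfg$A_dye, cfg$rho_dye,
                      cfg$populations$A_local[p],
                      cfg$populations$rho_local[p], cfg$rho_global)
    env <- exp(-tc / cfg$lifetime)
    w_par <- env * (1 + (2 - 3 * cfg$l1) * r)
    w_perp <- cfg$G * env * (1 - (1 - 3 * cfg$l2) * r)
    nrm <- cfg$populations$counts[p] / sum(w_par + w_perp)
    dec[[p]]$f_par <- w_par * nrm
    dec[[p]]$f_perp <- w_perp * nrm
  }
  curves <- lapply(dec, anisotropy_decay)
  fit <- fit_cone_in_cone(curves)
  expect_equal(fit$rho_dye, cfg$rho_dye, tolerance = 0.02)
  expect_equal(fit$rho_global, cfg$rho_global, tolerance = 0.02)
  expect_equal(fit$A_dye, cfg$A_dye, tolerance = 0.02)
  expect_equal(fit$per_pop$rho_local, cfg$populations$rho_local,
               tolerance = 0.02)
})

test_that("Poisson decays recover the shared rotation times", {
  dec <- simulate_polarized_decay(tra_config(seed = 4))
  fit <- fit_cone_in_cone(lapply(dec, anisotropy_decay))
  expect_equal(fit$rho_dye, 0.35, tolerance = 0.05 / 0.35) # +/- 0.05 ns
  expect_equal(fit$rho_global, 52, tolerance = 32 / 52) # +/- 32 ns
})

test_that("shared-parameter fits shrink the dye-time variance", {
  set.seed(6)
  shared <- indep <- c()
  for (k in 1:4) {
    dec <- simulate_polarized_decay(tra_config(seed = 100 + k))
    curves <- lapply(dec, anisotropy_decay)
    shared <- c(shared, fit_cone_in_cone(curves)$rho_dye)
    indep <- c(indep, vapply(curves, function(cu) {
      fit_cone_in_cone(list(cu), share = character(0))$rho_dye
    }, 1))
  }
  expect_lt(sd(shared), sd(indep))
})

test_that("multi-exponential fits are nested and selected by BIC", {
  tt <- seq(0.5, 30, by = 0.05)
  r1 <- 0.4 * exp(-tt / 5)
  cu1 <- data.frame(time = tt, r = r1, err = 1e-3, n = 1e4)
  class(cu1) <- c("anisotropy_curve", "data.frame")
  f1 <- fit_multiexp(cu1, 1)
  expect_equal(f1$rho, 5, tolerance = 1e-3)
  f2 <- fit_multiexp(cu1, 2)
  expect_lt(min(abs(f2$amplitude)), 0.02) # extra component is inert

  # product of exponentials with zero cone amplitudes = one rate sum
  rr <- cone_in_cone(tt, 0.4, 0, 0.4, 0, 3, 52)
  cup <- data.frame(time = tt, r = rr, err = 1e-3, n = 1e4)
  class(cup) <- c("anisotropy_curve", "data.frame")
  fp <- fit_multiexp(cup, 1)
  expect_equal(1 / fp$rho, 1 / 0.4 + 1 / 3 + 1 / 52, tolerance = 1e-3)

  # 2-exponential data: BIC prefers 2 components over 3
  set.seed(1)
  r2 <- 0.25 * exp(-tt / 1.2) + 0.15 * exp(-tt / 20) + rnorm(length(tt), 0, 1e-3)
  cu2 <- data.frame(time = tt, r = r2, err = 1e-3, n = 1e4)
  class(cu2) <- c("anisotropy_curve", "data.frame")
  b2 <- fit_multiexp(cu2, 2)$bic
  b3 <- fit_multiexp(cu2, 3)$bic
  expect_lt(b2, b3)
  expect_error(fit_multiexp(cu2, 4), "n_comp")
})

test_that("burst microtime histograms conserve counts and lifetimes", {
  cfg <- photon_stream_config(
    duration = 6, brightness = 2e5, occupancy = 0.2, n_molecules = 4,
    mode = "pie", c_T = 0, c_b = 0, alpha = 0, lifetime_a = 3e-9,
    states = data.frame(E = 0.6, occupancy = 1),
    background = rep(20, 4), seed = 11)
  s <- simulate_photon_stream(cfg)
  b <- delta_t_burst_search(s, burst_search_params(dual_channel = TRUE))
  expect_gt(nrow(b), 3)
  pd <- decay_from_bursts(s, b, source = "A", bin_width = 0.064)
  # conservation: histograms sum to the selected red-excitation photons
  idx <- unlist(lapply(seq_len(nrow(b)), function(i) b$start[i]:b$stop[i]))
  n_red <- sum(s$source[idx] == 2L)
  expect_equal(sum(pd$f_par) + sum(pd$f_perp), n_red)
  # total decay carries the configured acceptor lifetime (3 ns within 5%)
  tot <- pd$f_par + pd$f_perp
  sel <- pd$time > 0.3 & pd$time < 15 & tot > 0
  fit <- lm(log(tot[sel]) ~ pd$time[sel], weights = tot[sel])
  expect_equal(-1 / unname(coef(fit)[2]), 3, tolerance = 0.05)
})

test_that("cone-in-cone fits are invariant to the intensity scale", {
  dec <- simulate_polarized_decay(tra_config(seed = 9))
  f1 <- fit_cone_in_cone(lapply(dec, anisotropy_decay))
  dec4 <- lapply(dec, function(d) {
    d$f_par <- d$f_par * 4
    d$f_perp <- d$f_perp * 4
    d
  })
  # the count floor is scaled with the data so both fits see the same bins
  f2 <- fit_cone_in_cone(lapply(dec4, anisotropy_decay), min_counts = 400)
  expect_equal(f1$rho_dye, f2$rho_dye, tolerance = 1e-6)
  expect_equal(f1$rho_global, f2$rho_global, tolerance = 1e-6)
})
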