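# Trajectory mode analysis: superposition, inertia-axis rotation, PCA,
# accessible volumes, elastic network modes.

make_rotor_traj <- function(n_frames = 400, seed = 3, elongated = TRUE) {
  set.seed(seed)
  lobe <- matrix(rnorm(12 * 3, sd = 3), 12, 3)
  if (elongated) lobe[, 3] <- lobe[, 3] * 4
  cfg <- bead_dimer_config(coords = lobe, masses = rep(100, 12),
                           chain = rep("A", 12), D_t = 1, D_r = 2e-3,
                           n_frames = n_frames, seed = seed)
  simulate_bead_dimer(cfg)
}

test_that("superposition recovers rigid transforms exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  rot <- nanodyn:::rot_about_axis(rnorm(3), 1.1)
  moved <- ref %*% t(rot) + matrix(c(5, -2, 7), 10, 3, byrow = TRUE)
  co <- array(0, c(2, 10, 3))
  co[1, , ] <- ref
  co[2, , ] <- moved
  tr <- trajectory(co, data.frame(mass = rep(1, 10), resid = 1:10,
                                  chain = "A", name = "CA",
                                  backbone = TRUE, ss = TRUE), 1)
  sup <- superpose(tr, reference = ref, selection = 1:10)
  expect_lt(sup$rmsd[1], 1e-10)
  expect_lt(sup$rmsd[2], 1e-8)
})

test_that("Kabsch matches an exhaustive rotation-grid minimizer", {
  set.seed(2)
  p <- matrix(rnorm(12), 4, 3)
  q <- p %*% t(nanodyn:::rot_about_axis(c(0, 0, 1), 0.7))
  k <- nanodyn:::kabsch(p, q)
  rmsd_k <- sqrt(mean(rowSums((sweep(p, 2, k$cp) %*% t(k$rot) -
                                 sweep(q, 2, k$cq))^2)))
  # brute-force search over an Euler-angle grid
  best <- Inf
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  for (a in ang) for (b in seq(0, pi, length.out = 13)) for (c in ang) {
    rz1 <- nanodyn:::rot_about_axis(c(0, 0, 1), a)
    ry <- nanodyn:::rot_about_axis(c(0, 1, 0), b)
    rz2 <- nanodyn:::rot_about_axis(c(0, 0, 1), c)
    r <- rz1 %*% ry %*% rz2
    best <- min(best, sqrt(mean(rowSums((pc %*% t(r) - qc)^2))))
  }
  expect_lte(rmsd_k, best + 1e-12) # optimal beats any grid point
  expect_lt(best - rmsd_k, 0.5)    # and the grid comes close
})

test_that("principal axis of a hand-built ellipsoid is its long axis", {
  # 6-point ellipsoid: semi-axes 5 > 2 > 1
  pts <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 2, 0), c(0, -2, 0),
               c(0, 0, 1), c(0, 0, -1))
  co <- array(0, c(3, 6, 3))
  for (j in 1:3) co[j, , ] <- pts
  tr <- trajectory(co, data.frame(mass = rep(1, 6), resid = 1:6,
                                  chain = "A", name = "CA",
                                  backbone = TRUE, ss = TRUE), 1)
  pax <- principal_axis_series(tr)
  for (j in 1:3) {
    expect_equal(abs(pax$axis[j, 1]), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(pax$axis[j, ]^2)), 1, tolerance = 1e-12)
  }
})

test_that("sign-flip rule yields a continuous axis series", {
  tr <- make_rotor_traj(n_frames = 300)
  pax <- principal_axis_series(tr)
  jumps <- apply(abs(diff(pax$axis)), 1, max)
  expect_lt(max(jumps), 0.5)
  expect_equal(sqrt(rowSums(pax$axis^2)), rep(1, 300), tolerance = 1e-12)
})

test_that("rotation ACF is exactly normalized and matches a direct sum", {
  set.seed(4)
  n <- 150
  u <- matrix(rnorm(n * 3), n, 3)
  u <- u / sqrt(rowSums(u^2))
  ac <- rotation_acf(u, lag_max = 60)
  expect_equal(ac$G[1], 1, tolerance = 1e-12)
  # direct double-loop evaluation with the same pooled-mean convention
  mu <- colMeans(u)
  sig2 <- vapply(1:3, function(i) mean((u[, i] - mu[i])^2), 1)
  direct <- vapply(0:60, function(k) {
    mean(vapply(1:3, function(i) {
      x <- u[, i] - mu[i]
      sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k) / sig2[i]
    }, 1))
  }, 1)
  expect_equal(ac$G, direct, tolerance = 1e-12)
  # white-noise components decorrelate beyond lag zero
  expect_lt(max(abs(ac$G[-1])), 4 / sqrt(n))
})

test_that("rotation fit recovers a pure exponential and a cosine mixture", {
  lag <- seq(0, 400, by = 0.5)
  ac <- data.frame(lag = lag, G = exp(-lag / 81),
                   n_overlap = rep(1e4, length(lag)))
  class(ac) <- c("rot_acf", "data.frame")
  attr(ac, "frame_interval") <- 0.5
  f <- fit_rotation(ac, fit_range = c(0, 400))
  expect_equal(f$tau1, 81, tolerance = 1e-4)
  expect_lt(abs(f$B), 1e-4)

  g2 <- 1.17 * exp(-lag / 81) + 0.199 * cos(2 * pi * lag / 500 + 0.3)
  ac2 <- ac
  ac2$G <- g2
  f2 <- fit_rotation(ac2, fit_range = c(0, 400))
  expect_equal(f2$B / f2$A, 0.199 / 1.17, tolerance = 0.3)
  expect_equal(f2$tau1, 81, tolerance = 0.1)
  expect_gt(f2$r_squared, f2$single$r_squared)
})

test_that("isotropic rotor recovery lands near the analytic 1/(2 D_r)", {
  ot <- simulate_orientation(orientation_config(
    D_r = 1 / (2 * 40), n_frames = 6000, replicas = 4,
    frame_interval = 0.1, seed = 8))
  f <- fit_rotation(rotation_acf(ot, lag_max = 2000))
  expect_equal(f$tau1, 40, tolerance = 0.25)
})

test_that("constant-rotation rotor produces a cosine weight", {
  ot <- simulate_orientation(orientation_config(
    D_r = 1e-4, omega = 1 / 400, n_frames = 4000, replicas = 2,
    frame_interval = 0.1, seed = 9))
  f <- fit_rotation(rotation_acf(ot, lag_max = 3000),
                    fit_range = c(0, 300))
  expect_gt(f$B, 0.02)
  expect_equal(f$preferred, "exp+cos")
})

test_that("zero-diffusion zero-rotation axis stays constant", {
  ot <- simulate_orientation(orientation_config(D_r = 0, omega = 0,
                                                n_frames = 50,
                                                replicas = 1, seed = 1))
  expect_equal(max(abs(diff(ot$axis[[1]]))), 0)
  expect_error(rotation_acf(ot), "variance")
})

test_that("cartesian PCA recovers an injected OU mode", {
  v <- matrix(0, 32, 3)
  v[1:16, 3] <- 1
  v[17:32, 3] <- -1
  v <- v / sqrt(sum(v^2))
  cfg <- bead_dimer_config(modes = list(list(vector = v, tau = 100,
                                             rms = 3)),
                           n_frames = 12000, seed = 5)
  tr <- superpose(simulate_bead_dimer(cfg), selection = 1:32)
  pm <- cartesian_pca(tr)
  # orthonormal eigenvectors, conserved variance
  k <- min(10, ncol(pm$evecs))
  gram <- crossprod(pm$evecs[, 1:k])
  expect_equal(gram, diag(k), tolerance = 1e-8)
  expect_equal(sum(pm$evals), pm$total_variance, tolerance = 1e-8)
  # leading mode matches the injected displacement direction
  v1 <- nanodyn:::mode_vector(pm, 1)
  v1 <- v1 / sqrt(sum(v1^2))
  expect_gt(abs(sum(v1 * v)), 0.95)
  # projection ACF time within 20% of the OU relaxation
  pa <- projection_acf(pm, modes = 1)
  expect_equal(pa$mode1$tau, 100, tolerance = 0.2)
  expect_equal(pa$mode1$acf[1], 1, tolerance = 1e-12)
})

test_that("rigid-body-only trajectory has ~zero variance after fitting", {
  cfg <- bead_dimer_config(n_frames = 400, seed = 11)
  tr <- simulate_bead_dimer(cfg)
  pre <- sum(apply(matrix(tr$coords, 400, ncol = 32 * 3), 2, var))
  sup <- superpose(tr, selection = 1:32)
  pm <- cartesian_pca(sup)
  post <- pm$total_variance / mean(cfg$masses)
  expect_lt(post / pre, 1e-6)
})

test_that("mode RMSF is constant for a uniform translation mode", {
  n <- 8
  ev <- rep(c(1, 0, 0), n) / sqrt(n)
  model <- structure(list(evecs = matrix(ev, ncol = 1), evals = 2.5,
                          masses = rep(12, n)), class = "pca_model")
  r <- mode_rmsf(model, 1)
  expect_equal(r, rep(r[1], n))
  expect_true(all(r >= 0))
  expect_error(mode_rmsf(model, 3), "range")
})

test_that("accessible volume approaches the analytic free-dye sphere", {
  av <- accessible_volume(matrix(0, 1, 3), 1,
                          av_params(linker_length = 10, dye_radius = 1,
                                    spacing = 0.5))
  expect_equal(av, 4 / 3 * pi * 1000, tolerance = 0.05)
})

test_that("an enclosed attachment has zero accessible volume", {
  shell <- as.matrix(expand.grid(x = c(-2, 2), y = c(-2, 2),
                                 z = c(-2, 2)))
  co <- rbind(c(0, 0, 0), shell)
  av <- accessible_volume(co, 1,
                          av_params(linker_length = 4, dye_radius = 2.5,
                                    contact_radius = 2, spacing = 0.8))
  expect_equal(av, 0)
})

test_that("accessible volume is monotone in the linker length", {
  set.seed(6)
  co <- rbind(c(0, 0, 0), matrix(rnorm(60, sd = 6), 20, 3))
  p1 <- av_params(linker_length = 6, spacing = 1.2)
  p2 <- av_params(linker_length = 10, spacing = 1.2)
  expect_lte(accessible_volume(co, 1, p1), accessible_volume(co, 1, p2))
})

test_that("AV correlation recovers an OU relaxation time", {
  set.seed(12)
  x <- nanodyn:::ou_series(6000, dt = 1, tau = 100, sigma = 1)
  ac <- av_correlation(x, frame_interval = 1, lag_max = 800)
  expect_equal(ac$corr[1], 1, tolerance = 1e-12)
  expect_equal(max(ac$tau), 100, tolerance = 0.15)
  # independent series decorrelate
  y <- nanodyn:::ou_series(6000, dt = 1, tau = 100, sigma = 1)
  cc <- av_correlation(x, y, frame_interval = 1, lag_max = 200)
  expect_lt(max(abs(cc$corr)), 0.25)
  expect_error(av_correlation(rep(1, 50)), "constant")
})

test_that("ANM reproduces the two-body spring and rigid null space", {
  co2 <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_warning(m2 <- anm_modes(co2, cutoff = 5, gamma_spring = 1.7),
                 NA)
  nz <- sum(m2$evals < 1e-8)
  expect_equal(length(m2$evals) - nz, 1) # one stretching mode
  expect_equal(max(m2$evals), 2 * 1.7, tolerance = 1e-10)

  set.seed(13)
  co <- matrix(rnorm(40 * 3, sd = 6), 40, 3)
  m <- anm_modes(co, cutoff = 18, gamma_spring = 1)
  expect_equal(sum(m$evals < 1e-8 * max(m$evals)), 6)
  # rigid translation lies in the null space
  h <- m$evecs %*% (m$evals * t(m$evecs))
  tx <- rep(c(1, 0, 0), 40) / sqrt(40)
  expect_lt(max(abs(h %*% tx)), 1e-8)
  expect_gt(length(anm_mobility(m, 1)), 0)
})
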