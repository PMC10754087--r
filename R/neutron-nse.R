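# Spin-echo side of the neutron module: scattering geometry, initial-decay
# fits of I(q, tau), the rigid-body first-cumulant D_eff(q), oligomer
# rescaling, rotational times, and PCA-mode amplitude functions A_k(q).

#' Momentum transfer from scattering geometry
#'
#' q = 4 pi sin(2theta / 2) / lambda.
#'
#' @param two_theta scattering angle 2theta (degrees), in (0, 180].
#' @param wavelength neutron wavelength (Angstrom).
#' @return q (1/Angstrom).
#' @export
q_from_geometry <- function(two_theta, wavelength) {
  chk(all(two_theta > 0 & two_theta <= 180),
      "scattering angle must lie in (0, 180] degrees")
  chk(all(wavelength > 0), "wavelength must be positive")
  4 * pi * sin(two_theta * pi / 360) / wavelength
}

#' Real-space correlation length of a q-space feature
#'
#' @param q scattering vector (1/Angstrom), positive.
#' @return length 2 pi / q (Angstrom).
#' @export
peak_length <- function(q) {
  chk(all(q > 0), "q must be positive")
  2 * pi / q
}

#' Mean rotational correlation time from a rotational diffusion coefficient
#'
#' Scalar D_r: tau_r = 1/(6 D_r). Per-axis D_r (length 3): per-axis times
#' 1/(6 D_i) plus the overall time 1/(6 mean(D_i)).
#'
#' @param D_r rotational diffusion coefficient(s); any time unit's inverse.
#' @return for scalar input, tau_r; for per-axis input, a list with
#'   `per_axis` and `mean` (from the mean coefficient).
#' @export
tau_r_from_Dr <- function(D_r) {
  chk(all(D_r > 0), "D_r must be positive")
  if (length(D_r) == 1) return(1 / (6 * D_r))
  list(per_axis = 1 / (6 * D_r), mean = 1 / (6 * mean(D_r)))
}

#' Rescale diffusion coefficients to an oligomeric assembly
#'
#' For an assembly of `n_dimers` building blocks the radius grows with
#' n^(1/3), so D_t' = D_t / n^(1/3) and D_r' = D_r / n.
#'
#' @param D_t,D_r translational / rotational diffusion coefficients.
#' @param n_dimers assembly factor (>= 1).
#' @return list with rescaled `D_t` and `D_r`.
#' @export
oligomer_rescale <- function(D_t, D_r, n_dimers) {
  chk(n_dimers >= 1, "n_dimers must be >= 1")
  list(D_t = D_t / n_dimers^(1 / 3), D_r = D_r / n_dimers)
}

#' Effective diffusion from the initial decay of I(q, tau)
#'
#' Per q, a weighted fit of C exp(-D_eff q^2 tau) restricted to the initial
#' decay (tau below `tau_max` and I above `i_min`); q values with fewer
#' than 3 surviving points are omitted with a warning.
#'
#' @param isf an `isf` object (see [simulate_nse()]) or compatible list
#'   with `q`, `tau`, `I`, `err`.
#' @param tau_max,i_min initial-decay cuts (ns / amplitude).
#' @return data.frame of class `deff_curve`: `q`, `D_eff` (Angstrom^2/ns),
#'   `se`, `C`, `n_used`; provenance attribute "initial-decay fit".
#' @export
fit_initial_decay <- function(isf, tau_max = 30, i_min = 0.3) {
  nq <- length(isf$q)
  out <- data.frame(q = isf$q, D_eff = NA_real_, se = NA_real_,
                    C = NA_real_, n_used = 0L)
  for (k in seq_len(nq)) {
    ii <- isf$I[, k]
    sel <- isf$tau < tau_max & ii > i_min & is.finite(ii)
    out$n_used[k] <- sum(sel)
    if (sum(sel) < 3) next
    tt <- isf$tau[sel]
    y <- ii[sel]
    w <- 1 / pmax(isf$err[sel, k], 1e-6)
    q2 <- isf$q[k]^2
    res <- function(p) (y - p[1] * exp(-exp(p[2]) * q2 * tt)) * w
    slope0 <- max((log(max(y)) - log(max(min(y), 1e-3))) /
                    (max(tt) - min(tt) + 1e-9) / q2, 1e-4)
    fit <- lm_multistart(res, list(c(1, log(slope0)),
                                   c(1, log(slope0 * 5)),
                                   c(1, log(slope0 / 5))))
    se <- lm_se(fit)
    out$D_eff[k] <- exp(fit$par[2])
    out$se[k] <- exp(fit$par[2]) * se[2]
    out$C[k] <- fit$par[1]
  }
  if (anyNA(out$D_eff)) {
    warning(sum(is.na(out$D_eff)),
            " q value(s) omitted: fewer than 3 points survive the cuts")
    out <- out[!is.na(out$D_eff), , drop = FALSE]
  }
  class(out) <- c("deff_curve", "data.frame")
  attr(out, "provenance") <- "initial-decay fit"
  out
}

#' Rigid-body first-cumulant effective diffusion D_eff(q)
#'
#' Orientation-averaged first cumulant of a rigid scatterer:
#' D_eff(q) = < sum_ab b_a b_b e^{iq.(r_a - r_b)} (D_t q^2 +
#'   (q x r_a) . D_r . (q x r_b)) > / (q^2 < sum_ab b_a b_b
#'   e^{iq.(r_a - r_b)} >), coordinates about the scattering-length-weighted
#' centroid, average over a Fibonacci sphere of directions. D_eff -> D_t
#' as q -> 0 and D_eff >= D_t everywhere.
#'
#' @param body list with `coords` (n x 3, Angstrom), `b` (scattering
#'   lengths), `D_t` (Angstrom^2/ns), `D_r` (1/ns; scalar or 3 principal
#'   values, applied along the lab axes).
#' @param q_list scattering vectors (1/Angstrom).
#' @param n_dir orientation-average directions.
#' @return data.frame of class `deff_curve` (provenance "rigid-body
#'   model").
#' @export
rigid_body_deff <- function(body, q_list, n_dir = 256) {
  chk(nrow(body$coords) >= 1, "need at least one scatterer")
  dr <- body$D_r
  if (length(dr) == 1) dr <- rep(dr, 3)
  chk(length(dr) == 3 && all(dr >= 0),
      "D_r must be a nonnegative scalar or 3 principal values")
  b <- body$b
  x <- sweep(body$coords, 2, colSums(body$coords * b) / sum(b))
  u <- fibonacci_sphere(n_dir)
  nq <- length(q_list)
  num <- den <- numeric(nq)
  for (d in seq_len(n_dir)) {
    ud <- u[d, ]
    proj <- x %*% ud # n x 1
    cr <- cbind(ud[2] * x[, 3] - ud[3] * x[, 2],
                ud[3] * x[, 1] - ud[1] * x[, 3],
                ud[1] * x[, 2] - ud[2] * x[, 1]) # u x r_a
    ph <- exp(1i * outer(drop(proj), q_list)) # n x nq
    f <- drop(crossprod(ph, b)) # nq
    ff <- Mod(f)^2
    rot <- numeric(nq)
    for (m in 1:3) {
      if (dr[m] == 0) next
      sm <- drop(crossprod(ph, b * cr[, m])) # nq, lacks factor q
      rot <- rot + dr[m] * Mod(sm)^2 * q_list^2
    }
    num <- num + body$D_t * q_list^2 * ff + rot
    den <- den + q_list^2 * ff
  }
  out <- data.frame(q = q_list, D_eff = num / den)
  class(out) <- c("deff_curve", "data.frame")
  attr(out, "provenance") <- "rigid-body model"
  out
}

#' Scattering amplitude functions of collective modes
#'
#' For mode k with per-particle displacement directions v_k:
#' A_k(q) = < | sum_a b_a e^{i q qhat . r_a} (qhat . v_ka) |^2 >_qhat,
#' a perfect square and hence nonnegative at every orientation. The
#' combined curve weights modes by the square root of their eigenvalues
#' (`weighting = "amplitude"`), or uses eigenvalue-scaled displacement
#' vectors inside the amplitude (`weighting = "displacement"`, i.e.
#' weight lambda_k).
#'
#' @param modes a `pca_model`, or a list of n x 3 displacement matrices.
#' @param coords particle coordinates (n x 3); defaults to the PCA mean.
#' @param b scattering lengths (default 1).
#' @param q_grid q values (1/Angstrom).
#' @param evals eigenvalue weights when `modes` is a plain list.
#' @param n_modes number of leading modes combined (default 10).
#' @param n_dir orientation-average directions.
#' @param weighting "amplitude" or "displacement" (see above).
#' @param check_convergence if TRUE, re-evaluates a few q at double the
#'   quadrature order and warns when the combined curve shifts by > 1%.
#' @return data.frame of class `amplitude_curve` with `q`, `A` (combined)
#'   and per-mode columns `A1..Ak`.
#' @export
amplitude_function <- function(modes, coords = NULL, b = NULL,
                               q_grid = seq(0.02, 0.2, by = 0.005),
                               evals = NULL, n_modes = 10, n_dir = 256,
                               weighting = c("amplitude", "displacement"),
                               check_convergence = FALSE) {
  weighting <- match.arg(weighting)
  if (inherits(modes, "pca_model")) {
    k <- min(n_modes, length(modes$evals))
    vex <- lapply(seq_len(k), function(i) {
      v <- mode_vector(modes, i)
      v / sqrt(sum(v^2))
    })
    evals <- modes$evals[seq_len(k)]
    if (is.null(coords)) coords <- modes$mean
  } else {
    vex <- modes[seq_len(min(n_modes, length(modes)))]
    chk(!is.null(coords), "coords required with raw mode vectors")
    if (is.null(evals)) evals <- rep(1, length(vex))
    evals <- evals[seq_along(vex)]
  }
  n <- nrow(coords)
  chk(all(vapply(vex, nrow, 1L) == n),
      "mode vector and coordinate lengths differ")
  if (is.null(b)) b <- rep(1, n)
  x <- sweep(coords, 2, colSums(coords * b) / sum(b))

  eval_ak <- function(ndir) {
    u <- fibonacci_sphere(ndir)
    ak <- matrix(0, length(q_grid), length(vex))
    for (d in seq_len(ndir)) {
      ud <- u[d, ]
      ph <- exp(1i * outer(drop(x %*% ud), q_grid)) # n x nq
      for (k in seq_along(vex)) {
        s <- drop(crossprod(ph, b * drop(vex[[k]] %*% ud)))
        ak[, k] <- ak[, k] + Mod(s)^2
      }
    }
    ak / ndir
  }
  ak <- eval_ak(n_dir)
  wts <- if (weighting == "amplitude") sqrt(evals) else evals
  combined <- drop(ak %*% wts)
  if (check_convergence) {
    sub <- unique(round(seq(1, length(q_grid), length.out = 3)))
    qg_full <- q_grid
    q_grid <- qg_full[sub]
    ak2 <- eval_ak(2 * n_dir)
    comb2 <- drop(ak2 %*% wts)
    q_grid <- qg_full
    rel <- abs(comb2 - combined[sub]) / pmax(abs(comb2), 1e-12)
    if (max(rel) > 0.01) {
      warning("orientation average not converged to 1%; increase n_dir")
    }
  }
  out <- data.frame(q = q_grid, A = combined)
  for (k in seq_along(vex)) out[[paste0("A", k)]] <- ak[, k]
  class(out) <- c("amplitude_curve", "data.frame")
  attr(out, "weighting") <- weighting
  attr(out, "evals") <- evals
  out
}

#' @export
print.deff_curve <- function(x, ...) {
  cat("<deff_curve> (", attr(x, "provenance"), ") ", nrow(x),
      " q values, D_eff ", format(min(x$D_eff), digits = 3), " - ",
      format(max(x$D_eff), digits = 3), " A^2/ns\n", sep = "")
  invisible(x)
}
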