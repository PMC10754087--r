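# Backscattering "conventional analysis": global fit of S(q, omega) with a
# global-diffusion Lorentzian plus a confined internal component whose
# elastic fraction is the diffusion-in-a-sphere EISF.

#' Global backscattering fit: apparent diffusion and confinement radius
#'
#' Fits all spectra jointly with
#' S(q, omega) = beta_q R (x) (A0(q) L(Gamma_g) +
#'   (1 - A0(q)) L(Gamma_g + Gamma_int)) + background,
#' Gamma_g = D_app q^2 and A0(q) = (3 j1(qa)/(qa))^2, convolved with the
#' Gaussian resolution. D_app, a and Gamma_int are global; the amplitude
#' beta_q is per q; the flat background is global.
#'
#' @param spectra a `qens_spectra` (see [simulate_qens()]) or compatible
#'   list with `q`, `omega`, `S`, `err`.
#' @param resolution_sigma Gaussian resolution SD (1/ns); default taken
#'   from the spectra object.
#' @return object of class `nbs_result`: `D_app` (Angstrom^2/ns), `a`
#'   (Angstrom), `gamma_int` (1/ns), standard errors, per-q global widths
#'   `Gamma_g`, amplitudes, background, reduced chi-squared.
#' @export
nbs_fit <- function(spectra, resolution_sigma = NULL) {
  chk(length(spectra$q) >= 5, "need at least 5 q values for a global fit")
  sig <- resolution_sigma %||% spectra$resolution_sigma
  chk(!is.null(sig) && sig > 0, "resolution width required")
  q <- spectra$q
  om <- spectra$omega
  nq <- length(q)
  w <- 1 / pmax(spectra$err, 1e-12)

  model_q <- function(k, d, a, gi, beta, bg) {
    a0 <- eisf_sphere(q[k], a)
    gg <- d * q[k]^2
    clean <- a0 * lorentz(om, gg) + (1 - a0) * lorentz(om, gg + gi)
    beta * convolve_resolution(clean, om, sig) + bg
  }
  # parameters: log D_app, log a, log gamma_int, log beta (per q), bg
  unpack <- function(p) {
    list(d = exp(p[1]), a = exp(p[2]), gi = exp(p[3]),
         beta = exp(p[3 + seq_len(nq)]), bg = p[4 + nq])
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    unlist(lapply(seq_len(nq), function(k) {
      (spectra$S[, k] - model_q(k, u$d, u$a, u$gi, u$beta[k], u$bg)) * w[, k]
    }))
  }
  # width heuristic for the start: half-width at half-max of the lowest-q
  # spectrum, divided by q^2
  s1 <- spectra$S[, 1]
  hm <- which(s1 > max(s1) / 2)
  d0 <- max((om[max(hm)] - om[min(hm)]) / 2 / q[1]^2, 0.5)
  starts <- lapply(c(1, 2, 4), function(a0) {
    c(log(d0), log(a0), log(10), rep(log(1), nq), 0)
  })
  lower <- c(log(1e-3), log(1e-3), log(1e-3), rep(log(1e-6), nq), -Inf)
  upper <- c(log(1e3), log(50), log(1e4), rep(log(1e6), nq), Inf)
  fit <- lm_multistart(resid_fn, starts, lower = lower, upper = upper,
                       control = nls.lm.control(maxiter = 400))
  u <- unpack(fit$par)
  if (max(q) * u$a > 4 * pi) {
    warning("qa exceeds the validity range of the sphere EISF model")
  }
  se <- lm_se(fit)
  dof <- length(fit$fvec) - length(fit$par)
  structure(list(D_app = u$d, D_app_se = u$d * se[1],
                 a = u$a, a_se = u$a * se[2],
                 gamma_int = u$gi, gamma_int_se = u$gi * se[3],
                 beta = u$beta, background = u$bg,
                 Gamma_g = u$d * q^2, q = q,
                 chi2_red = fit$deviance / dof, fit = fit),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("<nbs_result> D_app = ", format(x$D_app, digits = 4), " +/- ",
      format(x$D_app_se, digits = 2), " A^2/ns; a = ",
      format(x$a, digits = 4), " +/- ", format(x$a_se, digits = 2),
      " A; Gamma_int = ", format(x$gamma_int, digits = 3),
      " 1/ns (chi2_red = ", format(x$chi2_red, digits = 3), ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.nbs_result <- function(object, ...) {
  c(D_app = object$D_app, a = object$a, gamma_int = object$gamma_int)
}
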