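# Mass-weighted cartesian principal component analysis of superposed
# trajectories: collective displacement modes, per-mode RMSF, and
# projection autocorrelation times.

#' Mass-weighted cartesian PCA of a trajectory
#'
#' Diagonalizes the mass-weighted covariance matrix of the selected
#' particle coordinates (after rigid-body superposition). Eigenvectors are
#' orthonormal collective displacement modes in the mass-weighted basis;
#' eigenvalues carry the positional variance (Angstrom^2 amu) and sum to
#' the total weighted variance.
#'
#' @param traj a superposed [trajectory()].
#' @param exclude_residues residue numbers excluded from the analysis
#'   (e.g. a flexible charged loop whose dynamics would dominate the first
#'   components).
#' @param selection logical/integer particle selection; default backbone
#'   plus C-beta particles.
#' @param n_modes number of eigenpairs to keep (default all).
#' @return object of class `pca_model`: `mean` (particles x 3), `evecs`
#'   (3n x k, mass-weighted basis), `evals`, `projections` (frames x k),
#'   `atoms` (selected metadata), `masses`, `frame_interval`,
#'   `excluded_residues`, `total_variance`.
#' @export
cartesian_pca <- function(traj, exclude_residues = NULL, selection = NULL,
                          n_modes = NULL) {
  at <- traj$atoms
  if (is.null(selection)) {
    selection <- at$backbone | at$name %in% "CB"
  }
  sel <- if (is.logical(selection)) which(selection) else as.integer(selection)
  if (!is.null(exclude_residues)) {
    sel <- sel[!(at$resid[sel] %in% exclude_residues)]
  }
  chk(length(sel) >= 2, "selection too small for PCA")
  co <- traj$coords[, sel, , drop = FALSE]
  nf <- dim(co)[1]
  n <- length(sel)
  if (nf < 3 * n) {
    warning("fewer frames than coordinate dimensions; covariance is ",
            "rank-deficient")
  }
  x <- matrix(co, nf, n * 3) # columns: particle-major per axis blocks
  # reorder to particle-interleaved (x1 y1 z1 x2 ...) for readability
  ord <- as.vector(t(matrix(seq_len(3 * n), n, 3)))
  x <- x[, ord, drop = FALSE]
  mu <- colMeans(x)
  w <- rep(sqrt(at$mass[sel]), each = 3)
  xw <- sweep(sweep(x, 2, mu), 2, w, "*")
  cv <- crossprod(xw) / nf
  e <- eigen(cv, symmetric = TRUE)
  k <- if (is.null(n_modes)) ncol(e$vectors) else min(n_modes, ncol(e$vectors))
  evecs <- e$vectors[, seq_len(k), drop = FALSE]
  evals <- pmax(e$values[seq_len(k)], 0)
  proj <- xw %*% evecs
  structure(list(mean = matrix(mu, n, 3, byrow = TRUE),
                 evecs = evecs, evals = evals, projections = proj,
                 atoms = at[sel, , drop = FALSE],
                 masses = at$mass[sel],
                 frame_interval = traj$frame_interval,
                 excluded_residues = exclude_residues,
                 total_variance = sum(diag(cv))),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(10, length(x$evals))
  cum <- cumsum(x$evals) / sum(x$evals)
  cat("<pca_model> ", nrow(x$atoms), " particles, ",
      nrow(x$projections), " frames\n", sep = "")
  cat("  leading eigenvalues (cumulative variance): ",
      paste0(format(x$evals[seq_len(k)], digits = 3), " (",
             format(100 * cum[seq_len(k)], digits = 3), "%)",
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

# mode-k displacement direction per particle in unweighted coordinates
mode_vector <- function(model, k) {
  v <- matrix(model$evecs[, k], ncol = 3, byrow = TRUE)
  v / sqrt(model$masses)
}

#' Per-particle RMSF of one PCA mode
#'
#' RMSF_k(particle) = sqrt(lambda_k) |v_k(particle)| / sqrt(m_particle),
#' i.e. the root-mean-square fluctuation the mode contributes in
#' unweighted coordinates.
#'
#' @param model a `pca_model`.
#' @param k mode index.
#' @return numeric vector, one value per selected particle (Angstrom).
#' @export
mode_rmsf <- function(model, k) {
  chk(k >= 1 && k <= length(model$evals), "mode index out of range")
  v <- matrix(model$evecs[, k], ncol = 3, byrow = TRUE)
  sqrt(model$evals[k]) * sqrt(rowSums(v^2)) / sqrt(model$masses)
}

#' Projection autocorrelation of PCA modes
#'
#' Normalized autocorrelation (1 at lag zero) of the mode projections,
#' with a single-exponential decay-time estimate per mode.
#'
#' @param model a `pca_model`.
#' @param modes mode indices (default first 10).
#' @param lag_max maximal lag in frames.
#' @return list of per-mode results: `lag` (ns), `acf`, `tau` (ns).
#' @export
projection_acf <- function(model, modes = NULL, lag_max = NULL) {
  if (is.null(modes)) modes <- seq_len(min(10, length(model$evals)))
  chk(all(modes >= 1 & modes <= length(model$evals)),
      "mode index out of range")
  nf <- nrow(model$projections)
  if (is.null(lag_max)) lag_max <- floor(nf / 2)
  dt <- model$frame_interval
  out <- lapply(modes, function(k) {
    a <- acf_fft(model$projections[, k], lag_max)
    lag <- (0:lag_max) * dt
    # decay time from the initial decay only: the ACF tail of a trajectory
    # a few correlation times long is dominated by sample-mean bias
    cut <- which(a < 0.3)
    imax <- if (length(cut)) max(cut[1], 10) else length(a)
    ft <- fit_exp_sum(lag[1:imax], a[1:imax], 1,
                      t_range = c(dt, lag[imax] + dt))
    list(mode = k, lag = lag, acf = a, tau = ft$tau)
  })
  names(out) <- paste0("mode", modes)
  out
}
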