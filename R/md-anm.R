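# Anisotropic network model: pairwise-spring Hessian on C-alpha (or bead)
# nodes, normal modes, and per-residue mode mobility.

#' Anisotropic network model of a structure
#'
#' Builds the standard ANM Hessian (uniform springs between node pairs
#' within `cutoff`) and diagonalizes it. A connected network has exactly
#' six near-zero eigenvalues (rigid translations/rotations).
#'
#' @param coords node coordinates (n x 3, Angstrom), typically C-alpha.
#' @param cutoff spring cutoff distance (Angstrom).
#' @param gamma_spring uniform spring constant.
#' @return object of class `anm_model`: `evals` (ascending), `evecs`
#'   (3n x 3n), `coords`, `cutoff`, `gamma_spring`, `n_components`
#'   (connected components of the spring network).
#' @export
anm_modes <- function(coords, cutoff = 15, gamma_spring = 1) {
  n <- nrow(coords)
  chk(n >= 2, "need at least 2 nodes")
  chk(cutoff > 0 && gamma_spring > 0, "cutoff and spring must be positive")
  d2 <- as.matrix(dist(coords))^2
  contact <- d2 <= cutoff^2 & d2 > 0
  # connected components by repeated neighbor expansion
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    members <- s
    comp[s] <- cid
    repeat {
      nb <- which(comp == 0L & colSums(contact[members, , drop = FALSE]) > 0)
      if (length(nb) == 0) break
      comp[nb] <- cid
      members <- nb
    }
  }
  if (cid > 1L) {
    warning("spring network is disconnected: ", cid, " components of sizes ",
            paste(table(comp), collapse = ", "))
  }
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    js <- which(contact[i, ] & seq_len(n) > i)
    for (j in js) {
      dv <- coords[j, ] - coords[i, ]
      blk <- -gamma_spring * tcrossprod(dv) / sum(dv^2)
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  e <- eigen(h, symmetric = TRUE)
  ord <- order(e$values)
  structure(list(evals = e$values[ord],
                 evecs = e$vectors[, ord, drop = FALSE],
                 coords = coords, cutoff = cutoff,
                 gamma_spring = gamma_spring, n_components = cid),
            class = "anm_model")
}

#' @export
print.anm_model <- function(x, ...) {
  nz <- sum(x$evals < 1e-8 * max(x$evals))
  cat("<anm_model> ", nrow(x$coords), " nodes, cutoff ", x$cutoff,
      " A; ", nz, " near-zero modes\n", sep = "")
  cat("  slowest internal eigenvalues: ",
      paste(format(x$evals[(nz + 1):min(nz + 5, length(x$evals))],
                   digits = 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-node mobility of an ANM mode
#'
#' Displacement magnitude per node of normal mode `k` (counted from the
#' slowest internal mode, i.e. after the six rigid-body modes of a
#' connected network).
#'
#' @param model an `anm_model`.
#' @param k internal mode index (1 = slowest internal mode).
#' @return numeric vector of per-node displacement magnitudes.
#' @export
anm_mobility <- function(model, k = 1) {
  nz <- sum(model$evals < 1e-8 * max(model$evals))
  idx <- nz + k
  chk(idx <= length(model$evals), "mode index out of range")
  v <- matrix(model$evecs[, idx], ncol = 3, byrow = TRUE)
  sqrt(rowSums(v^2))
}
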