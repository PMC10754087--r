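# Rigid-body superposition (Kabsch) of trajectory frames onto a reference.

# optimal rotation/translation of P (n x 3) onto Q (n x 3), least squares
kabsch <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rot = rot, cp = cp, cq = cq)
}

#' Remove global translation and rotation from a trajectory
#'
#' Least-squares rigid superposition of every frame onto a reference
#' structure over a fit selection (by default the secondary-structure
#' backbone particles, mirroring the usual helix/sheet backbone fit).
#' All particles are transformed; only the selection defines the fit.
#'
#' @param traj a [trajectory()].
#' @param reference reference coordinates (particles x 3); default = first
#'   frame.
#' @param selection integer or logical particle selection for the fit;
#'   default = `atoms$ss & atoms$backbone`.
#' @return the superposed [trajectory()], with per-frame RMSD (over the
#'   selection) in `$rmsd`.
#' @export
superpose <- function(traj, reference = NULL, selection = NULL) {
  co <- traj$coords
  nf <- dim(co)[1]
  if (is.null(selection)) selection <- traj$atoms$ss & traj$atoms$backbone
  sel <- if (is.logical(selection)) which(selection) else as.integer(selection)
  chk(length(sel) >= 3, "need at least 3 particles in the fit selection")
  if (is.null(reference)) reference <- co[1, , ]
  chk(is.matrix(reference) && nrow(reference) == dim(co)[2],
      "reference must be a particles x 3 matrix")
  qsel <- reference[sel, , drop = FALSE]
  out <- array(0, dim(co))
  rmsd <- numeric(nf)
  for (j in seq_len(nf)) {
    pj <- co[j, , ]
    k <- kabsch(pj[sel, , drop = FALSE], qsel)
    moved <- sweep(pj, 2, k$cp) %*% t(k$rot)
    moved <- sweep(moved, 2, k$cq, "+")
    out[j, , ] <- moved
    rmsd[j] <- sqrt(mean(rowSums((moved[sel, , drop = FALSE] - qsel)^2)))
  }
  res <- trajectory(out, traj$atoms, traj$frame_interval)
  res$rmsd <- rmsd
  res$truth <- traj$truth
  res
}
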