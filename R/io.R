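# Plain-text I/O: photon streams and correlation curves as TSV, neutron
# tables as whitespace-delimited text with commented headers, structures
# via PDB (bio3d).

#' Read and write photon streams as TSV
#'
#' Columns: t (ps), channel, source, microtime (ps), mol, species.
#'
#' @param stream a `photon_stream`.
#' @param path file path.
#' @param duration measurement duration (s) stored/recovered via a header
#'   comment.
#' @return `read_photon_stream` returns a `photon_stream`.
#' @export
write_photon_stream <- function(stream, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# duration_s\t", attr(stream, "duration")), con)
  write.table(as.data.frame(stream), con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path, duration = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^# duration_s", first)) {
    duration <- as.numeric(sub("^# duration_s\t", "", first))
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  chk(!is.null(duration), "duration not found in header; supply it")
  chk(all(c("t", "channel", "source") %in% names(df)),
      "stream file lacks required columns")
  df <- df[order(df$t), , drop = FALSE]
  structure(df, class = c("photon_stream", "data.frame"),
            duration = duration, config = NULL)
}

#' Write/read a correlation curve as TSV (lag_s, G, err)
#'
#' @param curve a `correlation_curve`.
#' @param path file path.
#' @return `read_correlation` returns a `correlation_curve`.
#' @export
write_correlation <- function(curve, path) {
  df <- data.frame(lag_s = curve$lag, G = curve$G, err = curve$err,
                   npairs = curve$npairs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pair\t", attr(curve, "pair") %||% "NA",
                    "\tnormalization\t",
                    attr(curve, "normalization") %||% "NA"), con)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_correlation
#' @export
read_correlation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- data.frame(lag = df$lag_s, G = df$G, err = df$err,
                    npairs = df$npairs %||% NA_real_)
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Neutron tables as whitespace-delimited text
#'
#' `write_isf`/`read_isf` handle I(q, tau) (columns: q, tau_ns, I, err);
#' `write_qens`/`read_qens` handle S(q, omega) (columns: q, omega, S,
#' err; resolution width in a header comment).
#'
#' @param x an `isf` or `qens_spectra` object.
#' @param path file path.
#' @return readers return the corresponding object.
#' @export
write_isf <- function(x, path) {
  long <- data.frame(q = rep(x$q, each = length(x$tau)),
                     tau_ns = rep(x$tau, length(x$q)),
                     I = as.vector(x$I), err = as.vector(x$err))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# intermediate scattering function: q tau_ns I err", con)
  write.table(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isf
#' @export
read_isf <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#")
  q <- sort(unique(df$q))
  tau <- sort(unique(df$tau_ns))
  I <- err <- matrix(NA_real_, length(tau), length(q))
  iq <- match(df$q, q)
  it <- match(df$tau_ns, tau)
  I[cbind(it, iq)] <- df$I
  err[cbind(it, iq)] <- df$err
  structure(list(q = q, tau = tau, I = I, err = err, truth = NULL),
            class = "isf")
}

#' @rdname write_isf
#' @export
write_qens <- function(x, path) {
  long <- data.frame(q = rep(x$q, each = length(x$omega)),
                     omega = rep(x$omega, length(x$q)),
                     S = as.vector(x$S), err = as.vector(x$err))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# resolution_sigma ", x$resolution_sigma), con)
  writeLines("# backscattering spectra: q omega S err", con)
  write.table(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_isf
#' @export
read_qens <- function(path) {
  hdr <- readLines(path, n = 1)
  sig <- if (grepl("^# resolution_sigma", hdr)) {
    as.numeric(sub("^# resolution_sigma ", "", hdr))
  } else NULL
  df <- read.table(path, header = TRUE, comment.char = "#")
  q <- sort(unique(df$q))
  om <- sort(unique(df$omega))
  S <- err <- matrix(NA_real_, length(om), length(q))
  iq <- match(df$q, q)
  io <- match(df$omega, om)
  S[cbind(io, iq)] <- df$S
  err[cbind(io, iq)] <- df$err
  structure(list(q = q, omega = om, S = S, err = err,
                 resolution_sigma = sig, truth = NULL),
            class = "qens_spectra")
}

#' Read a structure from PDB as a single-frame trajectory
#'
#' Thin wrapper over bio3d's PDB reader; C-alpha and backbone flags are
#' derived from atom names, masses default to residue-independent 110 amu
#' unless `mass` is supplied.
#'
#' @param path PDB file path.
#' @param mass per-atom masses (amu) or a single value.
#' @return a [trajectory()] with one frame.
#' @export
read_trajectory_pdb <- function(path, mass = 110) {
  chk(requireNamespace("bio3d", quietly = TRUE),
      "bio3d is required for PDB input")
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  at <- pdb$atom
  atoms <- data.frame(
    mass = rep_len(mass, nrow(at)),
    resid = at$resno,
    chain = at$chain,
    name = at$elety,
    backbone = at$elety %in% c("N", "CA", "C", "O"),
    ss = TRUE
  )
  co <- array(0, c(1, nrow(at), 3))
  co[1, , ] <- xyz
  trajectory(co, atoms, frame_interval = 1)
}
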