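# Photon-pair correlation on arbitrary lag grids. Small lags are counted
# exactly photon-pair by photon-pair (two-pointer sweep in C); large lags of
# logarithmic grids use a binned intensity-trace estimator. Normalization is
# the symmetric (per-lag-bin) variant of the arbitrary-bin photon correlator.

#' Lag grids for photon correlation
#'
#' `lag_grid_linear()` builds the nanosecond-FCS grid: uniform bins of
#' `bin` seconds spanning `[-window, window]` (both branches of the
#' correlation on one axis). `lag_grid_log()` builds log-spaced bins from
#' `lag_min` to `lag_max`.
#'
#' @param window,bin linear-grid half-width and bin width (s).
#' @param lag_min,lag_max,per_decade log-grid range (s) and bin density.
#' @return numeric vector of bin edges (s).
#' @export
lag_grid_linear <- function(window = 1e-6, bin = 1e-9) {
  chk(window > 0 && bin > 0 && bin <= window, "invalid linear grid")
  seq(-window, window, by = bin)
}

#' @rdname lag_grid_linear
#' @export
lag_grid_log <- function(lag_min = 1e-9, lag_max = 1, per_decade = 16) {
  chk(lag_min > 0 && lag_max > lag_min, "invalid log grid")
  n <- ceiling(log10(lag_max / lag_min) * per_decade)
  10^seq(log10(lag_min), log10(lag_max), length.out = n + 1)
}

# Channel pairings per correlation curve. Autocorrelation bands use the
# crossed-polarization pairing (afterpulsing-immune); cross-band curves
# use matched polarizations so that any per-channel detection delay
# cancels within each pairing instead of smearing the antibunching dip.
channel_group <- function(pair) {
  switch(pair,
    DxD = list(cbind(a = 1L, b = 2L)),
    AxA = list(cbind(a = 3L, b = 4L)),
    AxD = list(cbind(a = 3L, b = 1L), cbind(a = 4L, b = 2L)),
    DxA = list(cbind(a = 1L, b = 3L), cbind(a = 2L, b = 4L)),
    stop("unknown channel pair: ", pair, call. = FALSE)
  )
}

#' Correlate a photon stream
#'
#' Computes the normalized intensity correlation G(tau) between two
#' detection-channel groups directly from photon arrival times on an
#' arbitrary lag-bin grid. For the autocorrelation pairs (`DxD`, `AxA`) the
#' parallel and perpendicular polarization channels are cross-correlated
#' (afterpulsing-immune pairing); `AxD` correlates the acceptor against the
#' donor band. When `bursts` is given, only photons inside the supplied
#' bursts are correlated (per-burst pair counting with duration-weighted
#' accidental normalization).
#'
#' @param stream a `photon_stream`.
#' @param pair one of "DxD", "AxA", "AxD", "DxA".
#' @param edges lag-bin edges in seconds (see [lag_grid_linear()]).
#' @param bursts optional `burst_set` restricting the correlation.
#' @param normalization "symmetric" (G -> 1 for uncorrelated signals) or
#'   "none" (pair rate density, for branch subtraction).
#' @param branch "both" keeps the grid as given; "pq" / "qp" fold to
#'   positive lags of the forward / reversed channel order.
#' @param split lag (s) above which log-grid bins switch to the binned
#'   intensity-trace estimator (full-stream mode only). Set `Inf` to force
#'   exact pair counting everywhere.
#' @param source excitation-source filter (default donor excitation).
#' @return data.frame of class `correlation_curve` with columns `lag` (bin
#'   centers, s), `G`, `err`, `npairs`.
#' @export
correlate <- function(stream, pair = "DxD", edges = lag_grid_linear(),
                      bursts = NULL, normalization = c("symmetric", "none"),
                      branch = c("both", "pq", "qp"), split = 2e-5,
                      source = 1L) {
  normalization <- match.arg(normalization)
  branch <- match.arg(branch)
  grp <- channel_group(pair)
  chk(!is.unsorted(stream$t), "photon stream must be sorted")

  if (branch == "qp") {
    grp <- lapply(grp, function(pp) cbind(a = pp[, "b"], b = pp[, "a"]))
  }
  if (branch != "both") edges <- edges[edges >= 0]
  chk(length(edges) >= 2 && all(diff(edges) > 0),
      "edges must be strictly increasing")

  keep <- stream$source == source
  edges_ps <- edges * 1e12
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  widths <- diff(edges_ps)
  counts <- numeric(length(centers))
  denom <- numeric(length(centers))

  if (is.null(bursts)) {
    t_tot <- attr(stream, "duration") * 1e12
    small <- abs(centers) <= split
    for (pp in grp) {
      ta <- stream$t[keep & stream$channel == pp[, "a"]]
      tb <- stream$t[keep & stream$channel == pp[, "b"]]
      chk(length(ta) >= 2 && length(tb) >= 2,
          "need at least 2 photons per channel group")
      if (any(small)) {
        sub <- range(which(small))
        e_small <- edges_ps[sub[1]:(sub[2] + 1)]
        counts[small] <- counts[small] + pair_count(ta, tb, e_small)
        denom[small] <- denom[small] +
          as.numeric(length(ta)) * length(tb) * widths[small] *
          (1 - abs(centers[small]) * 1e12 / t_tot) / t_tot
      }
      if (any(!small)) {
        big <- trace_correlate(ta, tb, edges_ps[c(which(!small),
                                                  max(which(!small)) + 1)],
                               t_tot, split * 1e12)
        counts[!small] <- counts[!small] + big$num
        denom[!small] <- denom[!small] + big$den
      }
    }
  } else {
    chk(nrow(bursts) > 0, "empty burst selection")
    t <- stream$t
    nb <- nrow(bursts)
    # burst id per photon (0 = outside every burst)
    bid_of <- function(idx) {
      bid <- findInterval(idx, bursts$start)
      bid[bid > 0 & idx > bursts$stop[pmax(bid, 1)]] <- 0L
      bid
    }
    # concatenate bursts with sentinel gaps larger than the lag window, so
    # one pair-count sweep counts within-burst pairs only
    gap_ps <- 2 * max(abs(edges_ps)) + 1
    ti <- pmax(bursts$t_stop - bursts$t_start, 1)
    for (pp in grp) {
      ia <- which(keep & stream$channel == pp[, "a"])
      ib <- which(keep & stream$channel == pp[, "b"])
      ba <- bid_of(ia)
      bb <- bid_of(ib)
      ia <- ia[ba > 0]; ba <- ba[ba > 0]
      ib <- ib[bb > 0]; bb <- bb[bb > 0]
      if (length(ia) < 1 || length(ib) < 1) next
      counts <- counts + pair_count(t[ia] + ba * gap_ps,
                                    t[ib] + bb * gap_ps, edges_ps)
      na_i <- tabulate(ba, nb)
      nb_i <- tabulate(bb, nb)
      wgt <- na_i * as.numeric(nb_i) / ti^2
      ov <- pmax(outer(ti, abs(centers) * 1e12, "-"), 0)
      denom <- denom + as.vector(crossprod(ov, wgt)) * widths
    }
    chk(sum(counts) > 0, "no photon pairs in burst selection")
    t_tot <- sum(bursts$t_stop - bursts$t_start)
  }

  # model-based Poisson errors: expected counts from the smoothed curve
  # level, not the bin's own noisy count (weights estimated from the
  # observed counts correlate with their own noise and bias weighted fits)
  if (normalization == "symmetric") {
    g <- ifelse(denom > 0, counts / denom, NA_real_)
    g_lvl <- stats::median(g[is.finite(g)])
    err <- ifelse(denom > 0, sqrt(pmax(denom * g_lvl, 1)) / denom, NA_real_)
  } else {
    # pair rate density: pairs per second of lag per second of data
    scale <- diff(edges) * t_tot * 1e-12
    g <- counts / scale
    err <- sqrt(pmax(stats::median(counts), 1)) / scale
  }

  out <- data.frame(lag = centers, G = g, err = err, npairs = counts)
  class(out) <- c("correlation_curve", "data.frame")
  attr(out, "pair") <- pair
  attr(out, "branch") <- branch
  attr(out, "normalization") <- normalization
  attr(out, "estimator") <- if (is.null(bursts)) {
    "symmetric arbitrary-bin (photon pairs <= split, binned trace above)"
  } else {
    "per-burst pair counting, duration-weighted accidental normalization"
  }
  out
}

# Binned intensity-trace estimator for large-lag log bins: counts the two
# channels into bins of width `base` (ps) and correlates the traces at the
# integer shift nearest each lag-bin center; per-shift symmetric
# normalization by the overlapping-window means.
trace_correlate <- function(ta, tb, edges_ps, t_tot, split_ps) {
  centers <- (edges_ps[-1] + edges_ps[-length(edges_ps)]) / 2
  num <- den <- numeric(length(centers))
  base0 <- split_ps / 10
  last_base <- -1
  xa <- xb <- NULL
  nbin <- 0L
  for (k in seq_along(centers)) {
    # quantize the trace resolution to powers of two of the base width so
    # consecutive lag bins reuse the same binned traces
    base <- base0 * 2^max(0, ceiling(log2(centers[k] / (50 * base0))))
    if (base != last_base) {
      nbin <- as.integer(ceiling(t_tot / base))
      xa <- tabulate(pmin(floor(ta / base) + 1, nbin), nbin)
      xb <- tabulate(pmin(floor(tb / base) + 1, nbin), nbin)
      last_base <- base
    }
    s <- round(centers[k] / base)
    if (s >= nbin) next
    i1 <- seq_len(nbin - s)
    prod_ab <- sum(as.numeric(xa[i1]) * as.numeric(xb[i1 + s]))
    na <- as.numeric(sum(xa[i1])); nb <- as.numeric(sum(xb[i1 + s]))
    # expected pairs in this lag bin from the trace product
    w_frac <- (edges_ps[k + 1] - edges_ps[k]) / base
    num[k] <- prod_ab * w_frac
    den[k] <- na * nb / (nbin - s) * w_frac
  }
  list(num = num, den = den)
}

#' Subtract the two branches of an nsFCS correlation
#'
#' Computes the pointwise difference of the forward (pq) and reversed (qp)
#' polarization branches of an unnormalized correlation and fits an
#' unconstrained double-exponential decay; a rotational contribution shows
#' up as a component at the rotational correlation time.
#'
#' @param curve_pq,curve_qp `correlation_curve` objects on the same grid.
#' @param fit_range lag range (s) used in the fit.
#' @return object of class `branch_difference` with the difference and the
#'   two fitted relaxation times.
#' @export
branch_difference <- function(curve_pq, curve_qp,
                              fit_range = c(1e-9, 1e-6)) {
  chk(nrow(curve_pq) == nrow(curve_qp) &&
        max(abs(curve_pq$lag - curve_qp$lag)) < 1e-15,
      "branch grids differ")
  delta <- curve_pq$G - curve_qp$G
  err <- sqrt(curve_pq$err^2 + curve_qp$err^2)
  sel <- curve_pq$lag >= fit_range[1] & curve_pq$lag <= fit_range[2] &
    is.finite(delta)
  tt <- curve_pq$lag[sel] * 1e9 # ns
  fit <- fit_exp_sum(tt, delta[sel], n_comp = 2,
                     weights = 1 / pmax(err[sel], 1e-12),
                     t_range = c(1, 300))
  structure(list(lag = curve_pq$lag, delta = delta, err = err,
                 tau_ns = fit$tau, amplitude = fit$amplitude,
                 deviance = fit$deviance),
            class = "branch_difference")
}

#' @export
print.branch_difference <- function(x, ...) {
  cat("<branch_difference> relaxation times ",
      paste(format(x$tau_ns, digits = 3), collapse = " and "),
      " ns\n", sep = "")
  invisible(x)
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("<correlation_curve> ", attr(x, "pair"), " (", attr(x, "branch"),
      "), ", nrow(x), " lag bins, ", format(sum(x$npairs), big.mark = ","),
      " pairs\n", sep = "")
  invisible(x)
}
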