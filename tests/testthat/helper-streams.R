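# Small deterministic fixtures built in code.

# hand-built photon stream from times in seconds
toy_stream <- function(t_s, channel = NULL, source = 1L, duration = NULL) {
  n <- length(t_s)
  if (is.null(channel)) channel <- rep(1L, n)
  df <- data.frame(t = round(t_s * 1e12), channel = channel,
                   source = rep_len(source, n),
                   microtime = NA_real_, mol = 1L, species = 1L)
  df <- df[order(df$t), ]
  structure(df, class = c("photon_stream", "data.frame"),
            duration = duration %||% (max(t_s) + 1e-3), config = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force DeltaT segmentation: scan gaps, collect maximal runs
burst_oracle <- function(t_ps, delta_t_ps, n_min, n_max) {
  runs <- list()
  start <- 1
  n <- length(t_ps)
  for (i in seq_len(n - 1)) {
    if (t_ps[i + 1] - t_ps[i] > delta_t_ps) {
      runs[[length(runs) + 1]] <- c(start, i)
      start <- i + 1
    }
  }
  runs[[length(runs) + 1]] <- c(start, n)
  keep <- Filter(function(r) {
    sz <- r[2] - r[1] + 1
    sz >= n_min && sz <= n_max
  }, runs)
  do.call(rbind, keep)
}

# brute-force ordered-pair lag histogram
pair_oracle <- function(ta, tb, edges) {
  cnt <- numeric(length(edges) - 1)
  for (i in seq_along(ta)) {
    for (j in seq_along(tb)) {
      lag <- tb[j] - ta[i]
      if (lag >= edges[1] && lag < edges[length(edges)]) {
        k <- findInterval(lag, edges)
        cnt[k] <- cnt[k] + 1
      }
    }
  }
  cnt
}
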