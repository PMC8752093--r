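#' Normalised correlation curve
#'
#' Holds the estimate of
#' \deqn{G(\tau) = \frac{\langle \delta F_A(t)\,\delta F_B(t+\tau)\rangle}
#'   {\langle F_A\rangle\langle F_B\rangle}}
#' on a lag grid, so that a perfectly uncorrelated channel pair gives
#' G close to 0 at every lag.
#'
#' @param lags Lag times in seconds, strictly increasing, all >= the bin
#'   width of the underlying trace.
#' @param G Correlation values.
#' @param G_err Per-lag dispersion estimate (NA where unavailable).
#' @param pair One of `"GG"`, `"RR"`, `"GR"`.
#' @param mean_rate_A,mean_rate_B Mean count rates of the two channels (Hz).
#' @param duration Trace duration (s).
#' @param bin_width Base bin width of the trace (s).
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, G_err = rep(NA_real_, length(lags)),
                              pair = c("GG", "RR", "GR"),
                              mean_rate_A = NA_real_, mean_rate_B = NA_real_,
                              duration = NA_real_, bin_width = min(lags)) {
  pair <- match.arg(pair)
  stopifnot(length(lags) == length(G), length(G) == length(G_err))
  if (any(diff(lags) <= 0)) stop("lags must be strictly increasing")
  if (!all(is.finite(G))) stop("G must be finite everywhere")
  structure(
    list(
      lags = lags, G = G, G_err = G_err, pair = pair,
      mean_rate_A = mean_rate_A, mean_rate_B = mean_rate_B,
      duration = duration, bin_width = bin_width
    ),
    class = "correlation_curve"
  )
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf(
    "correlation_curve %s: %d lags in [%.3g, %.3g] s, G[1] = %.4g\n",
    x$pair, length(x$lags), min(x$lags), max(x$lags), x$G[1]
  ))
  invisible(x)
}

# channel pair -> the two count vectors
.pair_channels <- function(trace, pair) {
  switch(pair,
    GG = list(a = trace$counts_G, b = trace$counts_G,
              ra = mean_count_rate(trace, "G"), rb = mean_count_rate(trace, "G")),
    RR = list(a = trace$counts_R, b = trace$counts_R,
              ra = mean_count_rate(trace, "R"), rb = mean_count_rate(trace, "R")),
    GR = list(a = trace$counts_G, b = trace$counts_R,
              ra = mean_count_rate(trace, "G"), rb = mean_count_rate(trace, "R"))
  )
}

# Symmetrically normalised correlation of two count vectors at integer lags
# (in bins): local means over the overlapping segments make the estimator
# robust to residual slow drifts. Shared by the direct and the multi-tau
# estimators so that both produce identical arithmetic on identical grids.
.corr_at_lags <- function(a, b, lags_bins) {
  n <- length(a)
  vapply(lags_bins, function(k) {
    if (k >= n) {
      return(NA_real_)
    }
    x <- a[seq_len(n - k)]
    y <- b[(k + 1):n]
    mx <- mean(x)
    my <- mean(y)
    if (mx <= 0 || my <= 0) {
      return(0)
    }
    mean(x * y) / (mx * my) - 1
  }, numeric(1))
}

#' Direct (brute-force) correlation estimator
#'
#' Computes the symmetrically normalised correlation at every integer
#' multiple of the bin width up to `max_lag`. Exact but O(n * n_lags); used
#' as the reference implementation against which the multi-tau estimator is
#' validated.
#'
#' @param trace An [intensity_trace()].
#' @param pair `"GG"`, `"RR"` or `"GR"`.
#' @param max_lag Largest lag in seconds; must be < duration / 2.
#' @param n_segments If > 1, the trace is split into this many contiguous
#'   blocks and `G_err` is the standard error of the per-block estimates.
#' @return A [correlation_curve()].
#' @export
correlate_direct <- function(trace, pair = c("GG", "RR", "GR"), max_lag,
                             n_segments = 0) {
  stopifnot(inherits(trace, "intensity_trace"))
  pair <- match.arg(pair)
  if (max_lag >= trace$duration / 2) {
    stop("max_lag must be smaller than half the trace duration")
  }
  ch <- .pair_channels(trace, pair)
  k_max <- floor(max_lag / trace$bin_width)
  if (k_max < 1) stop("max_lag shorter than one bin")
  lags_bins <- seq_len(k_max)
  G <- .corr_at_lags(ch$a, ch$b, lags_bins)
  G_err <- rep(NA_real_, k_max)
  if (n_segments > 1) {
    seg <- .segment_corr(ch$a, ch$b, lags_bins, n_segments,
      rebin = FALSE, m = NULL
    )
    G_err <- seg
  }
  correlation_curve(
    lags = lags_bins * trace$bin_width, G = G, G_err = G_err, pair = pair,
    mean_rate_A = ch$ra, mean_rate_B = ch$rb,
    duration = trace$duration, bin_width = trace$bin_width
  )
}

# multi-tau lag grid: level 0 has m linear lags at the base bin; every
# further level doubles the bin and contributes lags (m/2+1)..m in units of
# its own bin. Returns a list of (level, bin_mult, lags_bins).
.multitau_grid <- function(n_bins, bin_width, m, max_lag) {
  levels <- list()
  lev <- 0L
  repeat {
    mult <- 2^lev
    n_here <- floor(n_bins / mult)
    lags <- if (lev == 0L) seq_len(m) else (m / 2 + 1):m
    keep <- lags * mult * bin_width <= max_lag & lags < n_here
    if (lev > 0L && n_here < 2 * m) break
    if (!any(keep)) break
    levels[[length(levels) + 1]] <- list(
      level = lev, mult = mult, lags = lags[keep]
    )
    if (!all(keep)) break
    lev <- lev + 1L
  }
  levels
}

.rebin2 <- function(x) {
  n2 <- floor(length(x) / 2)
  x <- x[seq_len(2 * n2)]
  x[seq(1, 2 * n2, by = 2)] + x[seq(2, 2 * n2, by = 2)]
}

# run the multi-tau scheme on a pair of count vectors; returns data.frame
.multitau_engine <- function(a, b, bin_width, m, max_lag) {
  grid <- .multitau_grid(length(a), bin_width, m, max_lag)
  out_lags <- numeric(0)
  out_G <- numeric(0)
  for (lv in grid) {
    while (attr(a, "mult") %||% 1 < lv$mult) {
      a <- structure(.rebin2(a), mult = 2 * (attr(a, "mult") %||% 1))
      b <- structure(.rebin2(b), mult = attr(a, "mult"))
    }
    G <- .corr_at_lags(as.numeric(a), as.numeric(b), lv$lags)
    out_lags <- c(out_lags, lv$lags * lv$mult * bin_width)
    out_G <- c(out_G, G)
  }
  data.frame(lag = out_lags, G = out_G)
}

# blockwise standard error of G on a given lag grid
.segment_corr <- function(a, b, lags_bins, n_segments, rebin, m,
                          bin_width = NULL, max_lag = NULL) {
  n <- length(a)
  bounds <- floor(seq(0, n, length.out = n_segments + 1))
  per_seg <- sapply(seq_len(n_segments), function(i) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    if (rebin) {
      .multitau_engine(a[idx], b[idx], bin_width, m, max_lag)$G
    } else {
      .corr_at_lags(a[idx], b[idx], lags_bins)
    }
  })
  if (is.null(dim(per_seg))) per_seg <- matrix(per_seg, nrow = 1)
  apply(per_seg, 1, function(g) {
    g <- g[is.finite(g)]
    if (length(g) < 3) NA_real_ else sd(g) / sqrt(length(g))
  })
}

#' Multi-tau correlation estimator
#'
#' Quasi-logarithmic lag-grid estimator: `m_per_octave` linear lags at the
#' base bin width, then the counts are re-binned by a factor of two between
#' levels and each level contributes `m_per_octave / 2` further lags. The
#' symmetric normalisation is applied per level. `G_err` is a block-wise
#' standard error obtained by splitting the trace into `n_segments`
#' contiguous segments and repeating the estimate on each.
#'
#' @param trace An [intensity_trace()].
#' @param pair `"GG"`, `"RR"` or `"GR"`.
#' @param m_per_octave Lags per level; must be even (default 16).
#' @param max_lag Largest lag in seconds (default `min(1, duration / 20)`,
#'   which also keeps every lag inside half a segment).
#' @param n_segments Number of blocks for the error estimate (>= 10
#'   recommended; the default is 10).
#' @return A [correlation_curve()].
#' @export
correlate_multitau <- function(trace, pair = c("GG", "RR", "GR"),
                               m_per_octave = 16, max_lag = NULL,
                               n_segments = 10) {
  stopifnot(inherits(trace, "intensity_trace"))
  pair <- match.arg(pair)
  if (m_per_octave %% 2 != 0 || m_per_octave < 4) {
    stop("m_per_octave must be an even number >= 4")
  }
  if (is.null(max_lag)) max_lag <- min(1, trace$duration / 20)
  if (max_lag >= trace$duration / 2) {
    stop("max_lag must be smaller than half the trace duration")
  }
  if (trace$n_bins < 4 * m_per_octave) {
    stop("trace too short for the requested lag grid")
  }
  ch <- .pair_channels(trace, pair)
  full <- .multitau_engine(
    as.numeric(ch$a), as.numeric(ch$b),
    trace$bin_width, m_per_octave, max_lag
  )
  keep <- is.finite(full$G)
  G_err <- rep(NA_real_, nrow(full))
  if (n_segments > 1) {
    G_err <- .segment_corr(
      as.numeric(ch$a), as.numeric(ch$b),
      NULL, n_segments,
      rebin = TRUE, m = m_per_octave,
      bin_width = trace$bin_width, max_lag = max_lag
    )
    if (length(G_err) != nrow(full)) {
      # segments shorter than the full trace can lose deep levels
      G_err <- c(G_err, rep(NA_real_, nrow(full) - length(G_err)))[
        seq_len(nrow(full))
      ]
    }
  }
  correlation_curve(
    lags = full$lag[keep], G = full$G[keep], G_err = G_err[keep], pair = pair,
    mean_rate_A = ch$ra, mean_rate_B = ch$rb,
    duration = trace$duration, bin_width = trace$bin_width
  )
}
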