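#' Fit a mono-exponential photobleaching model to a trace
#'
#' The trace is re-binned to `coarse_bin` so that millisecond-scale diffusion
#' fluctuations average out, and the smoothed intensity is fitted with
#' \eqn{F(t) = F_0 e^{-t/\tau_b}}. If the fitted decay over the whole trace
#' is below 2% (or the fit does not converge) the model is flagged
#' `negligible` and the normalised decay is f(t) = 1.
#'
#' @param trace An [intensity_trace()].
#' @param channel `"G"` or `"R"`.
#' @param coarse_bin Re-binning width in seconds; the duration must be at
#'   least `10 * coarse_bin`.
#' @return An object of class `bleach_model` with fields `F0` (Hz), `tau_b`
#'   (s), `negligible` and `channel`.
#' @export
fit_bleach <- function(trace, channel = c("G", "R"), coarse_bin = 1) {
  stopifnot(inherits(trace, "intensity_trace"))
  channel <- match.arg(channel)
  if (trace$duration < 10 * coarse_bin) {
    stop("duration must be at least 10 * coarse_bin")
  }
  counts <- if (channel == "G") trace$counts_G else trace$counts_R
  per <- max(1L, as.integer(round(coarse_bin / trace$bin_width)))
  n_coarse <- floor(trace$n_bins / per)
  idx <- rep(seq_len(n_coarse), each = per)
  rate <- as.numeric(tapply(counts[seq_len(n_coarse * per)], idx, sum)) /
    (per * trace$bin_width)
  t_mid <- (seq_len(n_coarse) - 0.5) * per * trace$bin_width

  negligible <- function(F0) {
    structure(
      list(F0 = F0, tau_b = Inf, negligible = TRUE, channel = channel),
      class = "bleach_model"
    )
  }
  if (all(rate <= 0)) {
    return(negligible(mean(rate)))
  }

  # log-linear start, then weighted nonlinear refinement
  pos <- rate > 0
  start_fit <- lm(log(rate[pos]) ~ t_mid[pos])
  slope <- unname(coef(start_fit)[2])
  if (!is.finite(slope) || slope >= 0 ||
    1 - exp(slope * trace$duration) < 0.02) {
    # no decay trend worth modelling
    return(negligible(mean(rate)))
  }
  k0 <- -slope
  F00 <- unname(exp(coef(start_fit)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ F0 * exp(-k * t_mid),
      start = list(F0 = F00, k = k0),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("photobleaching fit did not converge; treating decay as negligible")
    return(negligible(mean(rate)))
  }
  p <- coef(fit)
  decay <- 1 - exp(-p[["k"]] * trace$duration)
  if (!is.finite(decay) || decay < 0.02) {
    return(negligible(mean(rate)))
  }
  structure(
    list(
      F0 = p[["F0"]], tau_b = 1 / p[["k"]],
      negligible = FALSE, channel = channel
    ),
    class = "bleach_model"
  )
}

#' Evaluate the normalised bleaching decay f(t)
#'
#' @param model A `bleach_model`.
#' @param t Times in seconds.
#' @return f(t) in (0, 1], with f(0) = 1.
#' @export
bleach_fraction <- function(model, t) {
  stopifnot(inherits(model, "bleach_model"))
  if (model$negligible) rep(1, length(t)) else exp(-t / model$tau_b)
}

#' @export
print.bleach_model <- function(x, ...) {
  if (x$negligible) {
    cat(sprintf("bleach_model (%s): negligible decay, F0 = %.4g Hz\n",
                x$channel, x$F0))
  } else {
    cat(sprintf("bleach_model (%s): F0 = %.4g Hz, tau_b = %.4g s\n",
                x$channel, x$F0, x$tau_b))
  }
  invisible(x)
}

#' Compensate photobleaching decay in a trace
#'
#' Applies the square-root detrending transform per channel,
#' \deqn{F_c(t) = F(t)/\sqrt{f(t)} + F_0\,(1 - \sqrt{f(t)}),}
#' which restores a stationary mean at the t = 0 intensity scale while
#' preserving the fluctuation statistics to first order. A `negligible`
#' model leaves the channel untouched.
#'
#' @param trace An [intensity_trace()].
#' @param model_G,model_R `bleach_model`s for the two channels (NULL skips
#'   the channel).
#' @return A detrended [intensity_trace()]; counts become real-valued.
#' @export
detrend <- function(trace, model_G = NULL, model_R = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  t_mid <- (seq_len(trace$n_bins) - 0.5) * trace$bin_width
  fix <- function(counts, model) {
    if (is.null(model) || model$negligible) {
      return(counts)
    }
    f <- bleach_fraction(model, t_mid)
    if (any(f <= 0)) stop("bleach fraction must stay positive")
    s <- sqrt(f)
    counts / s + model$F0 * trace$bin_width * (1 - s)
  }
  out <- trace
  out$counts_G <- fix(trace$counts_G, model_G)
  out$counts_R <- fix(trace$counts_R, model_R)
  out$metadata$detrended <- TRUE
  out
}

#' Photobleaching amplitude-correction factor
#'
#' The square-root detrend restores a stationary mean but leaves the
#' correlation amplitude attenuated by the time average of the normalised
#' decay, \eqn{\bar f = \frac{1}{T}\int_0^T f(t)\,dt}. The apparent molecule
#' number from a detrended trace therefore over-counts by \eqn{1/\bar f},
#' and is corrected by multiplying with this factor
#' (\eqn{\bar f = (\tau_b/T)(1 - e^{-T/\tau_b})} for the mono-exponential
#' model; 1 when the decay is negligible).
#'
#' @param model A `bleach_model`.
#' @param duration Trace duration in seconds.
#' @return The factor \eqn{\bar f} in (0, 1].
#' @export
bleach_amplitude_factor <- function(model, duration) {
  stopifnot(inherits(model, "bleach_model"), duration > 0)
  if (model$negligible) {
    return(1)
  }
  (model$tau_b / duration) * (1 - exp(-duration / model$tau_b))
}

#' Ensemble background estimate
#'
#' Median background count rates measured on cells without the fluorescent
#' label, per compartment. The analyte trace itself is never used to
#' estimate its own background.
#'
#' @param B_G,B_R Median background rates (Hz), >= 0.
#' @param source Compartment label the estimate refers to.
#' @param n_cells Number of cells the median was taken over (>= 1).
#' @return An object of class `background_estimate`.
#' @export
background_estimate <- function(B_G, B_R, source = "cytosol", n_cells = 1) {
  if (B_G < 0 || B_R < 0) stop("background rates must be >= 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  structure(
    list(B_G = B_G, B_R = B_R, source = source, n_cells = n_cells),
    class = "background_estimate"
  )
}

#' Correct a fitted molecule number for uncorrelated background
#'
#' Uncorrelated background light attenuates the correlation amplitude by
#' \eqn{((F-B)/F)^2}, where F is the measured mean count rate and B the
#' ensemble-median background, so the apparent molecule number over-counts
#' by the inverse factor. This applies the closed-form correction
#' \deqn{N_{corr} = N_{app}\,\left(\frac{F-B}{F}\right)^2.}
#'
#' @param N_apparent Fitted molecule number (from 1/G(0)).
#' @param mean_rate Measured mean count rate F of the trace (Hz).
#' @param background A [background_estimate()] or a single rate in Hz.
#' @param channel `"G"` or `"R"` (used when `background` is an estimate).
#' @return List with `N_corrected` and the applied `factor` ((F-B)/F)^2.
#' @export
correct_background <- function(N_apparent, mean_rate, background,
                               channel = c("G", "R")) {
  channel <- match.arg(channel)
  B <- if (inherits(background, "background_estimate")) {
    if (channel == "G") background$B_G else background$B_R
  } else {
    as.numeric(background)
  }
  if (mean_rate <= B) {
    stop("mean rate does not exceed the background; measurement unusable")
  }
  factor <- ((mean_rate - B) / mean_rate)^2
  list(N_corrected = N_apparent * factor, factor = factor)
}

#' Read a background table (compartment, channel, B_Hz, n_cells)
#'
#' @param path Tab-separated file with columns `compartment`, `channel`,
#'   `B_Hz`, `n_cells`.
#' @return A named list of [background_estimate()]s, one per compartment.
#' @export
read_background_table <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  out <- list()
  for (comp in unique(d$compartment)) {
    sub <- d[d$compartment == comp, ]
    g <- sub[sub$channel == "G", ]
    r <- sub[sub$channel == "R", ]
    out[[comp]] <- background_estimate(
      B_G = if (nrow(g)) g$B_Hz[1] else 0,
      B_R = if (nrow(r)) r$B_Hz[1] else 0,
      source = comp,
      n_cells = max(1, sub$n_cells)
    )
  }
  out
}
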