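#' Single-component 3D free-diffusion model function
#'
#' The autocorrelation of freely diffusing molecules in a 3D-Gaussian
#' observation volume:
#' \deqn{G(\tau) = \text{offset} + \frac{1}{N}
#'   \left(1+\frac{\tau}{\tau_D}\right)^{-1}
#'   \left(1+\frac{\tau}{\kappa^2\tau_D}\right)^{-1/2}.}
#' The amplitude G(0) - offset equals 1/N, the inverse of the mean number of
#' molecules in the effective volume; \eqn{\tau_D = \omega_{xy}^2/(4D)} is
#' the diffusion time.
#'
#' @param tau Lag times in seconds (vectorised).
#' @param N Mean occupancy, > 0.
#' @param tau_D Diffusion time in seconds, > 0.
#' @param kappa Structure parameter, > 0.
#' @param offset Long-lag baseline.
#' @return G values at `tau`.
#' @examples
#' model_3d_diffusion(1e-3, N = 5, tau_D = 1e-3, kappa = 5) # half amplitude
#' @export
model_3d_diffusion <- function(tau, N, tau_D, kappa, offset = 0) {
  stopifnot(N > 0, tau_D > 0, kappa > 0)
  offset + (1 / N) / ((1 + tau / tau_D) * sqrt(1 + tau / (kappa^2 * tau_D)))
}

#' Fit the 3D free-diffusion model to a correlation curve
#'
#' Weighted least squares (weights \eqn{1/G_{err}^2}) with the
#' Levenberg-Marquardt algorithm. The structure parameter is held fixed at
#' the calibrated value; amplitude, diffusion time and (optionally) a small
#' offset are floated. Lags shorter than `min_lag` (default five base bins)
#' are excluded to suppress shot-noise artefacts at the shortest lags.
#' Non-convergence is reported through `converged = FALSE`, never through
#' silent defaults.
#'
#' @param curve A [correlation_curve()] with at least 20 lags spanning two
#'   decades.
#' @param kappa Structure parameter from calibration.
#' @param weights Optional explicit weights; default derives them from
#'   `G_err`.
#' @param fit_offset Float a baseline offset term (default TRUE).
#' @param min_lag Shortest lag included in the fit; default
#'   `5 * curve$bin_width`.
#' @return An object of class `diffusion_fit` with fields `N`, `tau_D`,
#'   `offset`, `amplitude`, `kappa`, `chi2_reduced`, `se_N`, `se_tauD`,
#'   `converged` and `diagnostic`.
#' @export
fit_curve <- function(curve, kappa, weights = NULL, fit_offset = TRUE,
                      min_lag = NULL) {
  stopifnot(inherits(curve, "correlation_curve"), kappa > 0)
  if (is.null(min_lag)) min_lag <- 5 * curve$bin_width
  sel <- curve$lags >= min_lag & is.finite(curve$G)
  tau <- curve$lags[sel]
  G <- curve$G[sel]
  if (length(tau) < 20 || max(tau) / min(tau) < 100) {
    stop("curve must provide >= 20 lags spanning at least two decades")
  }

  if (is.null(weights)) {
    err <- curve$G_err[sel]
    good <- is.finite(err) & err > 0
    if (any(good)) {
      err[!good] <- median(err[good])
      weights <- 1 / err^2
    } else {
      weights <- rep(1, length(tau))
    }
  }

  failed <- function(msg) {
    structure(
      list(
        N = NA_real_, tau_D = NA_real_, offset = NA_real_,
        amplitude = NA_real_, kappa = kappa, chi2_reduced = NA_real_,
        se_N = NA_real_, se_tauD = NA_real_, converged = FALSE,
        n_points = length(tau), diagnostic = msg
      ),
      class = "diffusion_fit"
    )
  }

  A0 <- max(G)
  if (!is.finite(A0) || A0 <= 0) {
    return(failed("no positive correlation amplitude"))
  }
  below <- which(G <= A0 / 2)
  tau0 <- if (length(below)) tau[below[1]] else sqrt(min(tau) * max(tau))
  tau_lo <- curve$bin_width
  tau_hi <- curve$duration / 10
  tau0 <- min(max(tau0, tau_lo * 1.01), tau_hi * 0.99)
  A_lo <- 1e-6 # N upper bound 1e6
  A_hi <- 1e3 # N lower bound 1e-3
  A0 <- min(max(A0, A_lo * 1.01), A_hi * 0.99)

  df <- data.frame(tau = tau, G = G)
  form <- if (fit_offset) {
    G ~ offset + A / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
  } else {
    G ~ A / ((1 + tau / tauD) * sqrt(1 + tau / (kappa^2 * tauD)))
  }
  start <- if (fit_offset) {
    list(A = A0, tauD = tau0, offset = 0)
  } else {
    list(A = A0, tauD = tau0)
  }
  lower <- if (fit_offset) c(A_lo, tau_lo, -1) else c(A_lo, tau_lo)
  upper <- if (fit_offset) c(A_hi, tau_hi, 1) else c(A_hi, tau_hi)

  lm_error <- NULL
  fit <- tryCatch(
    minpack.lm::nlsLM(form,
      data = df, start = start, lower = lower, upper = upper,
      weights = weights,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-10, ptol = 1e-10
      )
    ),
    error = function(e) {
      lm_error <<- conditionMessage(e)
      NULL
    }
  )
  if (is.null(fit)) {
    return(failed(paste("Levenberg-Marquardt did not converge:", lm_error)))
  }
  p <- coef(fit)
  A <- p[["A"]]
  tau_D <- p[["tauD"]]
  off <- if (fit_offset) p[["offset"]] else 0
  if (A <= A_lo * 1.0001) {
    f <- failed("amplitude indistinguishable from zero: no correlated signal")
    f$diagnostic <- paste(f$diagnostic, "(no co-diffusion)")
    return(f)
  }
  ses <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    rep(NA_real_, length(p))
  })
  rss <- sum(weights * resid(fit)^2)
  n_par <- length(p)
  structure(
    list(
      N = 1 / A, tau_D = tau_D, offset = off, amplitude = A, kappa = kappa,
      chi2_reduced = rss / (length(tau) - n_par),
      se_N = unname(ses["A"]) / A^2, se_tauD = unname(ses["tauD"]),
      converged = TRUE, n_points = length(tau), diagnostic = "ok"
    ),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "diffusion_fit: N = %.4g, tau_D = %.4g s, offset = %.3g, chi2_red = %.3g\n",
      x$N, x$tau_D, x$offset, x$chi2_reduced
    ))
  } else {
    cat(sprintf("diffusion_fit: NOT converged (%s)\n", x$diagnostic))
  }
  invisible(x)
}

#' Cross-correlation amplitude read-out
#'
#' Estimates G_x(0) as the mean of the correlation values over the shortest
#' lags of the curve, with a standard error propagated from the block-wise
#' `G_err`. Used as the co-diffusion read-out: for independently diffusing
#' species the amplitude is zero within error.
#'
#' @param curve A [correlation_curve()] (typically the GR pair).
#' @param n_lags Number of leading lags averaged (default 8).
#' @return List with `G0`, `se` and `significant` (G0 > 3 se).
#' @export
crosscorr_amplitude <- function(curve, n_lags = 8) {
  stopifnot(inherits(curve, "correlation_curve"))
  n <- min(n_lags, length(curve$G))
  G0 <- mean(curve$G[seq_len(n)])
  err <- curve$G_err[seq_len(n)]
  se <- if (all(is.finite(err))) {
    sqrt(sum(err^2)) / n
  } else {
    sd(curve$G[seq_len(n)]) / sqrt(n)
  }
  list(G0 = G0, se = se, significant = is.finite(se) && G0 > 3 * se)
}
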