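#' Instrument calibration from a reference dye
#'
#' FCS measurements yield instrument-dependent quantities: a diffusion time
#' \eqn{\tau_D} and a molecule number N. A calibration measurement on a dye
#' of known diffusion coefficient \eqn{D_{ref}} converts them to
#' instrument-independent ones via
#' \deqn{\omega_{xy} = \sqrt{4 D_{ref} \tau_{D,ref}}, \qquad
#'   V_{eff} = \pi^{3/2} \omega_{xy}^2 (\kappa\,\omega_{xy}).}
#' Each colour channel is calibrated independently with its own dye because
#' chromatic aberration makes the two detection volumes differ.
#'
#' @param dye_fit A converged [fit_curve()] result for the dye measurement.
#' @param D_ref Literature diffusion coefficient of the dye (um^2/s), > 0.
#' @param kappa Structure parameter of the detection volume.
#' @param dye_name Dye label (e.g. "Alexa488").
#' @param channel `"G"` or `"R"`.
#' @return An object of class `fcs_calibration` with `omega_xy` (um),
#'   `kappa`, `V_eff` (fL), `D_ref`, `tau_D_ref`, `dye_name`, `channel`.
#' @examples
#' fit <- structure(list(tau_D = 3.906e-5, converged = TRUE),
#'   class = "diffusion_fit"
#' )
#' calibrate(fit, D_ref = 400, kappa = 5)$omega_xy # 0.25 um
#' @export
calibrate <- function(dye_fit, D_ref, kappa, dye_name = "dye",
                      channel = c("G", "R")) {
  stopifnot(inherits(dye_fit, "diffusion_fit"))
  channel <- match.arg(channel)
  if (!isTRUE(dye_fit$converged)) {
    stop("reference dye fit did not converge; cannot calibrate")
  }
  if (D_ref <= 0) stop("D_ref must be positive")
  omega_xy <- sqrt(4 * D_ref * dye_fit$tau_D)
  structure(
    list(
      omega_xy = omega_xy, kappa = kappa,
      V_eff = effective_volume(omega_xy, kappa),
      D_ref = D_ref, tau_D_ref = dye_fit$tau_D,
      dye_name = dye_name, channel = channel
    ),
    class = "fcs_calibration"
  )
}

#' Ground-truth calibration from a known detection volume
#'
#' For synthetic data the detection volume is known exactly, so a
#' calibration object can be built directly instead of via a dye
#' measurement.
#'
#' @param volume A [detection_volume()].
#' @param channel `"G"` or `"R"`.
#' @return An `fcs_calibration`.
#' @export
calibration_from_volume <- function(volume, channel = c("G", "R")) {
  stopifnot(inherits(volume, "detection_volume"))
  channel <- match.arg(channel)
  structure(
    list(
      omega_xy = volume$omega_xy, kappa = volume$kappa,
      V_eff = volume$V_eff, D_ref = NA_real_, tau_D_ref = NA_real_,
      dye_name = "ground truth", channel = channel
    ),
    class = "fcs_calibration"
  )
}

#' @export
print.fcs_calibration <- function(x, ...) {
  cat(sprintf(
    "fcs_calibration (%s, %s): omega_xy = %.4g um, kappa = %.3g, V_eff = %.4g fL\n",
    x$channel, x$dye_name, x$omega_xy, x$kappa, x$V_eff
  ))
  invisible(x)
}

#' Convert a diffusion time to a diffusion coefficient
#'
#' \eqn{D = \omega_{xy}^2 / (4 \tau_D)} with the calibrated lateral waist.
#'
#' @param fit A converged `diffusion_fit` (or a bare tau_D in seconds).
#' @param calib An `fcs_calibration`.
#' @return Diffusion coefficient in um^2/s.
#' @export
to_diffusion <- function(fit, calib) {
  stopifnot(inherits(calib, "fcs_calibration"))
  tau_D <- if (inherits(fit, "diffusion_fit")) {
    if (!isTRUE(fit$converged)) stop("fit did not converge")
    fit$tau_D
  } else {
    as.numeric(fit)
  }
  calib$omega_xy^2 / (4 * tau_D)
}

#' Convert a corrected molecule number to a molar concentration
#'
#' \eqn{c = N / (N_A V_{eff})}, reported in nM.
#'
#' @param N_corrected Background-corrected molecule number, > 0 (0 allowed
#'   as a limit).
#' @param calib An `fcs_calibration`.
#' @return Concentration in nM.
#' @export
to_concentration <- function(N_corrected, calib) {
  stopifnot(inherits(calib, "fcs_calibration"))
  if (any(N_corrected < 0)) stop("N_corrected must be >= 0")
  N_corrected / (.PER_UM3_PER_NM * calib$V_eff)
}

#' Write a calibration to YAML
#'
#' @param calib An `fcs_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "fcs_calibration"))
  yaml::write_yaml(unclass(calib), path, precision = 15)
  invisible(path)
}

#' Read a calibration written by [write_calibration()]
#'
#' @param path YAML path.
#' @return An `fcs_calibration`.
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  structure(y, class = "fcs_calibration")
}
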