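#' Confocal detection volume
#'
#' Describes the observation volume of a confocal FCS instrument as a
#' three-dimensional Gaussian molecular detection function (MDF),
#' \deqn{MDF(x,y,z) = \exp(-2(x^2+y^2)/\omega_{xy}^2 - 2 z^2/\omega_z^2),}
#' parameterised by the lateral \eqn{1/e^2} radius \eqn{\omega_{xy}} and the
#' structure parameter \eqn{\kappa = \omega_z/\omega_{xy}}. The effective
#' volume used to convert molecule numbers into concentrations is
#' \deqn{V_{eff} = \pi^{3/2}\,\omega_{xy}^2\,\omega_z,}
#' in cubic micrometres (1 \eqn{\mu m^3} = 1 fL).
#'
#' @param omega_xy Lateral \eqn{1/e^2} radius in micrometres. Must be > 0.
#' @param kappa Structure parameter \eqn{\omega_z/\omega_{xy}}, dimensionless,
#'   must be >= 1.
#' @return An object of class `detection_volume` with fields `omega_xy`,
#'   `kappa`, `omega_z` and `V_eff` (fL).
#' @examples
#' v <- detection_volume(omega_xy = 0.25, kappa = 5)
#' v$V_eff # about 0.435 fL
#' @export
detection_volume <- function(omega_xy = 0.25, kappa = 5) {
  stopifnot(is.numeric(omega_xy), length(omega_xy) == 1, is.finite(omega_xy))
  stopifnot(is.numeric(kappa), length(kappa) == 1, is.finite(kappa))
  if (omega_xy <= 0) stop("omega_xy must be positive")
  if (kappa < 1) stop("kappa must be >= 1")
  omega_z <- kappa * omega_xy
  structure(
    list(
      omega_xy = omega_xy,
      kappa = kappa,
      omega_z = omega_z,
      V_eff = effective_volume(omega_xy, kappa)
    ),
    class = "detection_volume"
  )
}

#' Effective volume of a 3D-Gaussian detection profile
#'
#' @param omega_xy Lateral \eqn{1/e^2} radius (um).
#' @param kappa Structure parameter \eqn{\omega_z/\omega_{xy}}.
#' @return Effective volume \eqn{\pi^{3/2}\omega_{xy}^3\kappa} in fL.
#' @export
effective_volume <- function(omega_xy, kappa) {
  pi^(3 / 2) * omega_xy^2 * (kappa * omega_xy)
}

#' @export
print.detection_volume <- function(x, ...) {
  cat(sprintf(
    "3D-Gaussian detection volume: omega_xy = %.4g um, kappa = %.4g, V_eff = %.4g fL\n",
    x$omega_xy, x$kappa, x$V_eff
  ))
  invisible(x)
}
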