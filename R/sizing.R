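#' Stokes-Einstein mass scaling of a diffusion coefficient
#'
#' For a compact diffusing entity the Stokes-Einstein relation makes D
#' inversely proportional to the hydrodynamic radius and therefore to the
#' cube root of the volume or molecular mass:
#' \deqn{D_{target} = D_{known}\,(M_{known}/M_{target})^{1/3}.}
#' Used to predict the diffusion coefficient of a tagged protein from a
#' measurement of the free fluorescent tag.
#'
#' @param D_known Measured diffusion coefficient (um^2/s), > 0.
#' @param M_known Molecular mass of the measured entity (kDa), > 0.
#' @param M_target Molecular mass of the target entity (kDa), > 0.
#' @return Estimated diffusion coefficient of the target (um^2/s).
#' @examples
#' mass_scaled_diffusion(43, 26, 120) # about 25.8
#' @export
mass_scaled_diffusion <- function(D_known, M_known, M_target) {
  stopifnot(D_known > 0, M_known > 0, M_target > 0)
  D_known * (M_known / M_target)^(1 / 3)
}

#' Relative complex volume from two diffusion coefficients
#'
#' The inverse cube of the diffusion-coefficient ratio estimates how much
#' larger the slowly diffusing complex is:
#' \deqn{V_{slow}/V_{fast} = (D_{fast}/D_{slow})^3.}
#'
#' @param D_fast,D_slow Diffusion coefficients (um^2/s), both > 0.
#' @return The volume (or mass) ratio, > 0.
#' @examples
#' volume_ratio(17.3, 10.6) # about 4.35, i.e. "more than fourfold"
#' @export
volume_ratio <- function(D_fast, D_slow) {
  stopifnot(D_fast > 0, D_slow > 0)
  (D_fast / D_slow)^3
}

#' Size comparison of two diffusing species
#'
#' @param D_a,D_b Diffusion coefficients (um^2/s).
#' @param M_a,M_b Optional molecular masses (kDa).
#' @return A list with the inputs and `volume_ratio` = (D_a/D_b)^3
#'   (> 1 when species b is the larger complex).
#' @export
size_comparison <- function(D_a, D_b, M_a = NULL, M_b = NULL) {
  structure(
    list(
      D_a = D_a, D_b = D_b,
      volume_ratio = volume_ratio(D_a, D_b),
      M_a = M_a, M_b = M_b
    ),
    class = "size_comparison"
  )
}
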