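#' Diffusing fluorescent species
#'
#' A single molecular species characterised by its diffusion coefficient,
#' molar concentration and molecular brightness in each detection channel.
#' A dual-labelled (co-diffusing) species has both brightnesses positive; a
#' single-colour species has exactly one.
#'
#' @param name Species label.
#' @param D Diffusion coefficient in um^2/s, > 0.
#' @param concentration Molar concentration in nM, >= 0.
#' @param brightness_G,brightness_R Mean detected count rate per molecule at
#'   the centre of the detection volume, in Hz. At least one must be > 0.
#' @param bleach_rate First-order decay constant of the per-molecule
#'   brightness in 1/s (0 = no photobleaching).
#' @return An object of class `species_spec`.
#' @examples
#' species_spec("wt-like", D = 17.3, concentration = 32, brightness_G = 3000)
#' @export
species_spec <- function(name, D, concentration,
                         brightness_G = 0, brightness_R = 0,
                         bleach_rate = 0) {
  stopifnot(is.numeric(D), is.numeric(concentration))
  if (D <= 0) stop("D must be positive")
  if (concentration < 0) stop("concentration must be non-negative")
  if (brightness_G < 0 || brightness_R < 0) stop("brightness must be >= 0")
  if (brightness_G + brightness_R <= 0) {
    stop("a visible species needs brightness_G + brightness_R > 0")
  }
  if (bleach_rate < 0) stop("bleach_rate must be >= 0")
  structure(
    list(
      name = as.character(name), D = D, concentration = concentration,
      brightness_G = brightness_G, brightness_R = brightness_R,
      bleach_rate = bleach_rate
    ),
    class = "species_spec"
  )
}

#' Simulation configuration for synthetic FCS traces
#'
#' Bundles everything the Brownian-dynamics trace generator needs: the
#' detection volume, the species present, uncorrelated background count
#' rates, the acquisition duration and time discretisation, the periodic
#' simulation box and the random seed. Default duration and volume emulate a
#' 120 s per-cell acquisition on a confocal instrument with a ~0.44 fL
#' observation volume.
#'
#' @param species A `species_spec` or list of them.
#' @param volume A [detection_volume()].
#' @param background_G,background_R Uncorrelated background count rates (Hz).
#' @param duration Acquisition time in seconds.
#' @param base_bin Width of the counting bins in seconds; must be an integer
#'   multiple of `time_step`.
#' @param time_step Brownian propagation step in seconds.
#' @param box_factor Half-width of the periodic simulation box in units of
#'   (omega_xy, omega_xy, omega_z); must be >= 5 so the detection profile is
#'   negligible at the boundary.
#' @param seed Integer seed; identical configurations including the seed give
#'   bit-identical traces.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(species, volume = detection_volume(),
                              background_G = 0, background_R = 0,
                              duration = 120, base_bin = 2e-6,
                              time_step = 1e-6, box_factor = 8,
                              seed = NULL) {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(all(vapply(species, inherits, logical(1), "species_spec")))
  stopifnot(inherits(volume, "detection_volume"))
  if (duration <= 0) stop("duration must be positive")
  if (base_bin <= 0 || time_step <= 0) stop("bin width and step must be positive")
  if (base_bin < time_step) stop("base_bin must be >= time_step")
  spb <- base_bin / time_step
  if (abs(spb - round(spb)) > 1e-9) {
    stop("base_bin must be an integer multiple of time_step")
  }
  if (box_factor < 5) stop("box_factor must be >= 5")
  if (background_G < 0 || background_R < 0) stop("backgrounds must be >= 0")
  structure(
    list(
      volume = volume, species = species,
      background_G = background_G, background_R = background_R,
      duration = duration, base_bin = base_bin, time_step = time_step,
      box_factor = box_factor, seed = seed
    ),
    class = "simulation_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' The YAML file mirrors the [simulation_config()] fields: a `volume` mapping
#' with `omega_xy` and `kappa`, a `species` sequence whose entries carry the
#' [species_spec()] fields, and scalar entries for the remaining arguments.
#'
#' @param path YAML file path.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  vol <- do.call(detection_volume, y$volume %||% list())
  sp <- lapply(y$species, function(s) do.call(species_spec, s))
  args <- y[setdiff(names(y), c("volume", "species"))]
  do.call(simulation_config, c(list(species = sp, volume = vol), args))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
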