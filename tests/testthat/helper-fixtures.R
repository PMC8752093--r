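# Shared fixtures. Simulations are scaled down relative to the 120 s
# instrument default (shorter traces, coarser bins, minimal box) so the
# suite stays fast; the physics is unchanged.

default_volume <- function() detection_volume(omega_xy = 0.25, kappa = 5)

# one mutant-like red species, paper-median ground truth
mutant_species <- function(...) {
  species_spec("mutant-like",
    D = 10.6, concentration = 75,
    brightness_R = 3000, ...
  )
}

wildtype_species <- function(...) {
  species_spec("wildtype-like",
    D = 17.3, concentration = 32,
    brightness_G = 3000, ...
  )
}

quick_config <- function(species, duration = 2, base_bin = 2e-5,
                         seed = 1, ...) {
  simulation_config(
    species = species, volume = default_volume(),
    duration = duration, base_bin = base_bin, time_step = base_bin,
    box_factor = 5, seed = seed, ...
  )
}

# deterministic cosine-modulated "trace" for correlator oracles
cosine_trace <- function(a = 100, b = 20, freq = 10, bin = 1e-3, n = 10000) {
  t <- (seq_len(n) - 1) * bin
  intensity_trace(
    counts_G = a + b * cos(2 * pi * freq * t),
    counts_R = a + b * cos(2 * pi * freq * t),
    bin_width = bin
  )
}

# analytic relative standard error of the mean count rate of a single-species
# simulation: particle-number term (fixed per realisation) + occupancy
# fluctuations (averaged over ~T/2tau_D correlation times) + shot noise
rate_rel_se <- function(config) {
  vol <- config$volume
  sp <- config$species[[1]]
  hx <- config$box_factor * vol$omega_xy
  hz <- config$box_factor * vol$omega_z
  v_box <- (2 * hx)^2 * (2 * hz)
  n_box <- sp$concentration * 0.602214076 * v_box
  n_eff <- sp$concentration * 0.602214076 * vol$V_eff
  tau_D <- vol$omega_xy^2 / (4 * sp$D)
  rate <- expected_count_rate(config, if (sp$brightness_G > 0) "G" else "R")
  sqrt(1 / n_box +
    (1 / n_eff) / (config$duration / (2 * tau_D)) +
    1 / (rate * config$duration))
}
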