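# fcspipe

Two-colour fluorescence correlation spectroscopy (FCS) analysis in R —
from binned photon-count traces to diffusion coefficients, molar
concentrations, complex-size estimates and condition-level statistics —
plus a Brownian-dynamics generator of synthetic two-channel traces with
known ground truth, so the whole chain is testable without a microscope.

The package is aimed at quantitative cell biologists and biophysicists
who use dual-colour FCS to compare two differently tagged protein
variants in the same cell: for example a fluorescently tagged wild-type
protein in one colour channel and an oncogenic mutant allele in the
other, measured for ~120 s per cell in cytosol and nucleus across tens of
cells per condition.

## The model

Photon counts are recorded from a confocal observation volume modelled as
a 3D Gaussian with lateral waist ω_xy and structure parameter
κ = ω_z/ω_xy. The normalised correlation of the (detrended) channel
signals,

    G(τ) = ⟨δF_A(t) δF_B(t+τ)⟩ / (⟨F_A⟩⟨F_B⟩),

is estimated on a multi-tau lag grid and fitted, for each
autocorrelation, with the single-component free-diffusion model

    G(τ) = G∞ + (1/N) (1 + τ/τ_D)⁻¹ (1 + τ/(κ²τ_D))⁻¹ᐟ²,

with τ_D = ω_xy²/(4D). A reference dye of known D fixes
ω_xy = √(4 D_ref τ_D,ref) per channel, so fitted parameters convert to
instrument-independent quantities: D = ω_xy²/(4τ_D) and
c = N/(N_A·V_eff) with V_eff = π³ᐟ²ω_xy²ω_z. Amplitudes are corrected
for photobleaching (square-root detrend plus the mean-decay amplitude
factor) and for uncorrelated background (×((F−B)/F)²) before conversion.
The cross-correlation amplitude between the two colour channels reads out
co-diffusion: zero within error means the two tagged species do not bind
each other. Stokes–Einstein cube-root scaling turns diffusivity ratios
into relative complex volumes.

## Worked example

Simulate one synthetic "cell" carrying two independently diffusing
species — a wild-type-like green species (D = 17.3 µm²/s, 32 nM) and a
mutant-like red species (D = 10.6 µm²/s, 75 nM) — with 2 kHz background
in each channel, then run the full per-cell analysis:

```r
library(fcspipe)

vol <- detection_volume(omega_xy = 0.25, kappa = 5) # V_eff ~ 0.44 fL
cfg <- simulation_config(
  species = list(
    species_spec("wildtype-like", D = 17.3, concentration = 32, brightness_G = 3000),
    species_spec("mutant-like",  D = 10.6, concentration = 75, brightness_R = 3000)
  ),
  volume = vol, background_G = 2000, background_R = 2000,
  duration = 4, base_bin = 2e-5, time_step = 2e-5, box_factor = 5, seed = 2
)
trace <- simulate_trace(cfg)
trace
#> intensity_trace: 200000 bins of 2e-05 s (4 s), mean rates G 11.1 / R 22.3 kHz

cell <- run_cell(
  trace,
  calibration_from_volume(vol, "G"), calibration_from_volume(vol, "R"),
  background = background_estimate(2000, 2000),
  cell_id = "cell_001", condition = "control"
)
cell[, c("channel", "N_corrected", "tau_D", "D", "c", "gr_amplitude", "qc_pass")]
#>   channel N_corrected    tau_D    D    c gr_amplitude qc_pass
#> 1       G         9.4 0.000885 17.7 35.9      0.00438    TRUE
#> 2       R        19.3 0.001201 13.0 73.7      0.00438    TRUE
```

The green channel recovers D ≈ 17.7 µm²/s and c ≈ 36 nM, the red channel
D ≈ 13.0 µm²/s and c ≈ 74 nM; the cross-correlation amplitude (0.004,
versus autocorrelation amplitudes of ~0.1) is zero within its block
error, i.e. the two species do not co-diffuse. Single-cell D estimates
scatter by 15–20% at this photon budget — conclusions are drawn from
ensemble medians (`run_experiment()`, `summarize_cells()`,
`compare_conditions()`), which recover ground truth within 10% over
45-cell ensembles.

Size inference is plain arithmetic on the medians:

```r
volume_ratio(17.3, 10.6)          # 4.35 - the slower complex is >4x larger
mass_scaled_diffusion(43, 26, 120) # 25.8 um^2/s expected for a 120 kDa fusion
                                   # from a 26 kDa free tag measured at 43
```

A thin CLI (`exec/fcspipe`) exposes `simulate`, `analyze` and `summarize`
subcommands over YAML configurations and tab-separated trace files.

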