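---
title: "Two-colour FCS analysis with fcspipe: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-colour FCS analysis with fcspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fcspipe implements the analysis chain of a two-colour fluorescence
correlation spectroscopy (FCS) experiment — the kind used to compare the
mobility and abundance of two differently tagged protein variants in live
cells — together with a Brownian-dynamics generator of synthetic
photon-count traces, so that every stage can be validated against known
ground truth without instrument data. This vignette explains the models,
the corrections, the numerical choices, and what the synthetic data do and
do not establish about real measurements.

## The measurement model

A confocal FCS instrument records photon counts from a femtolitre-scale
observation volume. The detection efficiency is modelled as a 3D Gaussian
molecular detection function (MDF),

$$\mathrm{MDF}(x,y,z) = \exp\!\left(-\frac{2(x^2+y^2)}{\omega_{xy}^2}
  - \frac{2z^2}{\omega_z^2}\right),$$

parameterised by the lateral $1/e^2$ waist $\omega_{xy}$ and the structure
parameter $\kappa = \omega_z/\omega_{xy}$. The effective volume is
$V_\mathrm{eff} = \pi^{3/2}\omega_{xy}^2\omega_z$; with the package
defaults $\omega_{xy} = 0.25\,\mu m$ and $\kappa = 5$ this gives
$V_\mathrm{eff} \approx 0.44$ fL, the right order for a high-NA confocal
spot. Neither waist is printed by typical instrument software, which is
why both are exposed in configuration and fixed by dye calibration rather
than hard-coded.

The normalised correlation of two detrended channel signals $F_A, F_B$ is

$$G(\tau) = \frac{\langle \delta F_A(t)\, \delta F_B(t+\tau)\rangle}
  {\langle F_A\rangle \langle F_B\rangle},$$

and for a single freely diffusing species the autocorrelation follows the
familiar closed form

$$G(\tau) = G_\infty + \frac{1}{N}
  \left(1+\frac{\tau}{\tau_D}\right)^{-1}
  \left(1+\frac{\tau}{\kappa^2\tau_D}\right)^{-1/2},
  \qquad \tau_D = \frac{\omega_{xy}^2}{4D}.$$

$N$ is the mean number of molecules in $V_\mathrm{eff}$, so concentration
follows as $c = N/(N_A V_\mathrm{eff})$ and the diffusion coefficient as
$D = \omega_{xy}^2/(4\tau_D)$ once a reference dye of known $D$ has fixed
$\omega_{xy} = \sqrt{4 D_\mathrm{ref}\tau_{D,\mathrm{ref}}}$. Each colour
channel is calibrated separately because chromatic aberration makes the
two detection volumes differ.

```{r}
library(fcspipe)
vol <- detection_volume(omega_xy = 0.25, kappa = 5)
vol$V_eff # 0.435 fL
```

## The correlator

Correlations are estimated on a multi-tau grid: 16 linear lags at the base
bin width, then the counts are re-binned by a factor of two per level with
8 further lags per level, covering microseconds to seconds at
logarithmic cost. Normalisation is *symmetric* — the means in the
denominator are computed over the two overlapping trace segments for each
lag — which makes the estimator robust against residual slow drifts; a
consequence worth knowing is that slow photobleaching barely inflates the
amplitude even before detrending. Per-lag uncertainties `G_err` come from
a block-wise standard error over ten contiguous trace segments, so fit
weights derive from the trace itself, matching how single-cell curves must
be fitted in practice. A brute-force direct estimator
(`correlate_direct()`) with identical arithmetic at the base bin width
serves as the oracle in tests: level-0 lags agree to rounding error, and
deeper (re-binned) levels estimate the triangular window average of the
fine-grained curve.

## Corrections

**Photobleaching.** Slow loss of fluorophores produces a decaying
intensity. The trace is re-binned to 1 s (or a tenth of short traces),
fitted with $F(t) = F_0 e^{-t/\tau_b}$, and compensated with the
square-root detrend
$F_c(t) = F(t)/\sqrt{f(t)} + F_0(1-\sqrt{f(t)})$, $f(t) = e^{-t/\tau_b}$,
which restores a stationary mean at the $t=0$ intensity scale while
preserving fluctuation statistics to first order. The detrend leaves the
correlation amplitude attenuated by $\bar f = \frac1T\int_0^T f\,dt$; the
fitted molecule number is therefore multiplied by $\bar f$ ("detrend +
factor" as one combined correction). Decays below 2% over the trace are
flagged negligible and left untouched. Only the mono-exponential form is
implemented; bleaching that is strongly bi-exponential would need the
module swapped out.

**Uncorrelated background.** Background light with mean rate $B$ dilutes
the relative fluctuations and attenuates $G(0)$ by $((F-B)/F)^2$, where
$F$ is the measured mean rate. The apparent $N$ is corrected by the same
factor. $B$ is always an ensemble median measured on unlabelled cells per
compartment and supplied via configuration — the analyte trace is never
used to estimate its own background. A trace with $F \le B$ is an error,
flagged per channel while the other channel is still reported.

**Fit policy.** Weighted Levenberg-Marquardt with weights $1/G_{err}^2$;
$\kappa$ is fixed from calibration because $\kappa$ and $\tau_D$ are
poorly identifiable jointly on single-cell curves. A small baseline offset
is floated by default (config-switchable) to absorb residual long-lag
correlations. Lags below five base bins are excluded to keep shot-noise
artefacts at the shortest lags out of the fit. Bounds are
$N \in [10^{-3}, 10^6]$ and $\tau_D$ between one bin and a tenth of the
trace; non-convergence or an amplitude at the lower bound is reported as
`converged = FALSE` with a diagnostic, never replaced by defaults. A
cross-correlation amplitude is read out as the mean of the leading lags
with its propagated block error; "co-diffusion" requires $G_x(0) > 3$ SE.

## The synthetic-data generator

`simulate_trace()` propagates point particles through a periodic box with
half-widths `box_factor` $\times (\omega_{xy}, \omega_{xy}, \omega_z)$ by
isotropic Gaussian steps of per-axis variance $2D\,\Delta t$. Particle
numbers per species are Poisson with mean $c\,N_A V_\mathrm{box}$
(grand-canonical), so amplitude statistics match open-volume theory. The
expected count per bin sums $q\,e^{-k_b t}\,\mathrm{MDF}(r)$ over
particles plus the background rate; realised counts are Poisson. Defaults
mirror a live-cell acquisition: 120 s duration, 1 µs propagation step,
2 µs bins, box factor 8.

Because Brownian increments are exactly Gaussian at any step size, the
only discretisation effect is that the MDF is sampled once per step; with
$\geq$ 20 steps per $\tau_D$ the induced smoothing of $G$ is second order
($(\Delta t/\tau_D)^2/24$, well below 0.1% here). Far from the detection
volume (MDF below $10^{-5}$ of peak) particles advance by aggregated
Gaussian jumps bounded by a conservative first-passage criterion
($k \le d^2 / (20 D \Delta t)$ steps for a particle at distance $d$ from
the deposit region, using the tighter of a box and an ellipsoidal distance
bound), which changes the photon statistics only through a
$\sim 10^{-6}$-probability class of unsampled grazing passes at the
$10^{-5}$ contour. Randomness comes from a dedicated xoshiro256++ stream
with ziggurat normals, seeded from the configuration seed; identical
configurations give bit-identical traces.

The generator emulates: two (or more) independently diffusing
single-colour species, optional dual-labelled co-diffusing species,
Poisson shot noise, uncorrelated background, and slow mono-exponential
photobleaching. It deliberately omits triplet blinking, detector
afterpulsing and dead time, membrane-bound fractions, and spatially
varying environments. Passing recovery tests on these traces therefore
demonstrates the correctness of the estimator chain, not robustness to
photophysics the model excludes.

Ground-truth settings for ensemble tests are the measured medians of the
study system: a "wild-type-like" green species (D = 17.3 µm²/s, 32 nM)
and a "mutant-like" red species (D = 10.6 µm²/s, 75 nM) in the same cell,
with per-molecule brightness 3 kHz, ~2 kHz background and a bleaching
time constant of tens of seconds — typical live-cell values.

## Problem sizes in tests

The test and acceptance suites shorten acquisitions to 2-4 s at 20 µs
bins with box factor 5 (the smallest the boundary contract allows) —
roughly a hundredfold cheaper than the 120 s default while leaving
thousands of diffusion times per trace. At this photon budget single-cell
$\tau_D$ estimates scatter by 15-20% (as they do for real single-cell
curves); recovery claims are therefore posed at the ensemble-median level:
45-cell medians of both $D$ and $c$ recover ground truth within 10% after
detrending, bleach-factor and background corrections, and calibration.
Statistical operating characteristics (type-I rate, power of the
Mann-Whitney comparison at the 17.3-vs-10.6 effect size) use the
package's lognormal per-cell sampler with the reported cell-to-cell
spreads rather than trace-level simulation: those properties depend only
on the per-cell value distributions, and a thousand repetitions of a
90-trace experiment would be pointlessly expensive.

## Ensemble statistics

Per-cell measurements aggregate by condition, compartment and channel
into medians with two robust dispersions (MAD and IQR — the "±" spreads
of published figures are rarely defined, so both are reported and neither
is labelled as anyone's convention). Pairwise comparisons use the
two-sided Mann-Whitney U test — two-sided because directionality is a
conclusion, not an assumption — with the exact null distribution whenever
$n_a n_b \le 10^4$ and there are no ties, and the normal approximation
with tie and continuity corrections otherwise. Stars follow the usual
convention (*** p < 0.001, ** p < 0.01, * p < 0.05, NS). No
multiple-testing correction is applied across condition pairs, matching
the unadjusted pairwise reporting convention of the field; cells failing
QC (non-converged fits or reduced $\chi^2 > 5$) are excluded from
summaries but retained, flagged, in the per-cell table.

## Size inference

The Stokes-Einstein relation makes $D$ inversely proportional to the
hydrodynamic radius, hence to the cube root of the complex volume or
mass. Two pure-arithmetic helpers expose this:
`mass_scaled_diffusion(D, M_known, M_target)` $= D (M_k/M_t)^{1/3}$
predicts the diffusion of a tagged protein from the free tag
(43 µm²/s at 26 kDa scales to ≈ 25.8 µm²/s at 120 kDa), and
`volume_ratio(D_fast, D_slow)` $= (D_f/D_s)^3$ turns a diffusivity gap
into a relative complex size (17.3 vs 10.6 µm²/s implies a more than
fourfold larger complex). No shape corrections are attempted; the cube
root law assumes compact complexes, and reference $D$ values are taken at
face value — the temperature dependence of dye literature values (often
quoted at 22.5 °C against 37 °C measurements) is deliberately left to the
user's choice of `D_ref`.

## Known limitations

* Single-component fits only: a genuine mixture of fast and slow states
  is reported as one intermediate $\tau_D$.
* The mono-exponential bleach model and the two-term detrend are
  first-order; severe bleaching (> 50% loss) would need the stochastic
  per-molecule treatment the generator deliberately avoids.
* Cross-correlation amplitudes are read out but not converted into bound
  fractions: that would require the overlap volume of the two detection
  volumes, which plain two-colour calibration does not provide.
* The periodic simulation box re-injects particles; at box factor ≥ 5 the
  resulting excess long-lag correlation is far below the block error of a
  2 s trace, but pathological configurations (huge $D$, tiny box) are not
  defended against beyond the box-factor invariant.
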