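# gagcest

Glycosaminoglycan chemical exchange saturation transfer (gagCEST) MRI probes
cartilage GAG content at 3 T by saturating the exchangeable GAG hydroxyl
(+1 ppm) and amine (+3.2 ppm) protons and reading out the transferred
saturation on the water signal. `gagcest` implements the full computational
side of such a study for researchers in quantitative musculoskeletal MRI:

* an exact **Bloch–McConnell simulator** for shaped, pulsed pre-saturation
  trains (matrix-exponential propagation of the full 3N+1-dimensional affine
  system; water + GAG-OH + GAG-NH pools),
* **protocol optimisation** sweeps over pulse count `np`, pulse duration
  `tp` and saturation amplitude `B1` under a SAR-motivated `tp` ceiling,
* the **in-vivo quantification chain**: WASSR maximum-symmetry B0 mapping,
  per-voxel z-spectrum correction, MTR asymmetry mapping over the
  GAG-specific 0.9–1.9 ppm band, and six-pool Lorentzian decomposition,
* mono-exponential **T1/T2 relaxometry** (inversion recovery, multi-echo),
* a seeded **synthetic ankle-cartilage phantom** with ground-truth maps and
  two calibrated cohorts (healthy / degenerated cartilage), and
* **cohort statistics**: descriptive summaries and two-way random-effects
  intraclass correlations (single and average measure).

## The model

For pools *i* = 1…N (water first) with relaxation rates R1ᵢ, R2ᵢ,
equilibrium magnetization M0ᵢ ∝ concentration, exchange rates kᵢ towards
water and chemical shifts δᵢ, the coupled magnetization under RF amplitude
ω₁ = 2πγ̄B₁ at saturation offset ω obeys the Bloch–McConnell equations

    dM/dt = A(ω, B₁) · M + b,

a linear system that is solved exactly on every piecewise-constant segment of
the pulse train via the matrix exponential of the augmented (affine) system.
A Gaussian pulse is discretised into 64 amplitude steps (σ = tp/5, truncated
at ±2.5σ, time-average amplitude equal to the quoted B₁); interpulse gaps of
duration tp·(1−DC)/DC evolve freely with B₁ = 0. The z-spectrum is
Z(ω) = Mz,water(after train)/M0,water, and the gagCEST readout is

    MTR_asym(Δω) = Z(−Δω) − Z(+Δω),

reported in percent, either as a spline maximum inside a frequency window or
averaged over the GAG-specific band 0.9–1.9 ppm (the in-vivo map statistic).

## Worked example

```r
library(gagcest)

# the optimised in-vivo protocol: 8 Gaussian pulses, 300 ms, 0.8 uT, DC 0.5
zs <- simulate_pulsed_cest(cartilage_pools(),
                           saturation_scheme(b1_uT = 0.8, tp_ms = 300, np = 8),
                           offsets = seq(-4, 4, 0.05))
zs
#> z-spectrum: 161 offsets in [-4, 4] ppm, Z in [0.0239, 0.9019]

curve <- compute_mtr_asym(zs)
max_mtr_asym_in_window(curve, c(0.9, 1.9))
#> $max_pct   1.804       # largest simulated gagCEST effect in the window
#> $argmax_ppm 1.34       # ... attained near the GAG-OH resonance
mean_mtr_asym_in_window(curve, c(0.9, 1.9))
#> [1] 1.682              # window-average, the in-vivo map statistic
```

A seeded synthetic subject, quantified end to end:

```r
ds <- generate_phantom(phantom_spec(cohort = "healthy", seed = 42))
q  <- quantify_dataset(ds)
q$roi_mtr_pct
#> [1] 1.331   # ROI-mean MTR_asym; the cohort design point is 1.49%,
#>             # the shortfall is the WASSR-bias sensitivity discussed in the
#>             # methods vignette
```

The phantom's ground truth (`ds$truth`) lets every pipeline stage be checked
against what was injected: B0 field, MTR_asym, GAG-OH amplitude, T1/T2 maps.

A thin command-line wrapper for shell use lives in `inst/cli/gagcest.R`
(subcommands `simulate`, `optimize`, `phantom`, `quantify`, `stats`).

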