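---
title: "Methods: pulsed gagCEST simulation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsed gagCEST simulation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagcest)
```

## The physical model

Chemical exchange saturation transfer (CEST) imaging saturates a dilute pool
of exchangeable solute protons with a frequency-selective RF train and reads
the transferred saturation on the abundant water signal. For cartilage, the
relevant solutes are the glycosaminoglycan hydroxyl protons at +1 ppm
(exchange rate ≈ 1000 Hz, ≈ 0.3 M in healthy tissue) and amine protons at
+3.2 ppm (≈ 50 Hz, ≈ 0.1 M); water is modelled with T1 = 1.2 s,
T2 = 39 ms and 88 M at 3 T. These defaults are returned by
`cartilage_pools()` and can be rescaled to emulate GAG loss.

The coupled magnetization obeys the Bloch–McConnell (BM) equations. With the
solute pools exchanging only with water (star topology) and exchange balanced
by concentration (k_water→i = k_i·M0_i/M0_water), the system is linear in the
full state (Mx, My, Mz per pool). `simulate_pulsed_cest()` augments the state
with a constant to absorb the R1·M0 recovery terms and advances each
piecewise-constant segment of the saturation train by the matrix exponential
of the affine generator — the exact solution, not a z-only or weak-saturation
approximation. The propagator core is compiled (RcppArmadillo); an
independent stiff-ODE integration of the identical system is kept in the test
suite and agrees to ~1e-10 in Z.

## Saturation-train conventions

Quoted pulsed-CEST protocols rarely state their pulse conventions, so they
are explicit (and adjustable) here:

* **B1 amplitude** (`b1_convention = "mean"`, default): the quoted B1 is the
  time-average amplitude over the pulse-on period; a Gaussian envelope is
  rescaled so its mean equals B1. `"peak"` interprets B1 as the envelope
  maximum instead.
* **Gaussian envelope**: σ = tp/5, truncated at ±2.5σ, discretised into 64
  equal-duration segments. A convergence test doubles the segment count and
  requires the window maximum of MTR_asym to move by < 0.1 percentage points.
* **Interpulse gaps**: duration tp·(1−DC)/DC, free evolution with B1 = 0.
  Since the gaps (≥ 100 ms) far exceed T2, transverse coherence decays
  naturally; an ideal-spoiling flag (`spoil = TRUE`) zeroes the transverse
  components at each gap start and changes Z by < 1e-2 in the tested regimes.

## Window statistics and the sweep harness

`compute_mtr_asym()` evaluates MTR_asym(Δω) = Z(−Δω) − Z(+Δω) on the
positive offsets (cubic-spline interpolation where the grids do not mirror
exactly). Two window statistics are provided:

* `max_mtr_asym_in_window()` — spline maximum on a 0.01 ppm search grid,
  ties broken toward the smaller offset;
* `mean_mtr_asym_in_window()` — trapezoidal average on a 0.05 ppm
  interpolation grid. This is the in-vivo map statistic: the acquisition
  samples (0.25 ppm steps) do not hit the 0.9/1.9 ppm band edges, so a fixed
  interpolation grid keeps the average acquisition-independent.

Both are exposed in `run_sweep()` because published per-window summaries of
parameter sweeps are not always internally consistent with a maximum
semantics (a maximum over a nested window can never exceed the maximum over
its containing window, whereas window *averages* are free to order either
way). The default follows the maximum semantics.

The sweep harness varies exactly one of np, tp, B1 while holding the others
at the base scheme, simulates on a −4…4 ppm grid at 0.05 ppm, and refuses tp
above a configurable SAR-motivated ceiling (default 300 ms, the scanner limit
for this protocol family).

## In-vivo quantification chain

**WASSR B0 mapping.** Each voxel's low-power WASSR spectrum
(B1 = 0.25 µT, one 54 ms pulse, ±1 ppm at 0.1 ppm) is normalized by the
unsaturated image, interpolated onto a 0.001 ppm grid, and the water centre
is the candidate c minimising the mirror-symmetry cost
Σ_ω [Ẑ(c+ω) − Ẑ(c−ω)]², searched exhaustively over ±0.5 ppm with mirror
lags out to the guaranteed common support (every 0.01 ppm). Flat or dead
voxels are masked rather than raising errors.

**B0 correction and mapping.** `correct_zspectrum()` resamples the
normalized spectrum at the nominal offsets shifted by the voxel's B0 estimate
(cubic spline; flat extrapolation, flagged, outside the measured support).
A `corrected` attribute makes double application an error — the correction is
not idempotent and must be applied exactly once. `mtr_asym_map()` then
averages the MTR_asym curve over 0.9–1.9 ppm per voxel; the ROI statistic is
the mean of voxel values with NaN voxels excluded.

**Lorentzian decomposition.** The B0-corrected spectrum is fitted as
1 − Σ A_i·L(ω; δ_i, Γ_i) with six fixed centres — water 0, GAG-OH +1,
GAG-NH +3.2, NOE −1 and −2.8, MT −2.43 ppm — amplitudes bounded in [0, 1]
and FWHM in (0.1, 10] ppm, by bounded Levenberg–Marquardt with a
deterministic 5-start multi-start. The water centre is fixed at 0 ppm: after
B0 correction that is where the water line must sit, and −1 ppm in the pool
listing belongs to the NOE component. The MT pool uses a Lorentzian
lineshape (a super-Lorentzian would require lineshape parameters the
protocol does not constrain).

Two identifiability caveats, both visible in the tests: (i) at SNR 100 the
overlapping NOE (−2.8) and MT (−2.43) components make sub-10% amplitude
recovery statistically impossible — the Fisher-information standard errors
of the solute amplitudes are themselves 10–27% relative — so the SNR-100
test asserts errors within an information-bound envelope and exact recovery
is asserted at low noise; (ii) on BM-generated (non-Lorentzian) spectra the
GAG-OH component absorbs part of the broad direct-saturation shoulder of
water, so its absolute amplitude (~8% on the phantom) exceeds the pure CEST
increment, while the healthy > degenerated ordering is preserved.

## Relaxometry

T1 is fitted per voxel or per ROI with the three-parameter inversion-recovery
model Mz(t) = Mz0 − (Mz0 − Mz(0))·exp(−t/T1) at the protocol's TI grid
{25, 50, 100, 500, 1000, 2000} ms; scanner magnitude images are assumed, and
polarity is restored by trying every plausible zero-crossing position and
keeping the best-residual fit. T2 uses mono-exponential decay at TE
{13.8, 27.6, 41.4, 55.2, 69} ms, nonlinear by default with a log-linear
option that falls back to nonlinear when any sample is non-positive. A
constant T2 series carries no decay information and is flagged T2 = Inf
rather than fitted. Both fits are scale-invariant and exact on noiseless
model data across T1 ∈ [200, 3000] ms, T2 ∈ [10, 100] ms.

## The synthetic phantom

`generate_phantom()` builds a 64×64 single-slice "ankle": a circular body of
free water (T1 1200 / T2 39 ms) containing two parallel 3-voxel cartilage
bands (tibial and talar layers, emulating ≈ 2 mm cartilage at 0.6 mm
resolution; T1 940 / T2 35 ms) separated by a 2-voxel joint space, with an
ellipsoid-like central ROI covering both bands. Every voxel's CEST and WASSR
spectra are forward-simulated with the full BM model at its GAG concentration
(quantised to discrete levels so each level is simulated exactly once) on a
fine 0.05 ppm grid, then sampled at the nominal offsets shifted by the
voxel's B0 — so unshifted, noiseless voxels reproduce the direct simulation
bit-exactly.

Choices a real acquisition fixes but the phantom must pick:

* **Offset grids**: CEST −3…3 ppm at 0.25 ppm (25 images + one reference at
  300 ppm), WASSR ±1 ppm at 0.1 ppm (21 + 1) — the protocol's grids.
* **B0 field**: smooth low-order harmonic with peak amplitude 0.1 ppm by
  default (typical shim residue at 3 T in the ankle), or a constant field
  for recovery tests; always within the ±1 ppm WASSR range.
* **Noise**: Gaussian with σ = 0.5% of S0 by default — a high-SNR regime in
  which the Gaussian approximation of magnitude (Rician) noise is accurate;
  a Rician option exists for realism at low SNR. Real-voxel SNR is not
  constrained by the protocol, so this is a free design choice.
* **Cohort calibration**: the GAG concentration multiplier is solved by root
  finding on the forward model so the noiseless ROI-mean MTR_asym over
  0.9–1.9 ppm equals the cohort design point (healthy 1.49%, degenerated
  0.34%). The design points are therefore testable properties of the
  generator, not hard-coded outputs.
* **Between-subject variability** (`cohort_fixture()`): a unit-mean
  lognormal multiplier (sdlog 0.08, i.e. ≈ 8% biological spread) on the
  cohort concentration, with per-subject seeds derived deterministically
  from the master seed.

What the phantom deliberately does **not** emulate: anatomically realistic
geometry, partial-volume and synovial-fluid contamination, motion, coil
profiles, or readout weighting. Passing recovery tests therefore demonstrates
correctness of the analysis chain under the stated physics, not robustness to
those in-vivo confounds.

## Numerical choices and degenerate inputs

Cubic interpolation throughout is `stats::splinefun(method = "fmm")`;
max-searches use a fixed 0.01 ppm grid with first-maximum (lowest-offset) tie
break; window averages use the trapezoidal rule. The B0 search is exhaustive
on the dense grid (no descent step to get trapped), with the candidate range
(±0.5 ppm) chosen so every candidate keeps full mirror support inside the
acquired ±1 ppm. Degenerate inputs are masked or flagged rather than thrown
where a map is being produced (dead WASSR voxels, constant T2 series), and
rejected loudly where a scalar answer is expected (empty offsets, one-sided
spectra, windows outside support, incomplete ICC layouts).

Problem sizes used by the shipped tests — 64×64 single-slice phantoms,
17 + 5 subject cohorts, 500-replicate relaxometry Monte Carlo, 20-config
ODE cross-checks — were chosen as the smallest sizes at which the respective
statistical claims are meaningful.

## Cohort statistics

`icc_two_way()` computes ICC(2,1) and ICC(2,k) (two-way random effects) from
the ANOVA mean squares of the complete subjects × raters matrix, in
absolute-agreement form by default — the standard inter-rater choice when
raters are a random sample — with the consistency form available.
Agreement-form confidence bounds use the F-based construction with a
Satterthwaite degrees-of-freedom approximation; average-measure bounds apply
the Spearman–Brown relation to the single-measure bounds. The published
confidence intervals this design echoes are internally inconsistent (the
single- and average-measure intervals appear swapped), so no attempt is made
to reproduce them; the point estimates are oracle-tested against a direct
sums-of-squares computation. Cohort comparison on phantoms uses Welch's
t-test — explicitly a plumbing-level substitute for the mixed-model analysis
that real repeated-measures cohorts would need.

## Known limitations

* **B0-shift sensitivity of MTR_asym.** Near the GAG-OH resonance the
  asymmetry changes by roughly 0.8 percentage points per 0.01 ppm of residual
  water-centre error in this protocol's regime — the window average is a
  first-order function of the shift. The WASSR spectrum of GAG-containing
  voxels is itself slightly asymmetric (the CEST effect does not vanish even
  at 0.25 µT), which biases the maximum-symmetry centre by ~0.002 ppm and the
  recovered gagCEST by ~0.1–0.15 percentage points. This is a property of the
  method, not of the implementation: the end-to-end recovery tests quantify
  it rather than hide it.
* **Window semantics of published sweep summaries** are ambiguous; both
  statistics are exposed and the default (maximum) is stated.
* **Lorentzian amplitudes are model-relative**, not absolute CEST effect
  sizes, on non-Lorentzian (BM) spectra; compare them within a model, not
  across models.
* The simulator models the saturation module only — no readout, no B1
  transmit-field maps, no SAR computation beyond the tp ceiling.
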