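---
title: "Models and methods: IFT turnaround, kinesin-II recycling, and the synthetic data behind the tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: IFT turnaround, kinesin-II recycling, and the synthetic data behind the tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`iftdyn` packages the quantitative pipeline of a single-molecule study of
intraflagellar transport (IFT): how anterograde trains are remodeled and
mixed at the flagellar tip, and how the kinesin-II motor returns to the
cell body by diffusion rather than by riding retrograde trains. This
vignette records the models, their assumptions, the parameter choices that
matter, and the places where the design was genuinely open.

## The traffic model and its defaults

`trafficConfig()` holds the measured traffic statistics used everywhere:
anterograde speed 2.1 ± 0.4 µm s⁻¹, retrograde 3.0 ± 0.7 µm s⁻¹ (means ±
s.d. of per-train speeds), 1.3 anterograde trains s⁻¹ injected at the
base, and a retrograde/anterograde frequency ratio of 1.15. Train arrivals
and departures are modeled as Poisson processes — the simplest model
consistent with stochastic, memoryless injection — and per-train speeds are
drawn from normal distributions truncated at zero, the simplest
distribution consistent with a reported mean ± s.d.

Imaging defaults describe a TIRF setup at 10 Hz with 106 nm pixels. The
PSF width (130 nm Gaussian s.d.) and the photon budget (150
photons/frame on a 5 photons/pixel background) are *setup defaults, not
measured quantities*: the budget was chosen once so that repeat 2D Gaussian
fits localize a spot to ≈20 nm per frame, the precision the tracking
analyses assume. The shot-noise-limited 1/√N scaling of localization error
is exact only at zero background, which is how the property test probes it;
with background the error falls faster than 1/√N at low photon counts.

## Synthetic trajectories

`makeKapTrajectory()` concatenates the three phases seen in gated movies of
KAP-GFP (the non-motor kinesin-II subunit): a constant-velocity anterograde
run, a tip pause, and 1D Brownian return with increments of variance 2DΔt,
reflected at both ends; an optional absorbing base terminates the trace,
emulating uptake at the cell body. Axial positions receive Gaussian
localization noise (default 20 nm).

The lateral coordinate deserves a note. The measured lateral scatters —
≈19 nm s.d. during transport, ≈65 nm during diffusion — are *observed*
quantities, and the transport-phase value is itself comparable to the
tracking error; true lateral motion and localization noise are not
separable at that scale. The generator therefore draws the lateral
coordinate directly with the requested observed s.d. per phase, rather
than adding localization noise on top of a hypothetical "true" scatter
(which could never reproduce a 19 nm observation with 20 nm noise). The
axial coordinate, where the two contributions are separable through the
MSD offset, keeps explicit noise.

Because noise is added after reflection, observed axial positions can
exceed the physical domain by roughly the noise scale — exactly as in real
tracking data — so the `Trajectory` container does not enforce 0 ≤ x ≤ L.

Kymographs paint each particle as a Gaussian line profile (PSF s.d.) into
a position × time grid with optional Poisson shot noise; gate emulation is
cosmetic (columns during the 0.2 s-per-second gate-on windows are masked),
while the *photophysics* of gating lives in the PhotoGate module. The
generator does not attempt realistic TIRF optics (evanescent decay, EMCCD
gain statistics) or curved flagella; passing tests therefore validate the
estimators under idealized Gaussian/Poisson imaging, not robustness to
optical artifacts.

## Localization, linking, MSD

`fitSpot2d()` fits a pixel-integrated 2D Gaussian (centers, per-axis
widths, volume amplitude, offset) by Levenberg–Marquardt least squares; a
fit that fails, collapses or runs to the border returns
`converged = FALSE` rather than a silent bad value. The precision estimate
uses the standard shot-noise localization formula (PSF width and
pixelation over photons, plus the background term). Unresolved doublets
are flagged by width anisotropy: a doublet at one PSF s.d. separation fits
as a single Gaussian elongated by √(1 + 1/4) ≈ 1.12, so the default
threshold of 1.10 flags separations approaching one PSF s.d. at high SNR.
A doublet much closer than that is genuinely indistinguishable from a
single emitter and cannot be flagged by any fit statistic.

Linking is greedy nearest-neighbour with a one-frame gap tolerance and a
five-frame minimum length — the tracked fields here are sparse, isolated
spots, so globally optimal assignment matters only for the occasional
crossing, which the exhaustive small-frame branch resolves by minimum
total displacement.

`lateralFluctuation()` models the *flagellar axis*: the path is rotated
onto its principal axis and the transverse coordinate fitted as a
degree-3 polynomial of the axial coordinate (degree exposed as a
parameter; the measurement is described only as a polynomial fit, degree
unspecified). Residuals are
projected perpendicular to the local tangent and the s.d. uses an
n − (degree+1) degrees-of-freedom correction. Principal-axis alignment
makes the statistic exactly invariant under rigid rotations.

`msdFit()` computes the time-averaged MSD and fits `MSD = 2Dτ + offset`
by unweighted least squares over the first quarter of lags. Both choices
were open: the fit range is the standard bias–variance compromise for
time-averaged MSDs (long lags are dominated by correlated noise), and the
unweighted fit over that restricted range is reproducible without modeling
the full MSD covariance. The free offset absorbs localization noise
(expectation 2σ²), which the static-trace test checks in closed form.
Directed motion is flagged when the log–log MSD slope exceeds 1.5.
Per-trace D estimates at the study's trace geometry (5 s at 10 Hz) are
noisy by nature; pooled results report mean ± s.e.m. across traces.

## Tip turnaround kinetics

The tip resting time of the k-th retrograde train is the interval from the
arrival of the fluorescent anterograde train to that departure. The
mechanistic simulator composes a remodeling stage — `nRemodelSteps`
sequential exponential sub-steps — with exponential departures, so the
mean k-th resting time is `T_r + k·Δt`. The defaults (2 sub-steps at
1.54 s⁻¹, departures every 1.7 s) give `T_r = 1.3` s and `Δt = 1.7` s, the
fitted tip kinetics; the dwell-time distribution they induce is consistent
with the measured Gamma shape of ≈3 (two remodeling sub-steps plus one
departure stage). Only the aggregate Gamma shape is constrained by data,
so the sub-step count is a configuration choice, not an inference.

`fitGammaMl()` is a maximum-likelihood Gamma fit (the choice between MLE
and histogram least squares was open; MLE is efficient and assumption-
light, and the package records it). The Newton iteration solves the shape
profile likelihood and is vectorized across bootstrap resamples, so the
95% CI comes from ≥1000 parametric-bootstrap refits in milliseconds. The
interval is the *basic* (reflected-percentile) bootstrap interval, which
calibrates better than the raw percentile interval for this skewed,
small-n likelihood; the suite verifies ≈95% coverage over 500 replicate
datasets of n = 97. Small-n MLE shape estimates carry a modest positive
bias (~2% at n = 97), visible in replicate averages and left uncorrected.

`fitRestingVsIndex()` regresses *per-index mean* resting times on k
(the per-index means are the quantity such experiments summarize and plot)
rather than pooling records; departure-time ties under frame quantization are broken by record
order, and quantization itself is an optional simulator flag since its
effect on the published fits is unknowable.

## PhotoGate fluorophore bookkeeping

Each anterograde train carries ~6 GFPs; GFPs bleach at 0.07 s⁻¹ under TIR
illumination, scaled by the 0.8 imaging duty cycle, during transit *and*
tip dwell (each fluorophore holds an exponential illuminated-exposure
budget). The tip pool holds three train-equivalents of particle slots
*including* the arriving train's material, matching the measured tip
brightness of ≈3 trains. The pool is open with balanced fluxes — arrivals
add a train's particles at the anterograde frequency, departures remove
`particles/1.15` at the retrograde frequency — so its size is stationary
at capacity and fluorophores are never destroyed by bookkeeping; a strict
fixed-capacity discard would silently violate fluorophore conservation,
which the simulator instead asserts per trial. Retrograde trains draw
their particles uniformly without replacement (hypergeometric, which the
frozen-pool oracle test computes exactly).

The total particle count per train is not measured (only the fluorophore
count is); `particlesPerTrain = 18` is a model knob. Consequently the
measured detectable-train counts for one/two/three gated trains
(2.4/3.6/4.2) are treated as an approximate, configuration-sensitive band;
the robust predictions — sub-proportional growth (power-law exponent
n < 1), exact proportionality in the no-mixing limit, monotonicity in the
fluorophore budget — are what the tests pin down. `darkArrivals = FALSE`
realizes the no-mixing limit by switching off pool replenishment.

## FRAP and flux balance

The FRAP forward model is the cosine-series solution of 1D diffusion on a
finite domain with no-flux ends, bleached by a step of configurable depth
in a 5 µm central window of a 12 µm flagellum. The exact boundary
conditions were an open choice; no-flux at both ends is accurate on the
fit window's timescale, while basal absorption matters only on much longer
timescales — the steady-state module handles that regime. The fit
(`fitFrap1d`) frees D, bleach depth and baseline, with a residual
bootstrap CI; its metadata records these choices. The series conserves
total signal to machine precision (the n = 0 mode), and an independent
lattice-walker ensemble reproduces the post-bleach profile — site pairs
are averaged in that comparison because a strict ±1 walk is bipartite and
carries a checkerboard parity artifact the continuum equation does not.

Trace removal for background gradients takes explicit masks rather than
attempting automated kymograph segmentation, mirroring the manual
annotation step of the experimental workflow. Flux balance is unit-bridged in
camera intensities: efflux `|dI/dx|·D` versus influx
`train intensity × frequency`, both in intensity units s⁻¹, with no
absolute molecule calibration attempted. On the transport model's own
steady state this balance closes identically (everything injected exits
the base), which the suite uses as an internal consistency check.

## Steady-state kinesin-II return

The flagellum is a lattice of spacing √(2DΔt) — the root-mean-squared
displacement per 5 ms time step, the only reading of "spacing defined as
the MSD" that is dimensionally consistent — with a tip source fed by
`injectionRate × kapPerTrain`, ±1 steps, a tip site that steps only
baseward, and a perfectly absorbing base. Runs last 100,000 steps with the
first half discarded as burn-in (the burn-in fraction was open; half the
run is ≫ the ~42 s relaxation time at the default geometry and keeps the
averaging window long). Anterograde-bound motor is counted by
deterministic transit bookkeeping (`flux × L/v`), equivalent to simulating
train particles in steady state. Tip resting time defaults to zero —
negligible against the ~42 s return — with the pause available through
the trajectory generator instead.

The discrete walk's expected steady profile is linear — `2λi` per interior
site with a half-occupancy tip site and mean first-passage time `N²` steps,
exactly `L²/(2D)` when L is a multiple of the grid spacing — so the
analytic comparisons in the tests are exact, not approximations.
`kapPerTrain` is constant by default (6 per train); length-dependent
loading can be supplied by the user but no table ships, since those values
come from elsewhere. The diffusive/active accumulation ratio equals the
residence-time ratio `(T_antero + L²/2D) / (T_antero + T_retro)` by
Little's law; at L = 12 µm, D = 1.7 µm² s⁻¹ this is ≈4.9, and it is
length-sensitive (≈4–5 across 5–12 µm), hence the one-sided "≥ ~4-fold"
reading. Note the large-D limit of this ratio is
`T_antero/(T_antero + T_retro) < 1`, not 1: with instantaneous diffusive
return the flagellum holds *less* motor than with ballistic return, and
the property test asserts that limit.

## Problem sizes and numerics

The test suite and acceptance script size their simulations for laptop-
scale runs: 10⁴ walkers for return times, 10⁵-step steady states, 10⁴
increments for variance tests, 500 × 1000 bootstrap refits for CI
coverage, 27 × 5 s traces for MSD, 13-replicate FRAP averages, and
1000–3000 PhotoGate trials per condition; stochastic acceptance quantities
whose single-dataset sampling s.d. is comparable to their tolerance (the
Gamma shape at n = 97, the 97-arrival slope/intercept, the 27-trace D) are
reported as averages over replicate datasets of the stated size, which
estimates the same quantity with smaller Monte Carlo error. Seeds are
explicit everywhere; identical seeds give bit-identical output, and the
acceptance script derives all sub-seeds from its single `--seed`.

## Known limitations

- Imaging realism: Gaussian PSF + Poisson noise only; no EMCCD excess
  noise, evanescent-field decay, or flagellar curvature. Estimator
  performance on real TIRF data will be somewhat worse than on these
  synthetics.
- The PhotoGate pool's turnover discipline and train particle content are
  model knobs; only limits and trends, not absolute detectable counts, are
  identifiable.
- The FRAP fit ignores basal absorption within the fit window and models
  photofading only as a constant-rate option.
- The transport model does not feed back into length dynamics (no
  balance-point ODE) and ignores basal-body pool exchange with the
  cytoplasm.
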