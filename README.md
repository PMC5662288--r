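# iftdyn

Simulation and analysis of intraflagellar transport (IFT) dynamics at the
ciliary tip, built around single-molecule imaging of *Chlamydomonas*
flagella.

IFT trains carry axonemal building blocks from the cell body to the growing
flagellar tip (anterograde, kinesin-II–driven, ~2.1 µm s⁻¹) and back
(retrograde, dynein-1b–driven, ~3.0 µm s⁻¹). What happens at the tip — how
anterograde trains break down, mix, and reassemble into retrograde trains,
and how the kinesin-II motor itself gets back to the cell body — determines
steady-state flagellar length. `iftdyn` implements the quantitative
machinery needed to study these questions on single-molecule data, and the
stochastic models that interpret them:

- **Synthetic data generation** — Poisson train schedules, run/pause/diffuse
  KAP-GFP trajectories, kymographs with Gaussian line profiles and shot
  noise, 2D Gaussian spot image stacks, and FRAP bleach/recovery series
  (spectral solution of the 1D diffusion equation with no-flux ends).
- **Localization and tracking** — 2D Gaussian spot fitting with precision
  estimates and doublet flagging, nearest-neighbour linking with gap
  closing, velocity fits, polynomial-centerline lateral-fluctuation
  analysis, and time-averaged MSD fitting (`MSD = 2Dτ + offset`).
- **Tip turnaround kinetics** — extraction of tip resting times (arrival of
  a fluorescent anterograde train to departure of the k-th retrograde
  train), maximum-likelihood Gamma dwell-time fits with parametric-bootstrap
  CIs, the linear model `mean resting time = T_r + k·Δt` (remodeling time
  and inter-departure interval), and a mechanistic multistep turnaround
  simulator.
- **PhotoGate Monte Carlo** — fluorophore bookkeeping for gated
  single-train experiments: ~6 GFPs per train, photobleaching at 0.07 s⁻¹
  under TIR illumination, mixing into a dark tip pool, random repackaging
  into retrograde trains, detectability counting and power-law
  (`y = a·xⁿ`) analysis of sub-proportional mixing.
- **Diffusion and flux balance** — FRAP fitting with free D, bleach depth
  and baseline; kymograph background gradients after trace removal; and
  Fick's-law flux balance (efflux `|dI/dx|·D` versus influx
  `train intensity × frequency`).
- **Steady-state transport model** — a lattice random walk (spacing
  `√(2DΔt)`) of kinesin-II released at the tip with an absorbing base:
  linear concentration gradients, mean return times (`L²/2D ≈ 42 s` for a
  12 µm flagellum at 1.7 µm² s⁻¹), and the ~4–5-fold accumulation of
  kinesin-II relative to a hypothetical active-return scenario.

The central containers (`TrafficConfig`, `Trajectory`, `Kymograph`,
`FrapSeries`, `PhotoGateConfig`/`PhotoGateResult`,
`TransportConfig`/`SteadyState`) are S4 classes with validity checks and
accessors; fit results are plain lists with print methods. Random-walk
inner loops are implemented in C++ (Rcpp).

## Worked example

Fit the tip-turnaround kinetics of an annotated event table (a small
synthetic example ships with the package), then ask how long tip-released
kinesin-II needs to diffuse home:

```r
library(iftdyn)

events <- read.csv(system.file("extdata", "synthetic_tip_events.csv",
                               package = "iftdyn"))
rec <- extractTipEvents(events)   # one record per retrograde departure
fitRestingVsIndex(rec)
#> linearTipModel: remodeling time 0.92 +/- 0.85 s, Delta t 1.70 +/- 0.31 s

set.seed(1)
fitGammaMl(rgamma(97, 3, 1), nBoot = 1000)
#> gammaFit: alpha = 3.72 [2.47, 4.51], lambda = 1.28 [0.83, 1.58] 1/s (n = 97)

meanReturnTime(12, 1.7)                                    # analytic L^2/(2D)
#> [1] 42.35294
meanReturnTime(12, 1.7, "simulation", nWalkers = 1e4, seed = 1)$mean
#> [1] 42.306

compareReturnModes(transportConfig(seed = 1), nRepeats = 10)$ratio
#> [1] 4.934599
```

The linear fit reads: successive retrograde trains leave the tip every
`Δt ≈ 1.7` s, after a departure-order-independent remodeling period
(y-intercept) in which the arrived anterograde train is broken down. The
Gamma fit's shape parameter of ~3 (here recovered from 97 simulated dwell
times with its bootstrap CI) indicates that turnaround is a multistep
process — a single rate-limiting step would give an exponential (shape 1).
The last three numbers show that a kinesin-II motor released at the tip of
a full-length (12 µm) flagellum takes ~42 s to diffuse back to the base —
an order of magnitude longer than the 4 s retrograde transit — so diffusive
return holds ~5-fold more kinesin-II in the flagellum than active transport
would.

See `vignettes/ift-tip-dynamics.Rmd` for the models, assumptions and
parameter choices.

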