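#' Create a transport-model configuration
#'
#' Constructor for [TransportConfig-class]. The flagellum is a 1D lattice
#' with spacing `sqrt(2 D dt)` (the root-mean-squared displacement per time
#' step, so the +/-1 walk reproduces D exactly), a tip source fed by
#' anterograde trains and a perfectly absorbing base.
#'
#' @param flagellumLength um (full-length default 12; 5-12 during regrowth)
#' @param D diffusion coefficient, um^2/s
#' @param timeStep s
#' @param injectionRate anterograde trains/s
#' @param kapPerTrain KAP molecules per train (constant loading; supply a
#'   length-dependent value yourself for regrowth scenarios)
#' @param anteroSpeed,retroSpeed um/s
#' @param nSteps simulation steps
#' @param burnInFraction fraction of steps discarded before averaging
#' @param seed integer seed
#' @return a [TransportConfig-class]
#' @export
transportConfig <- function(flagellumLength = 12, D = 1.7, timeStep = 0.005,
                            injectionRate = 1.3, kapPerTrain = 6,
                            anteroSpeed = 2.1, retroSpeed = 3.0,
                            nSteps = 1e5, burnInFraction = 0.5, seed = 1L) {
  new("TransportConfig", flagellumLength = flagellumLength, D = D,
      timeStep = timeStep, injectionRate = injectionRate,
      kapPerTrain = kapPerTrain, anteroSpeed = anteroSpeed,
      retroSpeed = retroSpeed, nSteps = nSteps,
      burnInFraction = burnInFraction, seed = as.integer(seed))
}

#' Simulate the steady state of diffusive kinesin-II return
#'
#' Molecules are injected at the tip at rate `injectionRate * kapPerTrain`,
#' perform a +/-1 lattice walk (grid spacing `sqrt(2 D dt)`; the tip site
#' steps only baseward) and are absorbed at the base. Occupancy is
#' time-averaged after the burn-in. Anterograde-bound molecules are counted
#' by deterministic transit bookkeeping, `injectionRate * kapPerTrain *
#' L / anteroSpeed`, equivalent to simulating train particles in steady
#' state.
#'
#' @param config a [TransportConfig-class]
#' @param seed optional integer seed; defaults to the config seed
#' @return a [SteadyState-class]
#' @examples
#' ss <- simulateSteadyState(transportConfig(nSteps = 2e4, seed = 13))
#' totalDiffusing(ss)
#' @export
simulateSteadyState <- function(config, seed = config@seed) {
  stopifnot(is(config, "TransportConfig"))
  if (!is.null(seed)) set.seed(seed)
  dx <- sqrt(2 * config@D * config@timeStep)
  nSites <- max(2L, round(config@flagellumLength / dx))
  injMean <- config@injectionRate * config@kapPerTrain * config@timeStep
  burnIn <- floor(config@nSteps * config@burnInFraction)
  res <- steady_state_walk(nSites, as.integer(config@nSteps), injMean,
                           as.integer(burnIn))
  rt <- res$returnSteps * config@timeStep
  new("SteadyState",
      occupancy = res$occupancy,
      gridSpacing = dx,
      totalDiffusing = res$meanDiffusing,
      anteroBound = config@injectionRate * config@kapPerTrain *
        config@flagellumLength / config@anteroSpeed,
      meanReturnTime = if (length(rt)) mean(rt) else NA_real_,
      returnTimes = rt,
      injected = res$injected, absorbed = res$absorbed,
      inFlagellum = res$inFlagellum,
      config = config)
}

#' Mean tip-to-base return time by diffusion
#'
#' First-passage time from a reflecting tip to an absorbing base for 1D
#' diffusion: analytically `L^2 / (2 D)`, or the mean absorption time of an
#' ensemble of lattice walkers released at the tip (the two agree within
#' Monte Carlo error).
#'
#' @param L flagellum length, um
#' @param D diffusion coefficient, um^2/s
#' @param method `"analytic"` or `"simulation"`
#' @param nWalkers walkers for the simulation
#' @param timeStep s (simulation)
#' @param seed optional integer seed (simulation)
#' @return for `"analytic"` the time in s; for `"simulation"` a list
#'   `mean` (s), `sem`, `n`
#' @examples
#' meanReturnTime(12, 1.7)                      # 42.35 s
#' @export
meanReturnTime <- function(L, D, method = c("analytic", "simulation"),
                           nWalkers = 1e4, timeStep = 0.005, seed = NULL) {
  method <- match.arg(method)
  if (L <= 0 || D <= 0) stop("L and D must be positive")
  if (method == "analytic") return(L^2 / (2 * D))
  if (!is.null(seed)) set.seed(seed)
  dx <- sqrt(2 * D * timeStep)
  nSites <- max(2L, round(L / dx))
  steps <- walk_return_steps(as.integer(nWalkers), nSites)
  times <- steps * timeStep
  list(mean = mean(times), sem = sd(times) / sqrt(length(times)),
       n = length(times))
}

#' Steady-state accumulation: diffusive versus active return
#'
#' Ratio of total steady-state KAP in the flagellum (diffusing/returning plus
#' anterograde-bound) under diffusive return to the same total under a
#' hypothetical scenario in which tip-released KAP returns ballistically on
#' retrograde trains (retrograde-bound counted by transit bookkeeping,
#' `injectionRate * kapPerTrain * L / retroSpeed`). Repeated `nRepeats`
#' times for error bars.
#'
#' @param config a [TransportConfig-class] (needs `retroSpeed`)
#' @param nRepeats independent simulation repeats
#' @param seed optional integer seed; defaults to the config seed
#' @return list: `ratio` (mean fold-difference), `sd`, `perRepeat`,
#'   `diffusiveTotal`, `activeTotal`
#' @export
compareReturnModes <- function(config, nRepeats = 10, seed = config@seed) {
  stopifnot(is(config, "TransportConfig"))
  if (!.posScalar(config@retroSpeed))
    stop("retroSpeed missing from the configuration")
  if (!is.null(seed)) set.seed(seed)
  flux <- config@injectionRate * config@kapPerTrain
  antero <- flux * config@flagellumLength / config@anteroSpeed
  retro <- flux * config@flagellumLength / config@retroSpeed
  activeTotal <- antero + retro
  ratios <- numeric(nRepeats)
  diffTotals <- numeric(nRepeats)
  for (i in seq_len(nRepeats)) {
    ss <- simulateSteadyState(config, seed = NULL)  # continue RNG stream
    diffTotals[i] <- totalDiffusing(ss) + antero
    ratios[i] <- diffTotals[i] / activeTotal
  }
  list(ratio = mean(ratios), sd = sd(ratios), perRepeat = ratios,
       diffusiveTotal = mean(diffTotals), activeTotal = activeTotal)
}

#' Analytic steady-state occupancy profile
#'
#' Steady solution of the diffusion equation with a constant source at the
#' tip and an absorbing base: a linear gradient rising from 0 at the base to
#' its maximum at the tip. Returned per lattice site for direct comparison
#' with [simulateSteadyState] occupancy (expected site occupancy
#' `flux * dt * site index` for a discrete source-sink walk).
#'
#' @param config a [TransportConfig-class]
#' @return numeric vector of expected occupancies per site
#' @export
analyticOccupancy <- function(config) {
  stopifnot(is(config, "TransportConfig"))
  dx <- sqrt(2 * config@D * config@timeStep)
  nSites <- max(2L, round(config@flagellumLength / dx))
  flux <- config@injectionRate * config@kapPerTrain * config@timeStep
  # expected post-move steady occupancy (sink at 0, source at nSites):
  # 2*flux*i for interior sites; the tip site holds half its neighbour's
  # load because molecules there always step baseward
  occ <- 2 * flux * seq_len(nSites)
  occ[nSites] <- flux * (nSites - 1)
  occ
}
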