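#' @import methods
#' @importFrom stats approx coef dgamma lm optim pgamma pnorm predict qnorm
#'   quantile rexp rgamma rnorm rpois runif sd t.test var vcov
#' @importFrom utils head read.csv tail write.csv
#' @useDynLib iftdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.posScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
.nonNegScalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0

#' Traffic and imaging configuration for a simulated flagellum
#'
#' Holds the geometry, transport statistics and imaging parameters that define
#' a simulated flagellum: length, anterograde/retrograde speed distributions,
#' train injection frequency, the ratio of retrograde to anterograde train
#' frequencies, and camera/PSF parameters. Defaults reproduce wild-type
#' *Chlamydomonas* IFT traffic: anterograde 2.1 +/- 0.4 um/s, retrograde
#' 3.0 +/- 0.7 um/s, 1.3 trains/s injected, retro/antero frequency ratio 1.15,
#' 10 Hz imaging with 106 nm pixels.
#'
#' @slot flagellumLength flagellar length L, um (base at 0, tip at L)
#' @slot anteroSpeedMean,anteroSpeedSd anterograde train speed, um/s
#' @slot retroSpeedMean,retroSpeedSd retrograde train speed, um/s
#' @slot anteroFrequency anterograde train injection rate, trains/s
#' @slot retroToAnteroRatio retrograde/anterograde train frequency ratio
#' @slot frameRate camera acquisition rate, Hz
#' @slot pixelSize effective camera pixel, nm
#' @slot psfSd point-spread-function Gaussian sd, nm
#' @slot photonsPerFrame photon budget of one spot per frame
#' @slot background background level, photons/pixel/frame
#' @slot seed integer RNG seed carried by the configuration
#' @exportClass TrafficConfig
setClass("TrafficConfig",
  representation(
    flagellumLength = "numeric",
    anteroSpeedMean = "numeric", anteroSpeedSd = "numeric",
    retroSpeedMean = "numeric", retroSpeedSd = "numeric",
    anteroFrequency = "numeric", retroToAnteroRatio = "numeric",
    frameRate = "numeric", pixelSize = "numeric",
    psfSd = "numeric", photonsPerFrame = "numeric", background = "numeric",
    seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in c("flagellumLength", "anteroSpeedMean", "retroSpeedMean",
                 "frameRate", "pixelSize", "psfSd", "photonsPerFrame"))
      if (!.posScalar(slot(object, nm)))
        msg <- c(msg, paste0(nm, " must be a positive scalar"))
    for (nm in c("anteroSpeedSd", "retroSpeedSd", "anteroFrequency",
                 "retroToAnteroRatio", "background"))
      if (!.nonNegScalar(slot(object, nm)))
        msg <- c(msg, paste0(nm, " must be a non-negative scalar"))
    if (.posScalar(object@anteroSpeedMean) &&
        object@anteroSpeedSd >= object@anteroSpeedMean)
      msg <- c(msg, "anteroSpeedSd must be smaller than anteroSpeedMean")
    if (.posScalar(object@retroSpeedMean) &&
        object@retroSpeedSd >= object@retroSpeedMean)
      msg <- c(msg, "retroSpeedSd must be smaller than retroSpeedMean")
    if (length(msg)) msg else TRUE
  })

#' Single-particle trajectory
#'
#' Time series of a tracked particle: axial position along the flagellum (um,
#' base = 0), lateral position (nm), per-frame intensity (photons) and a phase
#' label per sample (`"anterograde"`, `"tip_paused"` or `"diffusing"`).
#'
#' @slot times frame times, s (strictly increasing, 1/frameRate spacing)
#' @slot axial axial position, um
#' @slot lateral lateral position, nm
#' @slot intensity photons per frame
#' @slot phase character phase label per sample
#' @slot frameRate acquisition rate, Hz
#' @exportClass Trajectory
setClass("Trajectory",
  representation(times = "numeric", axial = "numeric", lateral = "numeric",
                 intensity = "numeric", phase = "character",
                 frameRate = "numeric"),
  validity = function(object) {
    n <- length(object@times)
    msg <- character()
    if (length(object@axial) != n || length(object@lateral) != n ||
        length(object@intensity) != n || length(object@phase) != n)
      msg <- c(msg, "times, axial, lateral, intensity and phase must have equal length")
    if (n > 1 && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(!is.finite(object@axial)))
      msg <- c(msg, "axial positions must be finite")
    bad <- setdiff(unique(object@phase),
                   c("anterograde", "retrograde", "tip_paused", "diffusing"))
    if (length(bad))
      msg <- c(msg, paste("unknown phase label(s):", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Kymograph (position x time intensity image)
#'
#' @slot image numeric matrix, rows = position pixels (base at row 1),
#'   columns = frames
#' @slot positionScale nm per row
#' @slot timeScale s per column
#' @slot maskedColumns integer indices of columns flagged as gate-on frames
#' @exportClass Kymograph
setClass("Kymograph",
  representation(image = "matrix", positionScale = "numeric",
                 timeScale = "numeric", maskedColumns = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@image) && any(object@image < 0, na.rm = TRUE))
      msg <- c(msg, "kymograph intensities must be non-negative")
    if (!.posScalar(object@positionScale) || !.posScalar(object@timeScale))
      msg <- c(msg, "positionScale and timeScale must be positive")
    if (length(object@maskedColumns) &&
        (min(object@maskedColumns) < 1 ||
         max(object@maskedColumns) > ncol(object@image)))
      msg <- c(msg, "maskedColumns out of range")
    if (length(msg)) msg else TRUE
  })

#' FRAP concentration series
#'
#' Spatial concentration profile over time for a fluorescence recovery after
#' photobleaching experiment on a finite 1D domain with no-flux ends.
#'
#' @slot positions grid positions, um
#' @slot times frame times, s (bleach applied at `bleachTime`)
#' @slot profile matrix, length(positions) x length(times)
#' @slot bleachWindow c(start, end), um
#' @slot bleachTime s
#' @slot bleachDepth fraction of signal removed inside the window at bleach
#' @slot noise noise model used, `"none"` or `"shot"`
#' @exportClass FrapSeries
setClass("FrapSeries",
  representation(positions = "numeric", times = "numeric", profile = "matrix",
                 bleachWindow = "numeric", bleachTime = "numeric",
                 bleachDepth = "numeric", noise = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@profile) != length(object@positions) ||
        ncol(object@profile) != length(object@times))
      msg <- c(msg, "profile must be length(positions) x length(times)")
    if (length(object@bleachWindow) != 2L ||
        object@bleachWindow[1] >= object@bleachWindow[2])
      msg <- c(msg, "bleachWindow must be an increasing (start, end) pair")
    if (!object@noise %in% c("none", "shot"))
      msg <- c(msg, "noise must be 'none' or 'shot'")
    if (length(msg)) msg else TRUE
  })

#' Configuration of the photogate fluorophore-counting Monte Carlo
#'
#' Parameters of the fluorophore bookkeeping simulation: a limited number of
#' GFPs per anterograde train, photobleaching under TIR illumination,
#' a shared dark tip pool, random repackaging into retrograde trains and a
#' detectability threshold.
#'
#' @slot gfpsPerTrain fluorescent GFPs per anterograde train (default 6)
#' @slot bleachRate GFP photobleaching rate under TIR illumination, 1/s
#'   (default 0.07)
#' @slot dutyCycle fraction of time the imaging beam illuminates the flagellum
#'   (gate on 0.2 s of every 1 s, imaging 0.8 s: default 0.8)
#' @slot tipPoolTrainEquivalents tip pool size in units of one train's
#'   particle content (default 3)
#' @slot particlesPerTrain IFT particles per anterograde train; only the
#'   fluorophore count is measured, so this is a model knob
#' @slot nFluorescentIn number of fluorescent anterograde trains admitted
#'   through the gate (1-3)
#' @slot anteroFrequency,retroToAnteroRatio train traffic statistics
#' @slot anteroSpeed,retroSpeed train speeds, um/s
#' @slot flagellumLength um
#' @slot detectionThreshold minimum unbleached GFPs for a retrograde train to
#'   be scored detectable (>= 1)
#' @slot nTrials Monte Carlo trials
#' @slot seed integer RNG seed
#' @exportClass PhotoGateConfig
setClass("PhotoGateConfig",
  representation(gfpsPerTrain = "numeric", bleachRate = "numeric",
                 dutyCycle = "numeric", tipPoolTrainEquivalents = "numeric",
                 particlesPerTrain = "numeric", nFluorescentIn = "numeric",
                 anteroFrequency = "numeric", retroToAnteroRatio = "numeric",
                 anteroSpeed = "numeric", retroSpeed = "numeric",
                 flagellumLength = "numeric", detectionThreshold = "numeric",
                 nTrials = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in c("gfpsPerTrain", "tipPoolTrainEquivalents", "particlesPerTrain",
                 "anteroFrequency", "retroToAnteroRatio", "anteroSpeed",
                 "retroSpeed", "flagellumLength", "nTrials"))
      if (!.posScalar(slot(object, nm)))
        msg <- c(msg, paste0(nm, " must be a positive scalar"))
    if (!.nonNegScalar(object@bleachRate))
      msg <- c(msg, "bleachRate must be non-negative")
    if (!(object@dutyCycle > 0 && object@dutyCycle <= 1))
      msg <- c(msg, "dutyCycle must lie in (0, 1]")
    if (!object@nFluorescentIn %in% c(1, 2, 3))
      msg <- c(msg, "nFluorescentIn must be 1, 2 or 3")
    if (object@detectionThreshold < 1)
      msg <- c(msg, "detectionThreshold must be >= 1")
    if (object@tipPoolTrainEquivalents < 1)
      msg <- c(msg, "tip pool must hold at least one train equivalent")
    if (length(msg)) msg else TRUE
  })

#' Result of the photogate Monte Carlo
#'
#' @slot counts detectable retrograde train count per trial
#' @slot nIn number of fluorescent anterograde trains admitted
#' @slot meanCount,semCount summary of `counts`
#' @slot returnFrequency detectable-train return frequency, 1/s
#' @slot config the [PhotoGateConfig-class] used
#' @exportClass PhotoGateResult
setClass("PhotoGateResult",
  representation(counts = "numeric", nIn = "numeric", meanCount = "numeric",
                 semCount = "numeric", returnFrequency = "numeric",
                 config = "PhotoGateConfig"),
  validity = function(object) {
    if (any(object@counts < 0)) "counts must be non-negative" else TRUE
  })

#' Configuration of the steady-state kinesin-II return model
#'
#' The flagellum is a 1D lattice with spacing sqrt(2 D dt), a tip source fed
#' by anterograde trains and a perfectly absorbing base. Defaults follow the
#' full-length flagellum scenario: L = 12 um, D = 1.7 um^2/s, 5 ms time step,
#' 1.3 trains/s, 100,000 steps with the first half as burn-in.
#'
#' @slot flagellumLength um
#' @slot D diffusion coefficient, um^2/s
#' @slot timeStep s
#' @slot injectionRate anterograde train injection rate, trains/s
#' @slot kapPerTrain KAP molecules carried per train (constant loading)
#' @slot anteroSpeed,retroSpeed um/s (retro used by the active-return scenario)
#' @slot nSteps simulation steps
#' @slot burnInFraction fraction of steps discarded before averaging
#' @slot seed integer RNG seed
#' @exportClass TransportConfig
setClass("TransportConfig",
  representation(flagellumLength = "numeric", D = "numeric",
                 timeStep = "numeric", injectionRate = "numeric",
                 kapPerTrain = "numeric", anteroSpeed = "numeric",
                 retroSpeed = "numeric", nSteps = "numeric",
                 burnInFraction = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    for (nm in c("flagellumLength", "D", "timeStep", "kapPerTrain",
                 "anteroSpeed", "retroSpeed", "nSteps"))
      if (!.posScalar(slot(object, nm)))
        msg <- c(msg, paste0(nm, " must be a positive scalar"))
    if (!.nonNegScalar(object@injectionRate))
      msg <- c(msg, "injectionRate must be non-negative")
    if (!(object@burnInFraction >= 0 && object@burnInFraction < 1))
      msg <- c(msg, "burnInFraction must be in [0, 1)")
    dx <- sqrt(2 * object@D * object@timeStep)
    if (.posScalar(object@flagellumLength) &&
        dx > object@flagellumLength / 10)
      msg <- c(msg, "time step too large: grid spacing sqrt(2 D dt) exceeds L/10")
    if (length(msg)) msg else TRUE
  })

#' Steady state of the diffusive-return transport model
#'
#' @slot occupancy time-averaged molecule count per lattice site (site 1 is
#'   adjacent to the basal sink, the last site is the tip)
#' @slot gridSpacing um per site
#' @slot totalDiffusing time-averaged total diffusing molecules
#' @slot anteroBound steady-state molecules bound to anterograde trains
#' @slot meanReturnTime mean tip-to-base return time of absorbed molecules, s
#' @slot returnTimes individual return times, s
#' @slot injected,absorbed,inFlagellum molecule bookkeeping totals
#' @slot config the [TransportConfig-class] used
#' @exportClass SteadyState
setClass("SteadyState",
  representation(occupancy = "numeric", gridSpacing = "numeric",
                 totalDiffusing = "numeric", anteroBound = "numeric",
                 meanReturnTime = "numeric", returnTimes = "numeric",
                 injected = "numeric", absorbed = "numeric",
                 inFlagellum = "numeric", config = "TransportConfig"),
  validity = function(object) {
    msg <- character()
    if (any(object@occupancy < 0)) msg <- c(msg, "occupancy must be non-negative")
    if (abs(object@injected - (object@absorbed + object@inFlagellum)) > 1e-6)
      msg <- c(msg, "molecule conservation violated: injected != absorbed + in flagellum")
    if (length(msg)) msg else TRUE
  })
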