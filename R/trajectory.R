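#' Construct a Trajectory
#'
#' @param times frame times, s
#' @param axial axial positions, um (base = 0)
#' @param lateral lateral positions, nm
#' @param intensity photons per frame (defaults to NA-free zeros)
#' @param phase per-sample phase labels
#' @param frameRate acquisition rate, Hz
#' @return a [Trajectory-class]
#' @export
trajectory <- function(times, axial, lateral = rep(0, length(times)),
                       intensity = rep(0, length(times)),
                       phase = rep("diffusing", length(times)),
                       frameRate = 1 / stats::median(diff(times))) {
  new("Trajectory", times = as.numeric(times), axial = as.numeric(axial),
      lateral = as.numeric(lateral), intensity = as.numeric(intensity),
      phase = as.character(phase), frameRate = frameRate)
}

#' Simulate a kinesin-II (KAP) trajectory: run, pause, diffuse back
#'
#' Generates the canonical KAP-GFP trajectory: a constant-velocity
#' anterograde run from base to tip, a pause at the tip, then 1D Brownian
#' motion (axial increments of variance 2 D dt) reflected at both ends, with
#' an optional absorbing base that terminates the trace (return to the cell
#' body). Gaussian localization noise of sd `locNoise` nm is added to the
#' axial coordinate. The lateral coordinate is drawn per phase with sd
#' `lateralSdTransport` (run/pause) or `lateralSdDiffusing` (diffusion);
#' these are the *observed* scatters - at this scale the tracking error and
#' true lateral motion are not separable, so the parameter sets the sd of
#' the rendered coordinate directly.
#'
#' @param config a [TrafficConfig-class]
#' @param tipPause tip pause duration, s (>= 0)
#' @param D diffusion coefficient of the return phase, um^2/s (>= 0)
#' @param lateralSdTransport observed lateral scatter during transport, nm
#' @param lateralSdDiffusing observed lateral scatter during diffusion, nm
#' @param locNoise axial localization noise sd, nm
#' @param diffusionDuration length of the diffusing phase, s (shorter if the
#'   base absorbs the particle first and `absorbingBase` is TRUE)
#' @param speed anterograde speed, um/s; default drawn from the config's
#'   truncated-normal anterograde distribution
#' @param absorbingBase if TRUE the trace ends when the diffusing particle
#'   first crosses the base
#' @param seed optional integer seed; defaults to the config seed
#' @return a [Trajectory-class] with phases `"anterograde"`, `"tip_paused"`
#'   and `"diffusing"`
#' @examples
#' tr <- makeKapTrajectory(trafficConfig(seed = 3), tipPause = 2, D = 1.68)
#' table(phaseLabels(tr))
#' @export
makeKapTrajectory <- function(config, tipPause = 2.2, D = 1.68,
                              lateralSdTransport = 19,
                              lateralSdDiffusing = 65,
                              locNoise = 20,
                              diffusionDuration = 5,
                              speed = NULL,
                              absorbingBase = FALSE,
                              seed = config@seed) {
  stopifnot(is(config, "TrafficConfig"))
  if (D < 0) stop("D must be >= 0")
  if (tipPause < 0) stop("tipPause must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / config@frameRate
  L <- config@flagellumLength
  if (is.null(speed)) speed <- rtruncnorm0(1, config@anteroSpeedMean,
                                           config@anteroSpeedSd)

  nRun <- max(2L, ceiling(L / speed / dt))
  xRun <- pmin(speed * dt * seq_len(nRun), L)
  nPause <- round(tipPause / dt)
  xPause <- rep(L, nPause)

  nDiff <- round(diffusionDuration / dt)
  xDiff <- numeric(nDiff)
  if (nDiff > 0) {
    x <- L
    stepSd <- sqrt(2 * D * dt)
    for (i in seq_len(nDiff)) {
      x <- x + rnorm(1, 0, stepSd)
      # reflect into [0, L] (repeatedly, in case of large excursions)
      while (x < 0 || x > L) {
        if (x < 0) {
          if (absorbingBase) { x <- NA_real_; break }
          x <- -x
        }
        if (!is.na(x) && x > L) x <- 2 * L - x
      }
      if (is.na(x)) { nDiff <- i - 1L; xDiff <- xDiff[seq_len(nDiff)]; break }
      xDiff[i] <- x
    }
  }

  axialTrue <- c(xRun, xPause, xDiff)
  n <- length(axialTrue)
  phase <- c(rep("anterograde", nRun), rep("tip_paused", nPause),
             rep("diffusing", nDiff))
  lateral <- numeric(n)
  transportIdx <- phase != "diffusing"
  lateral[transportIdx] <- rnorm(sum(transportIdx), 0, lateralSdTransport)
  lateral[!transportIdx] <- rnorm(sum(!transportIdx), 0, lateralSdDiffusing)

  axial <- axialTrue + rnorm(n, 0, locNoise / 1000)
  intensity <- rpois(n, config@photonsPerFrame)

  trj <- trajectory(times = dt * seq_len(n), axial = axial, lateral = lateral,
                    intensity = intensity, phase = phase, frameRate = config@frameRate)
  attr(trj, "axialTrue") <- axialTrue
  trj
}

#' Simulate an unbounded 1D Brownian trajectory
#'
#' Pure Brownian motion (no boundaries) sampled at `frameRate`, with Gaussian
#' localization noise; the reference input for validating the MSD estimator.
#'
#' @param D diffusion coefficient, um^2/s
#' @param duration trace length, s
#' @param frameRate Hz
#' @param locNoise localization noise sd, nm
#' @param start starting axial position, um
#' @param seed optional integer seed
#' @return a [Trajectory-class] with all samples labelled `"diffusing"`
#' @export
makeBrownianTrajectory <- function(D, duration = 5, frameRate = 10,
                                   locNoise = 20, start = 0, seed = NULL) {
  if (D < 0) stop("D must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / frameRate
  n <- round(duration * frameRate)
  x <- start + cumsum(c(0, rnorm(n, 0, sqrt(2 * D * dt))))
  xObs <- x + rnorm(n + 1, 0, locNoise / 1000)
  trajectory(times = dt * (0:n), axial = xObs,
             lateral = rnorm(n + 1, 0, 65),
             intensity = rep(0, n + 1),
             phase = rep("diffusing", n + 1), frameRate = frameRate)
}

#' Extract one phase of a trajectory
#'
#' @param traj a [Trajectory-class]
#' @param phase phase label to keep
#' @return a [Trajectory-class] restricted to the matching samples
#' @export
subsetPhase <- function(traj, phase) {
  stopifnot(is(traj, "Trajectory"))
  keep <- traj@phase == phase
  if (!any(keep)) stop("no samples in phase '", phase, "'")
  trajectory(times = traj@times[keep], axial = traj@axial[keep],
             lateral = traj@lateral[keep], intensity = traj@intensity[keep],
             phase = traj@phase[keep], frameRate = traj@frameRate)
}

#' Read/write a trajectory as CSV
#'
#' Columns: `time_s`, `x_um`, `y_nm`, `intensity`, `phase`.
#'
#' @param traj a [Trajectory-class]
#' @param path file path
#' @return `readTrajectoryCsv` returns a [Trajectory-class];
#'   `writeTrajectoryCsv` returns `path` invisibly.
#' @export
writeTrajectoryCsv <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  df <- data.frame(time_s = traj@times, x_um = traj@axial, y_nm = traj@lateral,
                   intensity = traj@intensity, phase = traj@phase)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  trajectory(times = df$time_s, axial = df$x_um, lateral = df$y_nm,
             intensity = df$intensity, phase = df$phase)
}
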