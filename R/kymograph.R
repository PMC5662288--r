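#' Render a kymograph from train events and/or trajectories
#'
#' Paints each moving particle as a Gaussian line profile (sd = PSF sd) into a
#' position x time grid. Rows are position pixels (base at row 1, tip at the
#' last row), columns are frames. Anterograde events start at the base at
#' `start_time` and move tipward at their speed; retrograde events start at
#' the tip. Trajectories are sampled at their own frame times. Optional
#' Poisson shot noise; optional masking of gate-on columns (0.2 s of every
#' 1 s), emulating the saturated frames of photogated movies.
#'
#' @param events a train-schedule data.frame (see [makeTrainSchedule]), a
#'   [Trajectory-class], a list of trajectories, or NULL for an empty kymograph
#' @param config a [TrafficConfig-class]
#' @param duration movie duration, s
#' @param amplitude photons/frame painted per particle (trains); trajectories
#'   use their own intensity channel
#' @param shotNoise add per-pixel Poisson noise
#' @param gateMask flag columns during gate-on intervals (0.2 s per 1 s) as
#'   masked
#' @param seed optional integer seed; defaults to the config seed
#' @return a [Kymograph-class]
#' @examples
#' cfg <- trafficConfig(seed = 4)
#' k <- renderKymograph(makeTrainSchedule(cfg, 30), cfg, duration = 30)
#' dim(k@image)
#' @export
renderKymograph <- function(events, config, duration,
                            amplitude = config@photonsPerFrame,
                            shotNoise = FALSE, gateMask = FALSE,
                            seed = config@seed) {
  stopifnot(is(config, "TrafficConfig"))
  if (!.posScalar(duration)) stop("duration must be a positive scalar")
  if (!is.null(seed)) set.seed(seed)

  dt <- 1 / config@frameRate
  pxUm <- config@pixelSize / 1000              # um per pixel
  nRow <- max(2L, ceiling(config@flagellumLength / pxUm))
  nCol <- max(1L, round(duration / dt))
  img <- matrix(config@background, nRow, nCol)
  rowCenters <- (seq_len(nRow) - 0.5) * pxUm   # um
  tCol <- (seq_len(nCol) - 0.5) * dt           # frame mid-times
  psfUm <- config@psfSd / 1000

  paint <- function(tSamp, xSamp, amp) {
    # map sample times onto columns; one Gaussian profile per sample
    amp <- rep_len(amp, length(tSamp))
    cols <- findInterval(tSamp, seq(0, nCol) * dt, rightmost.closed = TRUE)
    ok <- cols >= 1 & cols <= nCol & xSamp >= 0 &
      xSamp <= config@flagellumLength
    for (i in which(ok)) {
      prof <- amp[i] * exp(-(rowCenters - xSamp[i])^2 / (2 * psfUm^2))
      img[, cols[i]] <<- img[, cols[i]] + prof
    }
  }

  addEvent <- function(dirn, t0, v, amp) {
    if (dirn == "anterograde") {
      tEnd <- t0 + config@flagellumLength / v
      sel <- tCol >= t0 & tCol <= min(tEnd, duration)
      paint(tCol[sel], (tCol[sel] - t0) * v, amp)
    } else {
      tEnd <- t0 + config@flagellumLength / v
      sel <- tCol >= t0 & tCol <= min(tEnd, duration)
      paint(tCol[sel], config@flagellumLength - (tCol[sel] - t0) * v, amp)
    }
  }

  if (is(events, "Trajectory")) events <- list(events)
  if (is.data.frame(events)) {
    for (i in seq_len(nrow(events)))
      addEvent(events$direction[i], events$start_time[i], events$speed[i],
               amplitude)
  } else if (is.list(events)) {
    for (trj in events) {
      stopifnot(is(trj, "Trajectory"))
      paint(trj@times, trj@axial, trj@intensity)
    }
  } else if (!is.null(events)) {
    stop("events must be a schedule data.frame, Trajectory, list or NULL")
  }

  if (shotNoise) img <- matrix(rpois(length(img), img), nRow, nCol)

  masked <- integer(0)
  if (gateMask) {
    gateOn <- (tCol %% 1) < 0.2
    masked <- which(gateOn)
    img[, masked] <- NA_real_
  }

  new("Kymograph", image = img, positionScale = config@pixelSize,
      timeScale = dt, maskedColumns = as.integer(masked))
}

#' Write/read a kymograph as a single-page TIFF
#'
#' Intensities are stored as 32-bit floats scaled to the unit interval by the recorded
#' maximum (kept in the return attribute and restored on read via the
#' `scale` argument). Masked columns are written as zeros.
#'
#' @param kymo a [Kymograph-class]
#' @param path file path
#' @param positionScale,timeScale scales used to rebuild the object on read
#' @param scale intensity scale by which the stored unit-scaled image is multiplied
#' @return `readKymographTiff` returns a [Kymograph-class];
#'   `writeKymographTiff` returns the intensity scale invisibly.
#' @export
writeKymographTiff <- function(kymo, path) {
  stopifnot(is(kymo, "Kymograph"))
  img <- kymo@image
  img[is.na(img)] <- 0
  sc <- max(img, 1e-12)
  tiff::writeTIFF(img / sc, path, bits.per.sample = 32L)
  invisible(sc)
}

#' @rdname writeKymographTiff
#' @export
readKymographTiff <- function(path, positionScale, timeScale, scale = 1) {
  img <- tiff::readTIFF(path)
  new("Kymograph", image = img * scale, positionScale = positionScale,
      timeScale = timeScale, maskedColumns = integer(0))
}
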