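#' Create a traffic/imaging configuration
#'
#' Constructor for [TrafficConfig-class]. Defaults are the measured wild-type
#' values: anterograde 2.1 +/- 0.4 um/s, retrograde 3.0 +/- 0.7 um/s,
#' 1.3 anterograde trains/s and a retrograde/anterograde frequency ratio of
#' 1.15, imaged at 10 Hz with 106 nm pixels. The PSF width (130 nm) and the
#' photon budget are setup defaults chosen to give ~20 nm localization
#' precision per frame; they are not measured quantities.
#'
#' @param flagellumLength flagellar length, um
#' @param anteroSpeedMean,anteroSpeedSd anterograde speed distribution, um/s
#' @param retroSpeedMean,retroSpeedSd retrograde speed distribution, um/s
#' @param anteroFrequency anterograde train injection rate, trains/s
#' @param retroToAnteroRatio retrograde/anterograde frequency ratio
#' @param frameRate camera rate, Hz
#' @param pixelSize camera pixel, nm
#' @param psfSd PSF Gaussian sd, nm
#' @param photonsPerFrame spot photon budget per frame
#' @param background background photons per pixel per frame
#' @param seed integer RNG seed stored with the configuration
#' @return a [TrafficConfig-class] object
#' @examples
#' cfg <- trafficConfig(seed = 1)
#' cfg
#' @export
trafficConfig <- function(flagellumLength = 12,
                          anteroSpeedMean = 2.1, anteroSpeedSd = 0.4,
                          retroSpeedMean = 3.0, retroSpeedSd = 0.7,
                          anteroFrequency = 1.3, retroToAnteroRatio = 1.15,
                          frameRate = 10, pixelSize = 106,
                          psfSd = 130, photonsPerFrame = 150, background = 5,
                          seed = 1L) {
  new("TrafficConfig",
      flagellumLength = flagellumLength,
      anteroSpeedMean = anteroSpeedMean, anteroSpeedSd = anteroSpeedSd,
      retroSpeedMean = retroSpeedMean, retroSpeedSd = retroSpeedSd,
      anteroFrequency = anteroFrequency,
      retroToAnteroRatio = retroToAnteroRatio,
      frameRate = frameRate, pixelSize = pixelSize, psfSd = psfSd,
      photonsPerFrame = photonsPerFrame, background = background,
      seed = as.integer(seed))
}

#' Read/write a traffic configuration as JSON
#'
#' The JSON keys carry explicit units (e.g. `anterograde_speed_um_per_s`).
#'
#' @param path file path
#' @param config a [TrafficConfig-class]
#' @return `readTrafficConfig` returns a [TrafficConfig-class];
#'   `writeTrafficConfig` returns `path` invisibly.
#' @export
writeTrafficConfig <- function(config, path) {
  x <- list(
    flagellum_length_um = config@flagellumLength,
    anterograde_speed_um_per_s = config@anteroSpeedMean,
    anterograde_speed_sd_um_per_s = config@anteroSpeedSd,
    retrograde_speed_um_per_s = config@retroSpeedMean,
    retrograde_speed_sd_um_per_s = config@retroSpeedSd,
    anterograde_frequency_per_s = config@anteroFrequency,
    retro_to_antero_ratio = config@retroToAnteroRatio,
    frame_rate_hz = config@frameRate,
    pixel_size_nm = config@pixelSize,
    psf_sd_nm = config@psfSd,
    photons_per_frame = config@photonsPerFrame,
    background_photons_per_px = config@background,
    rng_seed = config@seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTrafficConfig
#' @export
readTrafficConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trafficConfig(
    flagellumLength = x$flagellum_length_um,
    anteroSpeedMean = x$anterograde_speed_um_per_s,
    anteroSpeedSd = x$anterograde_speed_sd_um_per_s,
    retroSpeedMean = x$retrograde_speed_um_per_s,
    retroSpeedSd = x$retrograde_speed_sd_um_per_s,
    anteroFrequency = x$anterograde_frequency_per_s,
    retroToAnteroRatio = x$retro_to_antero_ratio,
    frameRate = x$frame_rate_hz,
    pixelSize = x$pixel_size_nm,
    psfSd = x$psf_sd_nm,
    photonsPerFrame = x$photons_per_frame,
    background = x$background_photons_per_px,
    seed = x$rng_seed)
}

# Truncated-normal speed draw (truncated at zero): inverse-CDF sampling so a
# single runif per draw suffices and seeds reproduce exactly.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(0, mean, sd)
  qnorm(lo + runif(n) * (1 - lo), mean, sd)
}
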