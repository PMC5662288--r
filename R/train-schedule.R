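#' Simulate a schedule of IFT train events
#'
#' Anterograde train injections at the flagellar base form a Poisson process
#' at `anteroFrequency`; retrograde departures from the tip form an
#' independent Poisson process at `anteroFrequency * retroToAnteroRatio`,
#' started once the first anterograde train has reached the tip (retrograde
#' material cannot leave a tip that nothing has reached). Speeds are drawn
#' from normal distributions truncated at zero.
#'
#' @param config a [TrafficConfig-class]
#' @param duration observation window, s (> 0)
#' @param nFluorophores fluorescent GFPs assigned to each anterograde train
#' @param seed optional integer seed; defaults to the seed in `config`
#' @return a data.frame with columns `direction` ("anterograde"/"retrograde"),
#'   `start_time` (s), `speed` (um/s) and `n_fluorophores`, ordered by start
#'   time. Anterograde `start_time` is the injection time at the base;
#'   retrograde `start_time` is the departure time from the tip.
#' @examples
#' sched <- makeTrainSchedule(trafficConfig(seed = 2), duration = 100)
#' table(sched$direction)
#' @export
makeTrainSchedule <- function(config, duration, nFluorophores = 6,
                              seed = config@seed) {
  stopifnot(is(config, "TrafficConfig"))
  if (!.posScalar(duration)) stop("duration must be a positive scalar")
  if (!is.null(seed)) set.seed(seed)

  fA <- config@anteroFrequency
  nA <- if (fA > 0) rpois(1, fA * duration) else 0L
  tA <- sort(runif(nA, 0, duration))
  vA <- rtruncnorm0(nA, config@anteroSpeedMean, config@anteroSpeedSd)

  ante <- data.frame(direction = rep("anterograde", nA),
                     start_time = tA, speed = vA,
                     n_fluorophores = rep(nFluorophores, nA),
                     stringsAsFactors = FALSE)

  retro <- data.frame(direction = character(0), start_time = numeric(0),
                      speed = numeric(0), n_fluorophores = numeric(0),
                      stringsAsFactors = FALSE)
  fR <- fA * config@retroToAnteroRatio
  if (nA > 0 && fR > 0) {
    # first tip arrival gates the retrograde process
    tTip <- min(tA + config@flagellumLength / vA)
    if (tTip < duration) {
      nR <- rpois(1, fR * (duration - tTip))
      tR <- sort(runif(nR, tTip, duration))
      vR <- rtruncnorm0(nR, config@retroSpeedMean, config@retroSpeedSd)
      retro <- data.frame(direction = rep("retrograde", nR),
                          start_time = tR, speed = vR,
                          n_fluorophores = rep(0, nR),
                          stringsAsFactors = FALSE)
    }
  }
  out <- rbind(ante, retro)
  out <- out[order(out$start_time), , drop = FALSE]
  rownames(out) <- NULL
  out
}
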