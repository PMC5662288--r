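#' Create a photogate Monte Carlo configuration
#'
#' Defaults follow the measured photophysics and traffic: 6 fluorescent GFPs
#' per anterograde train, 0.07/s photobleaching under TIR illumination with a
#' 0.8 imaging duty cycle, a tip pool holding three train equivalents of dark
#' particles, 1.3 anterograde trains/s with a retro/antero frequency ratio of
#' 1.15 and speeds of 2.1/3.0 um/s. The total particle content of a train is
#' not measured; `particlesPerTrain` is a model knob (default 18, i.e. one
#' GFP per third particle).
#'
#' @param gfpsPerTrain fluorescent GFPs per anterograde train
#' @param bleachRate photobleaching rate under TIR illumination, 1/s
#' @param dutyCycle illuminated fraction of each second (imaging 0.8 s / 1 s)
#' @param tipPoolTrainEquivalents tip pool size, train equivalents (>= 1)
#' @param particlesPerTrain IFT particles per train
#' @param nFluorescentIn fluorescent anterograde trains admitted (1-3)
#' @param anteroFrequency,retroToAnteroRatio train traffic
#' @param anteroSpeed,retroSpeed um/s
#' @param flagellumLength um
#' @param detectionThreshold minimum unbleached GFPs for detectability
#' @param nTrials Monte Carlo trials
#' @param seed integer seed
#' @return a [PhotoGateConfig-class]
#' @export
photoGateConfig <- function(gfpsPerTrain = 6, bleachRate = 0.07,
                            dutyCycle = 0.8, tipPoolTrainEquivalents = 3,
                            particlesPerTrain = 18, nFluorescentIn = 1,
                            anteroFrequency = 1.3, retroToAnteroRatio = 1.15,
                            anteroSpeed = 2.1, retroSpeed = 3.0,
                            flagellumLength = 12, detectionThreshold = 1,
                            nTrials = 1000, seed = 1L) {
  new("PhotoGateConfig", gfpsPerTrain = gfpsPerTrain, bleachRate = bleachRate,
      dutyCycle = dutyCycle, tipPoolTrainEquivalents = tipPoolTrainEquivalents,
      particlesPerTrain = particlesPerTrain, nFluorescentIn = nFluorescentIn,
      anteroFrequency = anteroFrequency,
      retroToAnteroRatio = retroToAnteroRatio, anteroSpeed = anteroSpeed,
      retroSpeed = retroSpeed, flagellumLength = flagellumLength,
      detectionThreshold = detectionThreshold, nTrials = nTrials,
      seed = as.integer(seed))
}

# One photogate trial. Bookkeeping in continuous time:
# - nIn fluorescent trains enter through the gate (inter-entry ~ Exp(fA)),
#   transit at a truncated-normal anterograde speed, and dump their particles
#   into the tip pool on arrival.
# - The pool holds tipPool train equivalents of material including the
#   arriving train, matching the measured tip brightness of ~3 trains: it
#   starts as (tipPool - 1) x P dark particles. Subsequent (photobleached)
#   anterograde arrivals add P dark particles each at rate fA, and retrograde
#   departures remove round(P / ratio) uniformly chosen particles at rate
#   fA * ratio, so the pool size is stationary. darkArrivals = FALSE switches
#   the replenishment off (the no-mixing limit).
# - Each GFP carries an Exp(bleachRate * dutyCycle) illuminated-exposure
#   budget covering transit plus tip dwell; a departing train is detectable
#   if it carries >= threshold unbleached GFPs at departure.
# - The trial ends when no unbleached GFP remains in the pool.
# Returns c(detectable count, observation window, fluorophores departed
# unbleached, fluorophores bleached).
.photogateTrial <- function(cfg, darkArrivals = TRUE) {
  P <- round(cfg@particlesPerTrain)
  R <- max(1L, round(P / cfg@retroToAnteroRatio))
  nG <- round(cfg@gfpsPerTrain)
  effRate <- cfg@bleachRate * cfg@dutyCycle
  fA <- cfg@anteroFrequency
  fR <- fA * cfg@retroToAnteroRatio

  entry <- cumsum(rexp(cfg@nFluorescentIn, fA)) - rexp(1, fA)  # first ~ t=0
  entry <- entry - min(entry)
  speeds <- rtruncnorm0(cfg@nFluorescentIn, cfg@anteroSpeed, 0.4)
  tipArrival <- sort(entry + cfg@flagellumLength / speeds)

  # fluorophores: tip arrival time, bleach-at time (absolute), departed flag
  fArr <- rep(tipArrival, each = nG)
  # exposure budget spans transit + dwell; transit exposure already elapsed
  fBleachAt <- rep(entry[order(entry + cfg@flagellumLength / speeds)],
                   each = nG) +
    if (effRate > 0) rexp(length(fArr), effRate) else Inf
  nF <- length(fArr)

  if (cfg@tipPoolTrainEquivalents < 1) stop("tip pool smaller than one train")
  poolDark <- round((cfg@tipPoolTrainEquivalents - 1) * P)
  # pool state: dark count + index set of fluorescent particles present
  flInPool <- integer(0)      # indices into fluorophore vectors
  t <- tipArrival[1]
  nextArrIdx <- 1L
  nextDarkArr <- if (darkArrivals) t + rexp(1, fA) else Inf
  nextDep <- t + rexp(1, fR)
  detect <- 0L
  departedUnbleached <- 0L
  lastEvent <- t
  guard <- 0L

  repeat {
    guard <- guard + 1L
    if (guard > 100000L) stop("photogate trial failed to terminate")
    # next event among: fluorescent arrival, dark arrival, departure
    tArr <- if (nextArrIdx <= length(tipArrival)) tipArrival[nextArrIdx] else Inf
    tNext <- min(tArr, nextDarkArr, nextDep)
    t <- tNext
    if (tArr <= nextDarkArr && tArr <= nextDep) {
      # fluorescent train reaches the tip: its particles join the pool
      idx <- which(fArr == tArr)
      flInPool <- c(flInPool, idx)
      poolDark <- poolDark + (P - length(idx))
      nextArrIdx <- nextArrIdx + 1L
    } else if (nextDarkArr <= nextDep) {
      poolDark <- poolDark + P
      nextDarkArr <- if (darkArrivals) t + rexp(1, fA) else Inf
      } else {
      # retrograde departure: draw R particles without replacement
      poolTotal <- poolDark + length(flInPool)
      take <- min(R, poolTotal)
      nFl <- length(flInPool)
      # number of fluorescent particles in the draw ~ hypergeometric
      kF <- if (nFl > 0) stats::rhyper(1, nFl, poolTotal - nFl, take) else 0L
      if (kF > 0) {
        pick <- sample(nFl, kF)
        chosen <- flInPool[pick]
        flInPool <- flInPool[-pick]
        unbleached <- sum(fBleachAt[chosen] > t)
        departedUnbleached <- departedUnbleached + unbleached
        if (unbleached >= cfg@detectionThreshold) {
          detect <- detect + 1L
          lastEvent <- t
        }
      }
      poolDark <- poolDark - (take - kF)
      nextDep <- t + rexp(1, fR)
    }
    # stop when no live fluorophore can ever depart again
    live <- flInPool[fBleachAt[flInPool] > t]
    if (nextArrIdx > length(tipArrival) && length(live) < cfg@detectionThreshold)
      break
  }
  bleached <- nF - departedUnbleached -
    sum(fBleachAt[flInPool] > t)          # still-live stragglers in pool
  window <- max(lastEvent - tipArrival[1], 1 / (fA * cfg@retroToAnteroRatio))
  c(detect = detect, window = window,
    departedUnbleached = departedUnbleached, bleached = bleached,
    remainingLive = sum(fBleachAt[flInPool] > t), injected = nF)
}

#' Monte Carlo of photogated fluorophore counting
#'
#' Simulates the fluorophore bookkeeping of the photogate experiment: a
#' limited number of GFPs per anterograde train, photobleaching during
#' illuminated transit and tip dwell, mixing into a shared dark tip pool,
#' random repackaging into retrograde trains, and counting of retrograde
#' trains that leave the tip with at least `detectionThreshold` unbleached
#' GFPs.
#'
#' @param config a [PhotoGateConfig-class]
#' @param darkArrivals replenish the pool with photobleached anterograde
#'   arrivals (TRUE, the experiment's geometry); FALSE gives the no-mixing
#'   limit
#' @param seed optional integer seed; defaults to the config seed
#' @return a [PhotoGateResult-class]
#' @examples
#' res <- simulatePhotogate(photoGateConfig(nTrials = 50, seed = 11))
#' res
#' @export
simulatePhotogate <- function(config, darkArrivals = TRUE, seed = config@seed) {
  stopifnot(is(config, "PhotoGateConfig"))
  if (config@tipPoolTrainEquivalents < 1)
    stop("tip pool smaller than one train")
  if (!is.null(seed)) set.seed(seed)
  trials <- t(vapply(seq_len(config@nTrials),
                     function(i) .photogateTrial(config, darkArrivals),
                     numeric(6)))
  counts <- trials[, "detect"]
  # conservation check in every trial: departed + bleached + live = injected
  stopifnot(all(abs(trials[, "departedUnbleached"] + trials[, "bleached"] +
                      trials[, "remainingLive"] - trials[, "injected"]) < 1e-9))
  new("PhotoGateResult", counts = as.numeric(counts),
      nIn = config@nFluorescentIn,
      meanCount = mean(counts),
      semCount = sd(counts) / sqrt(length(counts)),
      returnFrequency = mean(counts / trials[, "window"]),
      config = config)
}

#' Summarize photogate results across fluorescent-train inputs
#'
#' @param results list of [PhotoGateResult-class] (one per `nFluorescentIn`)
#' @return data.frame with `n_in`, `mean_count`, `sem`, `return_frequency_per_s`
#' @export
summarizeCounts <- function(results) {
  if (!length(results)) stop("no results supplied")
  rows <- lapply(results, function(r) {
    stopifnot(is(r, "PhotoGateResult"))
    data.frame(n_in = r@nIn, mean_count = r@meanCount, sem = r@semCount,
               return_frequency_per_s = r@returnFrequency)
  })
  out <- do.call(rbind, rows)
  out[order(out$n_in), , drop = FALSE]
}

#' Power-law fit of detectable counts versus fluorescent inputs
#'
#' Least-squares fit of `y = a x^n` on log-transformed values. Sub-mixing of
#' trains at the tip shows up as `n < 1`.
#'
#' @param nIn numbers of fluorescent anterograde trains (all > 0)
#' @param meanCounts mean detectable retrograde counts (all > 0)
#' @return list of class `powerLawFit`: `a`, `n`, `seA`, `seN`
#' @examples
#' fitPowerLaw(1:3, c(2.4, 3.6, 4.2))$n   # ~ 0.51
#' @export
fitPowerLaw <- function(nIn, meanCounts) {
  if (length(nIn) < 2) stop("need at least 2 points")
  if (any(nIn <= 0) || any(meanCounts <= 0))
    stop("all inputs and counts must be positive")
  fit <- lm(log(meanCounts) ~ log(nIn))
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are legal input
  out <- list(a = exp(unname(coef(fit)[1])), n = unname(coef(fit)[2]),
              seA = exp(coef(fit)[1]) * sm[1, 2], seN = sm[2, 2])
  class(out) <- "powerLawFit"
  out
}

#' @export
print.powerLawFit <- function(x, ...) {
  cat(sprintf("powerLawFit: y = %.2f x^%.2f (se n = %.2f)\n", x$a, x$n, x$seN))
  invisible(x)
}
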