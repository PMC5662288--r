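# Forward model of 1D diffusion on [0, L] with no-flux ends, from a
# step-bleached initial condition c0(x) = 1 - depth * 1[a, b]. Spectral
# (cosine-series) solution; the n = 0 mode conserves total signal exactly.

#' Analytic post-bleach concentration profile
#'
#' @param x positions, um
#' @param t time since bleach, s (scalar or vector)
#' @param D diffusion coefficient, um^2/s
#' @param L domain length, um
#' @param window bleach window c(a, b), um
#' @param depth bleach depth in (0, 1]
#' @param nTerms series terms
#' @return matrix length(x) x length(t) of concentrations (pre-bleach = 1)
#' @export
frapProfileModel <- function(x, t, D, L, window, depth = 1, nTerms = 200) {
  a <- window[1]; b <- window[2]
  n <- seq_len(nTerms)
  Bn <- (2 / (n * pi)) * (sin(n * pi * b / L) - sin(n * pi * a / L))
  out <- matrix(0, length(x), length(t))
  cosx <- cos(outer(x / L, n * pi))             # length(x) x nTerms
  for (j in seq_along(t)) {
    decay <- exp(-D * (n * pi / L)^2 * t[j])
    out[, j] <- 1 - depth * (b - a) / L - depth * as.vector(cosx %*% (Bn * decay))
  }
  out
}

#' Analytic windowed FRAP recovery curve
#'
#' Total signal inside the bleach window versus time since bleach, normalized
#' so the pre-bleach window signal is 1.
#'
#' @inheritParams frapProfileModel
#' @return numeric vector along `t`
#' @export
frapRecoveryModel <- function(t, D, L, window, depth = 1, nTerms = 200) {
  a <- window[1]; b <- window[2]; w <- b - a
  n <- seq_len(nTerms)
  Sn <- (sin(n * pi * b / L) - sin(n * pi * a / L))
  coefs <- depth * (2 * L / (n * pi)^2) * Sn^2
  sapply(t, function(tt) {
    (w - depth * w^2 / L - sum(coefs * exp(-D * (n * pi / L)^2 * tt))) / w
  })
}

#' Simulate a FRAP series
#'
#' Forward-simulates the concentration profile of a FRAP experiment on a
#' finite flagellum with no-flux ends: uniform pre-bleach signal, a step
#' bleach of `depth` inside `window` at `bleachTime`, then diffusive
#' recovery. Optional shot noise draws each stored profile value from a
#' Poisson distribution with `photonScale` expected photons per unit
#' concentration.
#'
#' @param D diffusion coefficient, um^2/s (>= 0)
#' @param L flagellum length, um
#' @param window bleach window c(a, b), um, inside the domain
#' @param duration post-bleach observation, s
#' @param frameRate Hz
#' @param bleachTime s of pre-bleach baseline recorded before the bleach
#' @param depth bleach depth in (0, 1]
#' @param dx spatial grid step, um
#' @param noise `"none"` or `"shot"`
#' @param photonScale photons per unit concentration per grid point (shot
#'   noise only)
#' @param seed optional integer seed
#' @return a [FrapSeries-class]
#' @examples
#' fs <- makeFrapSeries(D = 1.8, L = 12, window = c(3.5, 8.5), duration = 20)
#' @export
makeFrapSeries <- function(D, L = 12, window = c(3.5, 8.5), duration = 20,
                           frameRate = 10, bleachTime = 1, depth = 1,
                           dx = 0.05, noise = c("none", "shot"),
                           photonScale = 200, seed = NULL) {
  noise <- match.arg(noise)
  if (D < 0) stop("D must be >= 0")
  if (window[1] < 0 || window[2] > L || window[1] >= window[2])
    stop("bleach window must lie inside [0, L]")
  if (!is.null(seed)) set.seed(seed)

  x <- seq(dx / 2, L - dx / 2, by = dx)
  times <- seq(0, bleachTime + duration, by = 1 / frameRate)
  pre <- times < bleachTime
  prof <- matrix(1, length(x), length(times))
  post <- which(!pre)
  inWin <- x >= window[1] & x <= window[2]
  if (D == 0) {
    prof[inWin, post] <- 1 - depth
  } else {
    tPost <- times[post] - bleachTime
    # the bleach instant is the exact step profile; later frames the series
    atBleach <- tPost <= 0
    if (any(atBleach))
      prof[inWin, post[atBleach]] <- 1 - depth
    if (any(!atBleach))
      prof[, post[!atBleach]] <- frapProfileModel(x, tPost[!atBleach], D, L,
                                                  window, depth)
  }
  if (noise == "shot")
    prof <- matrix(rpois(length(prof), pmax(prof, 0) * photonScale),
                   nrow(prof)) / photonScale

  new("FrapSeries", positions = x, times = times, profile = prof,
      bleachWindow = window, bleachTime = bleachTime, bleachDepth = depth,
      noise = noise)
}

#' Windowed recovery curve of a FRAP series
#'
#' @param fs a [FrapSeries-class]
#' @return data.frame with `time_s` (absolute) and `intensity` (window total
#'   normalized to pre-bleach = 1)
#' @export
frapWindowRecovery <- function(fs) {
  stopifnot(is(fs, "FrapSeries"))
  inWin <- fs@positions >= fs@bleachWindow[1] &
    fs@positions <= fs@bleachWindow[2]
  w <- colMeans(fs@profile[inWin, , drop = FALSE])
  pre <- fs@times < fs@bleachTime
  base <- if (any(pre)) mean(w[pre]) else 1
  data.frame(time_s = fs@times, intensity = w / base)
}
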