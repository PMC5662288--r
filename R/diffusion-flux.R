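#' Background intensity profile of a kymograph after trace removal
#'
#' Masks out transport traces (and gate-on columns), averages the remaining
#' pixels over the time axis per position, and normalizes position to the unit interval
#' (base = 0, tip = 1) and intensity to its mean. Positions whose pixels are
#' all masked are linearly interpolated and flagged.
#'
#' @param kymo a [Kymograph-class]
#' @param mask logical matrix of the kymograph's dimensions, TRUE = pixel
#'   belongs to a transport trace and is excluded; NULL for no mask
#' @param normalize normalize intensity by its mean profile value
#' @return list of class `intensityProfile`: `position` (normalized),
#'   `position_um`, `intensity`, `interpolated` (logical per position),
#'   `nCells` (= 1)
#' @export
backgroundProfile <- function(kymo, mask = NULL, normalize = TRUE) {
  stopifnot(is(kymo, "Kymograph"))
  img <- kymo@image
  if (length(kymo@maskedColumns)) img[, kymo@maskedColumns] <- NA
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(img)))
      stop("mask dimensions must match the kymograph")
    img[mask] <- NA
  }
  if (all(is.na(img))) stop("all pixels are masked")
  prof <- rowMeans(img, na.rm = TRUE)
  interpolated <- !is.finite(prof)
  if (any(interpolated)) {
    ok <- which(!interpolated)
    prof[interpolated] <- approx(ok, prof[ok], xout = which(interpolated),
                                 rule = 2)$y
  }
  posUm <- (seq_along(prof) - 0.5) * kymo@positionScale / 1000
  out <- list(position = (seq_along(prof) - 0.5) / length(prof),
              position_um = posUm,
              intensity = if (normalize) prof / mean(prof) else prof,
              interpolated = interpolated, nCells = 1L)
  class(out) <- "intensityProfile"
  out
}

#' Average intensity profiles across cells
#'
#' Interpolates each per-cell profile onto a common normalized-position grid
#' and averages, as done when pooling flagella of different lengths.
#'
#' @param profiles list of `intensityProfile` objects
#' @param nGrid grid points on the unit interval
#' @return an `intensityProfile` with `nCells = length(profiles)`
#' @export
averageProfiles <- function(profiles, nGrid = 50) {
  stopifnot(length(profiles) >= 1)
  grid <- (seq_len(nGrid) - 0.5) / nGrid
  mat <- vapply(profiles, function(p)
    approx(p$position, p$intensity, xout = grid, rule = 2)$y, numeric(nGrid))
  out <- list(position = grid, position_um = NULL,
              intensity = rowMeans(mat),
              interpolated = rep(FALSE, nGrid),
              nCells = length(profiles))
  class(out) <- "intensityProfile"
  out
}

#' Fit a 1D diffusion model to a FRAP recovery curve
#'
#' Nonlinear least-squares fit of the finite-domain diffusion recovery (the
#' cosine-series solution with no-flux ends, see [frapRecoveryModel]) to the
#' windowed post-bleach intensity, with free diffusion coefficient, bleach
#' depth and baseline. The 95% CI for D comes from a residual bootstrap.
#'
#' @param times absolute frame times, s
#' @param intensity windowed intensity, normalized so pre-bleach = 1
#' @param L domain (flagellum) length, um
#' @param window bleach window c(a, b), um
#' @param bleachTime time of the bleach, s
#' @param nBoot residual-bootstrap replicates for the CI
#' @param seed optional integer seed for the bootstrap
#' @return list of class `frapFit`: `D` (um^2/s), `ciD`, `depth`,
#'   `baseline`, `residualNorm`, `model` (metadata: boundary conditions and
#'   free parameters)
#' @examples
#' fs <- makeFrapSeries(D = 1.8, seed = 12)
#' rec <- frapWindowRecovery(fs)
#' fitFrap1d(rec$time_s, rec$intensity, L = 12, window = c(3.5, 8.5),
#'           bleachTime = 1, nBoot = 50)$D
#' @export
fitFrap1d <- function(times, intensity, L, window, bleachTime = 0,
                      nBoot = 200, seed = NULL) {
  post <- times >= bleachTime
  if (sum(post) < 10) stop("need at least 10 post-bleach time points")
  t <- times[post] - bleachTime
  y <- intensity[post]
  if (!is.null(seed)) set.seed(seed)

  model <- function(p, tt) {
    D <- exp(p[1]); depth <- 1 / (1 + exp(-p[2])); base <- p[3]
    base * frapRecoveryModel(tt, D, L, window, depth)
  }
  start <- c(logD = log(1), qDepth = 2, base = 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(start, fn = function(p) y - model(p, t),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  noRecovery <- FALSE
  if (is.null(fit)) {
    warning("FRAP fit failed; D pinned at 0")
    out <- list(D = 0, ciD = c(0, 0), depth = NA, baseline = NA,
                residualNorm = NA,
                model = .frapModelMeta())
    class(out) <- "frapFit"
    return(out)
  }
  p <- fit$par
  D <- exp(p[1])
  # flat signal: no measurable recovery
  fitted <- model(p, t)
  if (diff(range(fitted)) < 1e-6 || D < 1e-8) {
    warning("no recovery signal; D pinned at 0")
    D <- 0
    noRecovery <- TRUE
  }
  res <- y - fitted

  ciD <- c(NA_real_, NA_real_)
  if (!noRecovery && nBoot > 0) {
    bD <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      yb <- fitted + sample(res, length(res), replace = TRUE)
      fb <- tryCatch(
        minpack.lm::nls.lm(p, fn = function(q) yb - model(q, t),
                           control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      bD[b] <- if (is.null(fb)) NA else exp(fb$par[1])
    }
    bD <- bD[is.finite(bD)]
    if (length(bD) >= 20) {
      q <- quantile(bD, c(0.025, 0.975), names = FALSE)
      ciD <- pmax(c(2 * D - q[2], 2 * D - q[1]), 0)
    }
  }
  out <- list(D = D, ciD = ciD, depth = 1 / (1 + exp(-p[2])),
              baseline = p[3], residualNorm = sqrt(sum(res^2)),
              model = .frapModelMeta())
  class(out) <- "frapFit"
  out
}

.frapModelMeta <- function() {
  list(equation = "1D diffusion, finite domain, cosine series",
       boundaries = "no-flux at both ends",
       freeParameters = c("D", "bleach depth", "baseline"))
}

#' @export
print.frapFit <- function(x, ...) {
  cat(sprintf("frapFit: D = %.3f um^2/s [%.3f, %.3f] (depth %.2f, baseline %.3f)\n",
              x$D, x$ciD[1], x$ciD[2], x$depth, x$baseline))
  invisible(x)
}

#' Fick's-law flux balance of diffusing motor along the flagellum
#'
#' Efflux of the diffusing species toward the base is `|dI/dx| * D` (Fick's
#' law applied to the background intensity gradient); influx is the mean
#' background-subtracted train intensity times the train frequency. Both are
#' in identical arbitrary intensity units per second, so their ratio tests
#' whether diffusive return balances delivery by anterograde trains. With
#' per-cell vectors a Welch two-sample comparison is reported.
#'
#' @param profile an `intensityProfile` (see [backgroundProfile]); must span
#'   at least half the flagellum. Absolute positions are taken from
#'   `position_um` or from `position * L`
#' @param D diffusion coefficient, um^2/s (> 0)
#' @param trainIntensity background-subtracted anterograde train intensity
#'   (scalar, or per-cell vector)
#' @param trainFrequency trains/s
#' @param L flagellum length, um (needed when the profile has no absolute
#'   positions)
#' @param effluxPerCell optional per-cell efflux values for the comparison
#' @return list of class `fluxEstimate`: `efflux`, `influx`, `ratio`
#'   (influx/efflux), `slope` (per um), `slopeSe`, `slopeSignificant`,
#'   `comparison` (Welch test or NULL)
#' @export
estimateFluxBalance <- function(profile, D, trainIntensity, trainFrequency,
                                L = NULL, effluxPerCell = NULL) {
  if (D <= 0) stop("D must be > 0")
  x <- profile$position_um
  if (is.null(x)) {
    if (is.null(L)) stop("supply L when the profile has normalized positions only")
    x <- profile$position * L
  }
  span <- diff(range(x))
  if (!is.null(L) && span < L / 2)
    stop("profile must span at least half the flagellum")
  fit <- lm(profile$intensity ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are legal input
  slope <- unname(coef(fit)[2]); slopeSe <- sm[2, 2]
  significant <- abs(slope) > 2 * slopeSe
  if (!significant)
    warning("background slope not significant: efflux CI includes 0")
  efflux <- abs(slope) * D
  influx <- mean(trainIntensity) * trainFrequency
  comparison <- NULL
  if (!is.null(effluxPerCell) && length(trainIntensity) > 1) {
    influxPerCell <- trainIntensity * trainFrequency
    comparison <- t.test(influxPerCell, effluxPerCell)
  }
  out <- list(efflux = efflux, influx = influx, ratio = influx / efflux,
              slope = slope, slopeSe = slopeSe,
              slopeSignificant = significant, comparison = comparison)
  class(out) <- "fluxEstimate"
  out
}

#' @export
print.fluxEstimate <- function(x, ...) {
  cat(sprintf("fluxEstimate: influx %.3g, efflux %.3g (a.u./s), ratio %.2f%s\n",
              x$influx, x$efflux, x$ratio,
              if (!x$slopeSignificant) " [slope n.s.]" else ""))
  if (!is.null(x$comparison))
    cat(sprintf("  Welch t-test p = %.3f\n", x$comparison$p.value))
  invisible(x)
}
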