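#' Estimate transport velocity from a trajectory phase
#'
#' Least-squares slope of axial position versus time over the samples in the
#' requested phase. Sign convention: anterograde (tipward) motion is
#' positive.
#'
#' @param traj a [Trajectory-class]
#' @param phase phase to use (`"anterograde"`, `"retrograde"`, ...); `NULL`
#'   uses all samples
#' @return list with `velocity` (um/s), `se`, `n`
#' @examples
#' tr <- makeKapTrajectory(trafficConfig(seed = 7), tipPause = 1, D = 1.68)
#' estimateVelocity(tr, "anterograde")$velocity
#' @export
estimateVelocity <- function(traj, phase = "anterograde") {
  stopifnot(is(traj, "Trajectory"))
  keep <- if (is.null(phase)) rep(TRUE, length(traj@times)) else traj@phase == phase
  if (sum(keep) < 5)
    stop("need at least 5 samples in phase '", phase, "'")
  fit <- lm(traj@axial[keep] ~ traj@times[keep])
  list(velocity = unname(coef(fit)[2]),
       se = summary(fit)$coefficients[2, 2],
       n = sum(keep))
}

#' Lateral fluctuation of a 2D path about a polynomial centerline
#'
#' The centerline models the (nearly straight) flagellar axis: the path is
#' rotated onto its principal axis and the transverse coordinate is fitted
#' as a polynomial of the axial coordinate. `sigmaLateral` is the standard
#' deviation of the perpendicular residuals (raw residuals divided by
#' `sqrt(1 + slope^2)` of the local centerline tangent), with a
#' degrees-of-freedom correction `n - (degree + 1)`. The principal-axis
#' alignment makes the result invariant under rigid rotations and
#' translations of the trajectory.
#'
#' @param traj a [Trajectory-class] (axial um, lateral nm), or a 2-column
#'   matrix of positions in nm
#' @param degree centerline polynomial degree (default 3)
#' @return list of class `lateralResult`: `sigmaLateral` (nm), `degree`,
#'   `residuals` (nm, perpendicular components)
#' @export
lateralFluctuation <- function(traj, degree = 3) {
  if (is(traj, "Trajectory")) {
    pts <- cbind(traj@axial * 1000, traj@lateral)  # nm
  } else {
    pts <- as.matrix(traj)
  }
  n <- nrow(pts)
  if (n < degree + 5) stop("need at least degree + 5 samples")
  pc <- sweep(pts, 2, colMeans(pts))
  if (max(abs(pc)) == 0) stop("degenerate path: all positions identical")
  ev <- eigen(var(pc), symmetric = TRUE)
  rot <- pc %*% ev$vectors                 # column 1 = major (axial) axis
  u <- rot[, 1]; v <- rot[, 2]
  if (length(unique(round(u, 6))) <= degree)
    stop("degenerate path: no extent along the major axis")
  fit <- lm(v ~ stats::poly(u, degree, raw = TRUE))
  res <- stats::residuals(fit)
  beta <- coef(fit)[-1]
  slope <- vapply(u, function(ui)
    sum(beta * seq_along(beta) * ui^(seq_along(beta) - 1)), 0)
  perp <- res / sqrt(1 + slope^2)
  sigma <- sqrt(sum(perp^2) / (n - (degree + 1)))
  out <- list(sigmaLateral = sigma, degree = degree, residuals = perp)
  class(out) <- "lateralResult"
  out
}

#' @export
print.lateralResult <- function(x, ...) {
  cat(sprintf("lateralResult: sigma = %.1f nm (degree-%d centerline, n = %d)\n",
              x$sigmaLateral, x$degree, length(x$residuals)))
  invisible(x)
}

#' Time-averaged MSD and diffusion coefficient of one trace
#'
#' Computes the time-averaged mean squared displacement of the axial
#' coordinate per lag and fits `MSD = 2 D tau + offset` by unweighted least
#' squares over lags up to `maxLagFraction` of the trace length. With
#' localization noise of sd sigma the offset estimates `2 sigma^2`. A trace
#' whose MSD grows clearly superlinearly (log-log slope > 1.5, e.g. directed
#' motion) is flagged `nonDiffusive`.
#'
#' @param traj a [Trajectory-class] or numeric position vector (um)
#' @param maxLagFraction fraction of the trace length fitted (default 1/4)
#' @param phase phase to use when `traj` is a Trajectory (`"diffusing"`);
#'   `NULL` uses all samples
#' @return list of class `msdResult`: `lags` (s), `msd` (um^2), `D`
#'   (um^2/s), `offset` (um^2), `fitRange` (lag indices), `nonDiffusive`
#' @examples
#' tr <- makeBrownianTrajectory(1.68, duration = 5, seed = 8)
#' msdFit(tr)$D
#' @export
msdFit <- function(traj, maxLagFraction = 0.25, phase = "diffusing") {
  if (is(traj, "Trajectory")) {
    keep <- if (is.null(phase)) rep(TRUE, length(traj@times)) else traj@phase == phase
    x <- traj@axial[keep]
    dt <- 1 / traj@frameRate
  } else {
    x <- as.numeric(traj)
    dt <- attr(traj, "dt")
    if (is.null(dt)) dt <- 1
  }
  n <- length(x)
  if (n < 20) stop("trace too short: need >= 20 samples")
  maxLag <- max(3L, floor(n * maxLagFraction))
  lags <- seq_len(maxLag)
  msd <- vapply(lags, function(k) mean((x[(k + 1):n] - x[1:(n - k)])^2), 0)
  tau <- lags * dt
  fit <- lm(msd ~ tau)
  D <- unname(coef(fit)[2]) / 2
  offset <- unname(coef(fit)[1])
  logFit <- lm(log(msd) ~ log(tau))
  nonDiffusive <- unname(coef(logFit)[2]) > 1.5
  out <- list(lags = tau, msd = msd, D = D, offset = offset,
              fitRange = lags, nonDiffusive = nonDiffusive,
              seD = summary(fit)$coefficients[2, 2] / 2)
  class(out) <- "msdResult"
  out
}

#' @export
print.msdResult <- function(x, ...) {
  cat(sprintf("msdResult: D = %.3f um^2/s (offset %.4f um^2, %d lags)%s\n",
              x$D, x$offset, length(x$lags),
              if (x$nonDiffusive) " [non-diffusive]" else ""))
  invisible(x)
}

#' Average diffusion coefficient over many traces
#'
#' Per-trace [msdFit] estimates averaged across traces, with the standard
#' error of the mean, as done for pooled single-particle data.
#'
#' @param trajs list of [Trajectory-class] objects (or position vectors)
#' @param ... passed to [msdFit]
#' @return list: `D` (mean, um^2/s), `sem`, `perTrace` (vector), `n`
#' @export
msdAcrossTraces <- function(trajs, ...) {
  Ds <- vapply(trajs, function(tr) msdFit(tr, ...)$D, 0)
  list(D = mean(Ds), sem = sd(Ds) / sqrt(length(Ds)), perTrace = Ds,
       n = length(Ds))
}
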