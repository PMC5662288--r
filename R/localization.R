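#' Localize one spot by least-squares 2D Gaussian fitting
#'
#' Fits `A * gx(x0, sx) * gy(y0, sy) + b` (pixel-integrated Gaussians) to a
#' single frame by Levenberg-Marquardt least squares. Never fails silently: a
#' fit that does not converge, runs to the border or collapses returns
#' `converged = FALSE`. The spot intensity is the volume of the fitted peak
#' and the precision estimate follows the standard shot-noise localization
#' formula (PSF width and pixelation over photons, plus the background term).
#' A doublet of barely-resolved spots inflates the fitted width along the
#' separation axis; fits whose width anisotropy `max(sx, sy) / min(sx, sy)`
#' exceeds `asymmetryTol`, or whose relative residual exceeds
#' `ambiguityTol`, are flagged `ambiguous`. (A doublet much closer than one
#' PSF sd is indistinguishable from a single emitter and cannot be flagged.)
#'
#' @param frame numeric matrix (photons), rows = x pixels, cols = y pixels
#' @param guess initial center, pixels `c(x, y)` (defaults to the brightest
#'   pixel)
#' @param pixelSize nm per pixel
#' @param ambiguityTol relative residual (residual sd / fitted amplitude)
#'   above which the fit is flagged ambiguous
#' @param asymmetryTol fitted width anisotropy above which the fit is
#'   flagged ambiguous (calibrated on a synthetic doublet sweep: a doublet
#'   at one PSF sd separation fits as a single Gaussian elongated by
#'   sqrt(1 + 1/4) ~ 1.12)
#' @return a list of class `spotFit`: `x`, `y` (nm), `widths` (nm, c(sx, sy)),
#'   `amplitude`, `offset`, `volume` (photons), `precision` (nm),
#'   `converged`, `ambiguous`, `residualSd`
#' @examples
#' st <- makeSpotStack(cbind(795, 795), 150, 130, 5, seed = 6)
#' fitSpot2d(st$stack[, , 1])
#' @export
fitSpot2d <- function(frame, guess = NULL, pixelSize = 106,
                      ambiguityTol = 0.035, asymmetryTol = 1.10) {
  stopifnot(is.matrix(frame))
  nx <- nrow(frame); ny <- ncol(frame)
  bad <- function() list(x = NA_real_, y = NA_real_, widths = c(NA_real_, NA_real_),
                         amplitude = NA_real_, offset = NA_real_,
                         volume = NA_real_, precision = NA_real_,
                         converged = FALSE, ambiguous = NA,
                         residualSd = NA_real_)
  if (max(frame) - min(frame) <= 0) { out <- bad(); class(out) <- "spotFit"; return(out) }

  if (is.null(guess)) {
    ij <- which(frame == max(frame), arr.ind = TRUE)[1, ]
    guess <- c(ij[1], ij[2])
  }
  if (guess[1] < 1 || guess[1] > nx || guess[2] < 1 || guess[2] > ny)
    stop("initial guess outside the image")

  b0 <- stats::median(frame)
  a0 <- max(sum(frame) - b0 * length(frame), max(frame) - b0, 1)  # volume scale
  s0 <- 1.2                 # pixels; generic PSF-scale start
  par0 <- c(x0 = guess[1] - 0.5, y0 = guess[2] - 0.5,
            lsx = log(s0), lsy = log(s0), A = a0, b = b0)

  model <- function(p) {
    sx <- exp(p[3]); sy <- exp(p[4])
    gx <- diff(pnorm(0:nx, p[1], sx))
    gy <- diff(pnorm(0:ny, p[2], sy))
    # pixel-integrated profile; A is the peak volume in photons
    p[5] * outer(gx, gy) + p[6]
  }
  resid <- function(p) as.vector(frame - model(p))

  fit <- tryCatch(
    minpack.lm::nls.lm(par0, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9)) { out <- bad(); class(out) <- "spotFit"; return(out) }

  p <- fit$par
  sxPx <- exp(p[3]); syPx <- exp(p[4])
  conv <- p[1] > 0 && p[1] < nx && p[2] > 0 && p[2] < ny &&
    sxPx < max(nx, ny) && syPx < max(nx, ny) && p[5] > 0
  res <- resid(p)
  residSd <- sd(res)
  # peak amplitude in photons/pixel for the relative-residual test
  peak <- p[5] * (diff(pnorm(c(-0.5, 0.5), 0, sxPx)) *
                    diff(pnorm(c(-0.5, 0.5), 0, syPx)))
  anisotropy <- max(sxPx, syPx) / min(sxPx, syPx)
  ambiguous <- (is.finite(peak) && peak > 0 &&
                  (residSd / peak) > ambiguityTol) ||
    (is.finite(anisotropy) && anisotropy > asymmetryTol)

  N <- max(p[5], 1)
  sMean <- mean(c(sxPx, syPx)) * pixelSize
  bVar <- max(p[6], 0)
  precision <- sqrt((sMean^2 + pixelSize^2 / 12) / N +
                      8 * pi * sMean^4 * bVar / (pixelSize^2 * N^2))

  out <- list(x = p[1] * pixelSize, y = p[2] * pixelSize,
              widths = c(sxPx, syPx) * pixelSize,
              amplitude = peak, offset = p[6],
              volume = p[5], precision = precision,
              converged = conv, ambiguous = ambiguous, residualSd = residSd)
  class(out) <- "spotFit"
  out
}

#' @export
print.spotFit <- function(x, ...) {
  if (!x$converged) { cat("spotFit: not converged\n"); return(invisible(x)) }
  cat(sprintf("spotFit: (%.1f, %.1f) nm, widths (%.1f, %.1f) nm, volume %.0f photons, precision %.1f nm%s\n",
              x$x, x$y, x$widths[1], x$widths[2], x$volume, x$precision,
              if (isTRUE(x$ambiguous)) " [ambiguous]" else ""))
  invisible(x)
}

#' Localize every frame of a spot stack
#'
#' @param stack boxSize x boxSize x n array
#' @param pixelSize nm per pixel
#' @param ... passed to [fitSpot2d]
#' @return data.frame of per-frame fits (frame, x, y, widths, volume,
#'   precision, converged, ambiguous)
#' @export
fitSpotStack <- function(stack, pixelSize = 106, ...) {
  n <- dim(stack)[3]
  rows <- lapply(seq_len(n), function(i) {
    f <- fitSpot2d(stack[, , i], pixelSize = pixelSize, ...)
    data.frame(frame = i, x = f$x, y = f$y, sx = f$widths[1], sy = f$widths[2],
               volume = f$volume, precision = f$precision,
               converged = f$converged, ambiguous = isTRUE(f$ambiguous))
  })
  do.call(rbind, rows)
}

#' Link per-frame spot fits into trajectories
#'
#' Nearest-neighbour frame-to-frame linking (optimal assignment for small
#' frames, greedy otherwise) with a one-frame gap tolerance; candidate links
#' longer than `maxJump` are rejected and trajectories shorter than
#' `minLength` frames are discarded.
#'
#' @param spots data.frame with columns `frame`, `x`, `y` (nm)
#' @param maxJump maximum frame-to-frame displacement, nm
#' @param minLength minimum trajectory length, frames
#' @param frameRate Hz, used to time-stamp the output trajectories
#' @return list of data.frames (frame, time_s, x, y), one per trajectory
#' @export
linkSpots <- function(spots, maxJump, minLength = 5, frameRate = 10) {
  if (is.null(spots) || nrow(spots) == 0) return(list())
  stopifnot(all(c("frame", "x", "y") %in% names(spots)))
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))

  # active tracks: list of (rows, lastFrame, lastXY)
  tracks <- list()
  done <- list()
  for (f in frames) {
    cur <- spots[spots$frame == f, , drop = FALSE]
    nC <- nrow(cur)
    active <- which(vapply(tracks, function(tr) f - tr$lastFrame <= 2, TRUE))
    assigned <- rep(FALSE, nC)
    if (length(active) && nC) {
      last <- t(vapply(tracks[active], function(tr) tr$lastXY, numeric(2)))
      cost <- outer(seq_along(active), seq_len(nC),
                    Vectorize(function(i, j)
                      sqrt((last[i, 1] - cur$x[j])^2 + (last[i, 2] - cur$y[j])^2)))
      cost <- matrix(cost, length(active), nC)
      pairs <- .assignPairs(cost, maxJump)
      for (k in seq_len(nrow(pairs))) {
        ti <- active[pairs[k, 1]]; j <- pairs[k, 2]
        tracks[[ti]]$rows <- rbind(tracks[[ti]]$rows, cur[j, c("frame", "x", "y")])
        tracks[[ti]]$lastFrame <- f
        tracks[[ti]]$lastXY <- c(cur$x[j], cur$y[j])
        assigned[j] <- TRUE
      }
    }
    # retire tracks that missed 2 consecutive frames
    if (length(tracks)) {
      stale <- which(vapply(tracks, function(tr) f - tr$lastFrame >= 2, TRUE))
      if (length(stale)) {
        done <- c(done, tracks[stale])
        tracks <- tracks[-stale]
      }
    }
    for (j in which(!assigned))
      tracks[[length(tracks) + 1]] <- list(rows = cur[j, c("frame", "x", "y")],
                                           lastFrame = f,
                                           lastXY = c(cur$x[j], cur$y[j]))
  }
  done <- c(done, tracks)
  out <- lapply(done, function(tr) {
    df <- tr$rows
    df$time_s <- df$frame / frameRate
    rownames(df) <- NULL
    df[, c("frame", "time_s", "x", "y")]
  })
  out[vapply(out, nrow, 0L) >= minLength]
}

# Minimum-total-displacement assignment with links capped at maxJump:
# exhaustive over permutations for small frames (the tracked fields here are
# sparse), greedy nearest-pair otherwise. Among assignments with the maximum
# number of admissible links, the one with the smallest total displacement
# wins. Returns a 2-column matrix of (row, col) pairs.
.assignPairs <- function(cost, maxJump) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0 || nc == 0) return(matrix(0L, 0, 2))
  if (nr <= 6 && nc <= 6) {
    transposed <- nr > nc
    if (transposed) { cost <- t(cost); tmp <- nr; nr <- nc; nc <- tmp }
    best <- matrix(0L, 0, 2); bestN <- -1L; bestCost <- Inf
    for (cols in .injections(nr, nc)) {
      cc <- cost[cbind(seq_len(nr), cols)]
      ok <- cc <= maxJump
      n <- sum(ok); tot <- sum(cc[ok])
      if (n > bestN || (n == bestN && tot < bestCost)) {
        bestN <- n; bestCost <- tot
        best <- cbind(seq_len(nr)[ok], cols[ok])
      }
    }
    if (transposed && nrow(best)) best <- best[, 2:1, drop = FALSE]
    return(best)
  }
  pairs <- matrix(0L, 0, 2)
  usedR <- rep(FALSE, nr); usedC <- rep(FALSE, nc)
  repeat {
    cost[usedR, ] <- Inf; cost[, usedC] <- Inf
    m <- which.min(cost)
    if (!length(m) || !is.finite(cost[m]) || cost[m] > maxJump) break
    i <- (m - 1) %% nr + 1; j <- (m - 1) %/% nr + 1
    pairs <- rbind(pairs, c(i, j))
    usedR[i] <- TRUE; usedC[j] <- TRUE
    if (all(usedR) || all(usedC)) break
  }
  pairs
}

# All injective maps 1..k -> 1..n (k <= n), as a list of index vectors.
.injections <- function(k, n) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1]] <<- prefix; return() }
    for (j in remaining) rec(c(prefix, j), setdiff(remaining, j))
  }
  rec(integer(0), seq_len(n))
  out
}
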