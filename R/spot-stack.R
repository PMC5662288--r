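#' Simulate an image stack of diffraction-limited spots
#'
#' One frame per row of `truePositions`: an integrated 2D Gaussian spot
#' (photon budget spread over pixels by the pixel-integrated PSF) on a
#' constant background, with Poisson noise. Ground-truth positions are
#' stored alongside the stack.
#'
#' @param truePositions n x 2 matrix of spot centers, nm (x, y within the
#'   field of view)
#' @param photonsPerFrame expected photons collected from the spot per frame
#' @param psfSd PSF Gaussian sd, nm
#' @param background expected background photons per pixel (>= 0)
#' @param pixelSize nm per pixel
#' @param boxSize field of view, pixels per side
#' @param noise add Poisson noise (TRUE) or return the noiseless expectation
#' @param seed optional integer seed
#' @return a list with `stack` (boxSize x boxSize x n array, photons),
#'   `truth` (the input positions, nm), `pixelSize`, `psfSd`
#' @examples
#' st <- makeSpotStack(cbind(800, 800), 150, 130, 5, seed = 5)
#' dim(st$stack)
#' @export
makeSpotStack <- function(truePositions, photonsPerFrame, psfSd,
                          background = 0, pixelSize = 106, boxSize = 15,
                          noise = TRUE, seed = NULL) {
  truePositions <- rbind(truePositions)
  if (!.posScalar(photonsPerFrame)) stop("photonsPerFrame must be > 0")
  if (!.posScalar(psfSd)) stop("psfSd must be > 0")
  if (background < 0) stop("background must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(truePositions)
  edges <- (0:boxSize) * pixelSize
  stack <- array(0, c(boxSize, boxSize, n))
  for (i in seq_len(n)) {
    px <- diff(pnorm(edges, truePositions[i, 1], psfSd))
    py <- diff(pnorm(edges, truePositions[i, 2], psfSd))
    mu <- photonsPerFrame * outer(px, py) + background
    stack[, , i] <- if (noise) matrix(rpois(length(mu), mu), boxSize) else mu
  }
  list(stack = stack, truth = truePositions, pixelSize = pixelSize,
       psfSd = psfSd)
}

#' Write/read a spot image stack as a multi-page TIFF
#'
#' Each frame becomes one TIFF page (32-bit float, scaled to the unit interval by the
#' recorded maximum).
#'
#' @param stack a boxSize x boxSize x n array (photons)
#' @param path file path
#' @param scale intensity scale by which the stored image is multiplied
#' @return `readSpotStackTiff` returns the array; `writeSpotStackTiff`
#'   returns the intensity scale invisibly.
#' @export
writeSpotStackTiff <- function(stack, path) {
  sc <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(sc)
}

#' @rdname writeSpotStackTiff
#' @export
readSpotStackTiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]] * scale
  arr
}
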