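#' Accessors for iftdyn containers
#'
#' Small accessor generics for the S4 containers: frame times, axial/lateral
#' coordinates, phase labels and intensities of a [Trajectory-class];
#' occupancy, return times and totals of a [SteadyState-class]; detectable
#' counts of a [PhotoGateResult-class].
#'
#' @param x an iftdyn S4 object
#' @param ... unused
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x, ...) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("axialPosition", function(x, ...) standardGeneric("axialPosition"))
#' @rdname accessors
#' @export
setGeneric("lateralPosition", function(x, ...) standardGeneric("lateralPosition"))
#' @rdname accessors
#' @export
setGeneric("phaseLabels", function(x, ...) standardGeneric("phaseLabels"))
#' @rdname accessors
#' @export
setGeneric("spotIntensity", function(x, ...) standardGeneric("spotIntensity"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("returnTimes", function(x, ...) standardGeneric("returnTimes"))
#' @rdname accessors
#' @export
setGeneric("totalDiffusing", function(x, ...) standardGeneric("totalDiffusing"))
#' @rdname accessors
#' @export
setGeneric("detectableCounts", function(x, ...) standardGeneric("detectableCounts"))

#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x, ...) x@times)
#' @rdname accessors
#' @export
setMethod("axialPosition", "Trajectory", function(x, ...) x@axial)
#' @rdname accessors
#' @export
setMethod("lateralPosition", "Trajectory", function(x, ...) x@lateral)
#' @rdname accessors
#' @export
setMethod("phaseLabels", "Trajectory", function(x, ...) x@phase)
#' @rdname accessors
#' @export
setMethod("spotIntensity", "Trajectory", function(x, ...) x@intensity)
#' @rdname accessors
#' @export
setMethod("occupancy", "SteadyState", function(x, ...) x@occupancy)
#' @rdname accessors
#' @export
setMethod("returnTimes", "SteadyState", function(x, ...) x@returnTimes)
#' @rdname accessors
#' @export
setMethod("totalDiffusing", "SteadyState", function(x, ...) x@totalDiffusing)
#' @rdname accessors
#' @export
setMethod("detectableCounts", "PhotoGateResult", function(x, ...) x@counts)

#' @describeIn accessors number of samples in a trajectory
#' @export
setMethod("length", "Trajectory", function(x) length(x@times))

setMethod("show", "TrafficConfig", function(object) {
  cat("TrafficConfig: L =", object@flagellumLength, "um,",
      "antero", object@anteroSpeedMean, "+/-", object@anteroSpeedSd, "um/s,",
      "retro", object@retroSpeedMean, "+/-", object@retroSpeedSd, "um/s\n")
  cat("  injection", object@anteroFrequency, "trains/s, retro/antero ratio",
      object@retroToAnteroRatio, "\n")
  cat("  imaging:", object@frameRate, "Hz,", object@pixelSize, "nm px, PSF sd",
      object@psfSd, "nm,", object@photonsPerFrame, "photons/frame\n")
})

setMethod("show", "Trajectory", function(object) {
  n <- length(object@times)
  cat("Trajectory:", n, "samples at", object@frameRate, "Hz\n")
  if (n) {
    tb <- table(object@phase)
    cat("  phases:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
    cat("  axial range:", round(min(object@axial), 3), "-",
        round(max(object@axial), 3), "um\n")
  }
})

setMethod("show", "Kymograph", function(object) {
  cat("Kymograph:", nrow(object@image), "px x", ncol(object@image), "frames (",
      object@positionScale, "nm/px,", object@timeScale, "s/frame )\n")
  if (length(object@maskedColumns))
    cat("  ", length(object@maskedColumns), "gate-on columns masked\n")
})

setMethod("show", "FrapSeries", function(object) {
  cat("FrapSeries:", length(object@positions), "positions x",
      length(object@times), "frames; bleach window [",
      object@bleachWindow[1], ",", object@bleachWindow[2], "] um at t =",
      object@bleachTime, "s; noise:", object@noise, "\n")
})

setMethod("show", "PhotoGateResult", function(object) {
  cat("PhotoGateResult:", length(object@counts), "trials, nIn =", object@nIn,
      "\n  mean detectable retrograde trains:", round(object@meanCount, 3),
      "+/-", round(object@semCount, 3), "(s.e.m.)\n",
      " return frequency:", round(object@returnFrequency, 3), "/s\n")
})

setMethod("show", "TransportConfig", function(object) {
  cat("TransportConfig: L =", object@flagellumLength, "um, D =", object@D,
      "um^2/s, dt =", object@timeStep, "s\n  injection",
      object@injectionRate, "trains/s x", object@kapPerTrain,
      "KAP/train;", object@nSteps, "steps\n")
})

setMethod("show", "SteadyState", function(object) {
  cat("SteadyState:", length(object@occupancy), "grid sites (",
      round(object@gridSpacing, 4), "um )\n")
  cat("  diffusing:", round(object@totalDiffusing, 1),
      " anterograde-bound:", round(object@anteroBound, 1), "\n")
  cat("  mean return time:", round(object@meanReturnTime, 2), "s over",
      length(object@returnTimes), "absorptions\n")
})
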