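# Accessor generics. Slot access from user code is discouraged; these are
# the supported surface.

#' @export
setGeneric("cellLength", function(x) standardGeneric("cellLength"))
#' @export
setGeneric("cellRadius", function(x) standardGeneric("cellRadius"))
#' @export
setGeneric("cellDiameter", function(x) standardGeneric("cellDiameter"))
#' @export
setGeneric("cellVolume", function(x) standardGeneric("cellVolume"))
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @export
setGeneric("channelLabel", function(x) standardGeneric("channelLabel"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @export
setGeneric("maskedPixelCount", function(x) standardGeneric("maskedPixelCount"))
#' @export
setGeneric("pixelGrid", function(x) standardGeneric("pixelGrid"))
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))
#' @export
setGeneric("clampedCount", function(x) standardGeneric("clampedCount"))
#' @export
setGeneric("referenceSource", function(x) standardGeneric("referenceSource"))
#' @export
setGeneric("corValue", function(x) standardGeneric("corValue"))
#' @export
setGeneric("corMethod", function(x) standardGeneric("corMethod"))
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))
#' @export
setGeneric("fittedMean", function(x) standardGeneric("fittedMean"))
#' @export
setGeneric("fittedSigma", function(x) standardGeneric("fittedSigma"))
#' @export
setGeneric("nullSettings", function(x) standardGeneric("nullSettings"))

#' @describeIn Spherocylinder-class tip-to-tip length (micrometers).
#' @export
setMethod("cellLength", "Spherocylinder", function(x) x@length)
#' @describeIn Spherocylinder-class radius (micrometers).
#' @export
setMethod("cellRadius", "Spherocylinder", function(x) x@radius)
#' @describeIn Spherocylinder-class diameter 2r (micrometers).
#' @export
setMethod("cellDiameter", "Spherocylinder", function(x) 2 * x@radius)
#' @describeIn Spherocylinder-class volume of the spherocylinder
#'   (cubic micrometers): cylinder plus two hemispherical caps.
#' @export
setMethod("cellVolume", "Spherocylinder", function(x) {
  lc <- x@length - 2 * x@radius
  pi * x@radius^2 * lc + 4 / 3 * pi * x@radius^3
})

#' @describeIn Points3D-class number of points.
#' @export
setMethod("nPoints", "Points3D", function(x) length(x@x))
#' @describeIn Points3D-class number of points.
#' @export
setMethod("nPoints", "Points2D", function(x) length(x@x))
#' @describeIn Points3D-class coordinate data.frame (x, y[, z]) in
#'   micrometers.
#' @export
setMethod("coords", "Points3D",
          function(x) data.frame(x = x@x, y = x@y, z = x@z))
#' @describeIn Points3D-class coordinate data.frame (x, y).
#' @export
setMethod("coords", "Points2D", function(x) data.frame(x = x@x, y = x@y))
#' @describeIn Points3D-class channel label.
#' @export
setMethod("channelLabel", "Points3D", function(x) x@channel)
#' @describeIn Points3D-class channel label.
#' @export
setMethod("channelLabel", "Points2D", function(x) x@channel)

#' @describeIn PixelGrid-class pixel edge length (micrometers).
#' @export
setMethod("pixelSize", "PixelGrid", function(x) x@pixelSize)
#' @describeIn PixelGrid-class c(nRows, nCols).
#' @export
setMethod("gridDim", "PixelGrid", function(x) c(x@nRows, x@nCols))
#' @describeIn PixelGrid-class logical in-cell pixel mask.
#' @export
setMethod("gridMask", "PixelGrid", function(x) x@mask)
#' @describeIn PixelGrid-class lower-left corner of pixel (1,1), micrometers.
#' @export
setMethod("gridOrigin", "PixelGrid", function(x) x@origin)
#' @describeIn PixelGrid-class number of in-cell (masked) pixels, N_p.
#' @export
setMethod("maskedPixelCount", "PixelGrid", function(x) sum(x@mask))

#' @describeIn DensityImage-class the underlying grid.
#' @export
setMethod("pixelGrid", "DensityImage", function(x) x@grid)
#' @describeIn ReferenceMatrix-class the underlying grid.
#' @export
setMethod("pixelGrid", "ReferenceMatrix", function(x) x@grid)
#' @describeIn NormalizedDifference-class the underlying grid.
#' @export
setMethod("pixelGrid", "NormalizedDifference", function(x) x@grid)
#' @describeIn DensityImage-class the count/intensity matrix.
#' @export
setMethod("imageValues", "DensityImage", function(x) x@counts)
#' @describeIn ReferenceMatrix-class the normalized reference matrix.
#' @export
setMethod("imageValues", "ReferenceMatrix", function(x) x@values)
#' @describeIn NormalizedDifference-class the unit-norm difference matrix.
#' @export
setMethod("imageValues", "NormalizedDifference", function(x) x@values)
#' @describeIn DensityImage-class sum of all pixel values.
#' @export
setMethod("totalCounts", "DensityImage", function(x) sum(x@counts))
#' @describeIn ReferenceMatrix-class sum of all pixel values (= nTarget).
#' @export
setMethod("totalCounts", "ReferenceMatrix", function(x) sum(x@values))
#' @describeIn DensityImage-class out-of-grid localizations clamped to edge
#'   pixels.
#' @export
setMethod("clampedCount", "DensityImage", function(x) x@nClamped)
#' @describeIn ReferenceMatrix-class "simulated" or "empirical".
#' @export
setMethod("referenceSource", "ReferenceMatrix", function(x) x@source)

#' @describeIn CorrelationResult-class the coefficient value.
#' @export
setMethod("corValue", "CorrelationResult", function(x) x@value)
#' @describeIn CorrelationResult-class "PCC" or "MPCC".
#' @export
setMethod("corMethod", "CorrelationResult", function(x) x@method)

#' @describeIn NullDistribution-class the Monte-Carlo MPCC samples.
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)
#' @describeIn NullDistribution-class Gaussian-fit mean.
#' @export
setMethod("fittedMean", "NullDistribution", function(x) x@fittedMean)
#' @describeIn NullDistribution-class Gaussian-fit standard deviation.
#' @export
setMethod("fittedSigma", "NullDistribution", function(x) x@fittedSigma)
#' @describeIn NullDistribution-class the generating settings.
#' @export
setMethod("nullSettings", "NullDistribution", function(x) x@settings)

setMethod("show", "Spherocylinder", function(object) {
  cat(sprintf(
    "Spherocylinder: L = %.3g um tip-to-tip, 2r = %.3g um (volume %.3g um^3)\n",
    object@length, 2 * object@radius, cellVolume(object)))
})

setMethod("show", "Points3D", function(object) {
  cat(sprintf("Points3D: %d points, channel '%s'\n",
              nPoints(object), object@channel))
})

setMethod("show", "Points2D", function(object) {
  cat(sprintf("Points2D: %d points, channel '%s', locSigma = %g um\n",
              nPoints(object), object@channel, object@locSigma))
})

setMethod("show", "PixelGrid", function(object) {
  cat(sprintf(
    "PixelGrid: %d x %d pixels of %g um (%d in-cell pixels)\n",
    object@nRows, object@nCols, object@pixelSize, sum(object@mask)))
})

setMethod("show", "DensityImage", function(object) {
  cat(sprintf(
    "DensityImage: %d x %d pixels of %g um, total %.6g",
    nrow(object@counts), ncol(object@counts), object@grid@pixelSize,
    sum(object@counts)))
  if (object@nClamped > 0)
    cat(sprintf(" (%d clamped to grid edge)", as.integer(object@nClamped)))
  cat("\n")
})

setMethod("show", "ReferenceMatrix", function(object) {
  cat(sprintf(
    "ReferenceMatrix (%s): %d x %d pixels, scaled to %.6g from %d molecules\n",
    object@source, nrow(object@values), ncol(object@values), object@nTarget,
    as.integer(object@nSource)))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("%s = %+.4f\n", object@method, object@value))
  cat(sprintf(
    "  n_red = %.6g, n_green = %.6g, pixel %g um, %d in-cell pixels\n",
    object@nRed, object@nGreen, object@pixelSize, object@nPixelsMasked))
  cat(sprintf("  mean occupancy/pixel: red %.3g, green %.3g\n",
              object@meanOccupancyRed, object@meanOccupancyGreen))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d trials, fitted mean %+.4g, sigma %.4g\n",
    object@nTrials, object@fittedMean, object@fittedSigma))
  if (object@nTrials < 30L)
    cat("  note: few trials; the Gaussian fit has a wide confidence interval\n")
})
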