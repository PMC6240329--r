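#' @import methods
NULL

.mpccStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mpccError", "error", "condition")))
}

#' Spherocylinder cell geometry
#'
#' An idealized rod-shaped bacterial cell: a cylinder of radius \code{radius}
#' capped by two hemispheres. \code{length} is the tip-to-tip length,
#' including both caps, so the cylindrical section has length
#' \code{length - 2 * radius}. The cell long axis lies along x, the origin is
#' at the cell center and the optical axis is z.
#'
#' @slot length tip-to-tip cell length in micrometers.
#' @slot radius cell radius in micrometers (half the diameter).
#'
#' @examples
#' cell <- Spherocylinder(length = 3.5, diameter = 0.82)
#' cellVolume(cell)
#' @name Spherocylinder-class
#' @exportClass Spherocylinder
setClass("Spherocylinder",
  slots = c(length = "numeric", radius = "numeric"),
  validity = function(object) {
    if (length(object@length) != 1L || length(object@radius) != 1L)
      return("length and radius must be scalars")
    if (!is.finite(object@length) || !is.finite(object@radius))
      return("length and radius must be finite")
    if (object@radius <= 0)
      return("radius must be strictly positive")
    if (object@length < 2 * object@radius)
      return("tip-to-tip length must be at least one diameter (2*radius)")
    TRUE
  }
)

#' @param length tip-to-tip length in micrometers.
#' @param diameter cell diameter (2r) in micrometers; give exactly one of
#'   \code{diameter} or \code{radius}.
#' @param radius cell radius in micrometers.
#' @rdname Spherocylinder-class
#' @export
Spherocylinder <- function(length, diameter = NULL, radius = NULL) {
  if (is.null(radius) == is.null(diameter))
    .mpccStop("give exactly one of 'diameter' or 'radius'", "mpccArgumentError")
  if (is.null(radius)) radius <- diameter / 2
  new("Spherocylinder", length = as.numeric(length), radius = as.numeric(radius))
}

#' Point sets in cell-frame coordinates
#'
#' \code{Points3D} holds molecule coordinates (micrometers) inside the cell
#' volume; \code{Points2D} holds coordinates after projection along the
#' optical (z) axis, optionally perturbed by localization error. The
#' \code{locSigma} slot records the Gaussian localization error (standard
#' deviation, micrometers) that was applied in x and y (0 if none).
#'
#' @slot x,y,z numeric coordinate vectors of equal length, micrometers.
#' @slot channel free-text channel label.
#' @slot locSigma localization error sigma applied, micrometers.
#' @name Points3D-class
#' @aliases Points2D-class
#' @exportClass Points3D
setClass("Points3D",
  slots = c(x = "numeric", y = "numeric", z = "numeric", channel = "character"),
  prototype = prototype(channel = ""),
  validity = function(object) {
    n <- length(object@x)
    if (length(object@y) != n || length(object@z) != n)
      return("x, y, z must have equal length")
    if (length(object@channel) != 1L) return("channel must be a single label")
    TRUE
  }
)

#' @exportClass Points2D
#' @rdname Points3D-class
setClass("Points2D",
  slots = c(x = "numeric", y = "numeric", channel = "character",
            locSigma = "numeric"),
  prototype = prototype(channel = "", locSigma = 0),
  validity = function(object) {
    if (length(object@x) != length(object@y))
      return("x and y must have equal length")
    if (length(object@channel) != 1L) return("channel must be a single label")
    if (length(object@locSigma) != 1L || object@locSigma < 0)
      return("locSigma must be a single non-negative value")
    TRUE
  }
)

#' @param x,y,z numeric coordinate vectors (micrometers).
#' @param channel channel label.
#' @rdname Points3D-class
#' @export
Points3D <- function(x, y, z, channel = "") {
  new("Points3D", x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
      channel = channel)
}

#' @param locSigma localization sigma recorded on the set (micrometers).
#' @rdname Points3D-class
#' @export
Points2D <- function(x, y, channel = "", locSigma = 0) {
  new("Points2D", x = as.numeric(x), y = as.numeric(y), channel = channel,
      locSigma = as.numeric(locSigma))
}

#' Pixelation grid over the cell footprint
#'
#' A regular square-pixel grid covering the bounding box of the projected
#' cell ("stadium") footprint, centered on the cell. \code{mask} flags
#' pixels whose center lies inside the footprint; masked pixels define the
#' in-cell pixel count \eqn{N_p} used for occupancy and for mask-restricted
#' PCC.
#'
#' @slot pixelSize pixel edge length, micrometers.
#' @slot nRows,nCols grid dimensions (rows index y, columns index x).
#' @slot origin x,y position (micrometers) of the lower-left corner of
#'   pixel (1,1).
#' @slot mask logical nRows x nCols matrix of in-cell pixels.
#' @name PixelGrid-class
#' @exportClass PixelGrid
setClass("PixelGrid",
  slots = c(pixelSize = "numeric", nRows = "integer", nCols = "integer",
            origin = "numeric", mask = "matrix"),
  validity = function(object) {
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single positive value")
    if (object@nRows < 1L || object@nCols < 1L)
      return("grid must have at least one row and one column")
    if (length(object@origin) != 2L) return("origin must be length-2 (x, y)")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (!identical(dim(object@mask), c(object@nRows, object@nCols)))
      return("mask dimensions must be nRows x nCols")
    TRUE
  }
)

#' Pixelated density image
#'
#' A non-negative count (localization mode) or intensity (widefield mode)
#' matrix on a \linkS4class{PixelGrid}. \code{nClamped} counts localizations
#' that fell outside the grid extent (possible after localization noise) and
#' were assigned to the nearest edge pixel so that channel totals are
#' preserved.
#'
#' @slot counts nRows x nCols non-negative matrix.
#' @slot grid the \linkS4class{PixelGrid}.
#' @slot nClamped number of out-of-grid localizations clamped to edge pixels.
#' @name DensityImage-class
#' @exportClass DensityImage
setClass("DensityImage",
  slots = c(counts = "matrix", grid = "PixelGrid", nClamped = "numeric"),
  prototype = prototype(nClamped = 0),
  validity = function(object) {
    g <- object@grid
    if (!identical(dim(object@counts), c(g@nRows, g@nCols)))
      return("counts dimensions must match the grid")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      return("counts must be finite and non-negative")
    TRUE
  }
)

#' @param counts non-negative matrix.
#' @param grid a \linkS4class{PixelGrid} with matching dimensions.
#' @param nClamped count of clamped out-of-grid points.
#' @rdname DensityImage-class
#' @export
DensityImage <- function(counts, grid, nClamped = 0) {
  new("DensityImage", counts = counts, grid = grid,
      nClamped = as.numeric(nClamped))
}

#' Normalized projected-random reference matrix
#'
#' The pixelated 2D projection of a large uniform random fill of the cell
#' volume, rescaled so its total equals the number of molecules imaged in
#' the channel it will be compared against. This is the reference that
#' replaces the constant mean of the standard PCC.
#'
#' @slot values non-negative matrix summing to \code{nTarget}.
#' @slot grid the \linkS4class{PixelGrid}.
#' @slot nTarget total the matrix is scaled to (imaged molecule count).
#' @slot source \code{"simulated"} or \code{"empirical"}.
#' @slot nSource number of molecules the unscaled reference was built from.
#' @name ReferenceMatrix-class
#' @exportClass ReferenceMatrix
setClass("ReferenceMatrix",
  slots = c(values = "matrix", grid = "PixelGrid", nTarget = "numeric",
            source = "character", nSource = "numeric"),
  validity = function(object) {
    g <- object@grid
    if (!identical(dim(object@values), c(g@nRows, g@nCols)))
      return("values dimensions must match the grid")
    if (any(object@values < 0)) return("values must be non-negative")
    if (!object@source %in% c("simulated", "empirical"))
      return("source must be 'simulated' or 'empirical'")
    if (abs(sum(object@values) - object@nTarget) >
        1e-6 * max(1, object@nTarget))
      return("values must sum to nTarget")
    TRUE
  }
)

#' Unit Frobenius-norm difference matrix
#'
#' (image - reference), scaled so the sum of squared pixel values is 1.
#' The MPCC is the Frobenius inner product of the red and green normalized
#' difference matrices.
#'
#' @slot values real matrix with Frobenius norm 1.
#' @slot grid the \linkS4class{PixelGrid}.
#' @name NormalizedDifference-class
#' @exportClass NormalizedDifference
setClass("NormalizedDifference",
  slots = c(values = "matrix", grid = "PixelGrid"),
  validity = function(object) {
    g <- object@grid
    if (!identical(dim(object@values), c(g@nRows, g@nCols)))
      return("values dimensions must match the grid")
    if (abs(sqrt(sum(object@values^2)) - 1) > 1e-9)
      return("Frobenius norm must be 1")
    TRUE
  }
)

#' Correlation statistic result
#'
#' Holds a PCC or MPCC value together with the settings it was computed
#' under (channel totals, pixel size, in-cell pixel count, mean occupancy
#' per pixel per channel).
#'
#' @slot value correlation coefficient in [-1, 1].
#' @slot method \code{"PCC"} or \code{"MPCC"}.
#' @slot nRed,nGreen channel totals.
#' @slot pixelSize micrometers.
#' @slot nPixelsMasked in-cell pixel count.
#' @slot meanOccupancyRed,meanOccupancyGreen mean molecules per in-cell pixel.
#' @name CorrelationResult-class
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  slots = c(value = "numeric", method = "character", nRed = "numeric",
            nGreen = "numeric", pixelSize = "numeric",
            nPixelsMasked = "integer", meanOccupancyRed = "numeric",
            meanOccupancyGreen = "numeric"),
  validity = function(object) {
    if (length(object@value) != 1L || !is.finite(object@value))
      return("value must be a single finite number")
    if (object@value < -1 - 1e-9 || object@value > 1 + 1e-9)
      return("value must lie in [-1, 1]")
    if (!object@method %in% c("PCC", "MPCC"))
      return("method must be 'PCC' or 'MPCC'")
    TRUE
  }
)

#' Monte-Carlo null distribution of the MPCC
#'
#' MPCC values computed between pairs of independent uniform random fills
#' of the cell, under the settings stored in \code{settings}, with a
#' Gaussian fit (sample mean and standard deviation).
#'
#' @slot samples MPCC values, one per trial.
#' @slot nTrials number of Monte-Carlo trials.
#' @slot fittedMean,fittedSigma Gaussian fit to the samples.
#' @slot settings list of the generating settings (geometry, pixel size,
#'   channel totals, sigmas, reference size, seed).
#' @name NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
  slots = c(samples = "numeric", nTrials = "integer", fittedMean = "numeric",
            fittedSigma = "numeric", settings = "list"),
  validity = function(object) {
    if (object@nTrials != length(object@samples))
      return("nTrials must equal length(samples)")
    if (object@nTrials < 2L) return("need at least 2 trials")
    if (any(abs(object@samples) > 1 + 1e-9))
      return("all samples must lie in [-1, 1]")
    if (object@fittedSigma <= 0) return("fittedSigma must be positive")
    TRUE
  }
)
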