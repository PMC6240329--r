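# PCC and MPCC between two pixelated images.
#
# PCC compares each image against a constant-mean reference; MPCC compares
# against the normalized projected-random reference of the cell geometry,
# which removes the projection-induced positive bias.

.checkSameGrid <- function(a, b) {
  ga <- pixelGrid(a); gb <- pixelGrid(b)
  if (!isTRUE(all.equal(ga@pixelSize, gb@pixelSize)) ||
      !identical(gridDim(ga), gridDim(gb)) ||
      !isTRUE(all.equal(ga@origin, gb@origin)))
    .mpccStop("inputs are not on the same pixel grid", "mpccGridMismatchError")
  invisible(TRUE)
}

.occ <- function(total, grid) total / max(1L, maskedPixelCount(grid))

.corResult <- function(value, method, imR, imG) {
  g <- pixelGrid(imR)
  new("CorrelationResult",
      value = min(1, max(-1, value)), method = method,
      nRed = totalCounts(imR), nGreen = totalCounts(imG),
      pixelSize = pixelSize(g), nPixelsMasked = as.integer(maskedPixelCount(g)),
      meanOccupancyRed = .occ(totalCounts(imR), g),
      meanOccupancyGreen = .occ(totalCounts(imG), g))
}

#' Standard Pearson correlation coefficient between two images
#'
#' Pixel-wise linear correlation of the two matrices against their constant
#' means. By default the sum runs over the in-cell (masked) pixels only;
#' \code{restrictToMask = FALSE} evaluates the full matrix, which
#' demonstrates the zero-inflation artifact caused by empty extracellular
#' pixels. Note that for 2D projections of 3D-random distributions the PCC
#' is biased toward +1 regardless of masking; see \code{\link{mpcc}}.
#'
#' @param imageR,imageG \linkS4class{DensityImage}s on the same grid.
#' @param restrictToMask evaluate over in-cell pixels only (default TRUE).
#' @return a \linkS4class{CorrelationResult} with \code{method = "PCC"}.
#' @export
pcc <- function(imageR, imageG, restrictToMask = TRUE) {
  .checkSameGrid(imageR, imageG)
  R <- imageValues(imageR); G <- imageValues(imageG)
  if (restrictToMask) {
    keep <- gridMask(pixelGrid(imageR))
    r <- R[keep]; g <- G[keep]
  } else {
    r <- as.vector(R); g <- as.vector(G)
  }
  if (length(r) < 2L)
    .mpccStop("need at least 2 pixels in scope", "mpccArgumentError")
  dr <- r - mean(r); dg <- g - mean(g)
  denom <- sqrt(sum(dr^2)) * sqrt(sum(dg^2))
  if (denom == 0)
    .mpccStop("constant image: PCC is undefined (zero variance)",
              "mpccDegenerateError")
  .corResult(sum(dr * dg) / denom, "PCC", imageR, imageG)
}

#' Normalized difference matrix of an image against its reference
#'
#' Subtracts the reference from the image and scales the difference to unit
#' Frobenius norm, so the sum of squared pixel values is 1. When the
#' reference is normalized to the image total, the unnormalized difference
#' sums to zero.
#'
#' @param image a \linkS4class{DensityImage}.
#' @param reference a \linkS4class{ReferenceMatrix} on the same grid.
#' @return a \linkS4class{NormalizedDifference}.
#' @export
differenceMatrix <- function(image, reference) {
  .checkSameGrid(image, reference)
  d <- imageValues(image) - imageValues(reference)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0)
    .mpccStop("image equals its reference: difference is undefined",
              "mpccDegenerateError")
  new("NormalizedDifference", values = d / nrm, grid = pixelGrid(image))
}

#' Modified Pearson correlation coefficient of two images
#'
#' Replaces the constant-mean references of the PCC with the normalized
#' projected-random reference matrices of the cell geometry: the MPCC is
#' the Frobenius inner product of the two unit-norm difference matrices
#' (image minus reference). It lies in [-1, 1], approaches 0 for
#' projections of independent 3D-random distributions, and is insensitive
#' to empty pixels outside the cell (reference and image are both zero
#' there), so it is always evaluated over the full matrix.
#'
#' Each reference must be normalized to its image's total; if not, it is
#' re-normalized with a warning.
#'
#' @param imageR,imageG \linkS4class{DensityImage}s on one grid.
#' @param refR,refG \linkS4class{ReferenceMatrix}s on the same grid,
#'   normalized to the corresponding image totals.
#' @return a \linkS4class{CorrelationResult} with \code{method = "MPCC"}.
#' @examples
#' cell <- Spherocylinder(3.5, diameter = 0.82)
#' grid <- makeGrid(cell, 0.2)
#' ref <- buildReference(cell, grid, nReference = 100000, seed = 1)
#' ab <- generateCaseI(cell, 20000, seed = 2)
#' imR <- pixelate(projectToPlane(ab$red), grid)
#' imG <- pixelate(projectToPlane(ab$green), grid)
#' mpcc(imR, imG,
#'      normalizeReference(ref, totalCounts(imR)),
#'      normalizeReference(ref, totalCounts(imG)))
#' @export
mpcc <- function(imageR, imageG, refR, refG) {
  .checkSameGrid(imageR, imageG)
  .checkSameGrid(imageR, refR)
  .checkSameGrid(imageR, refG)
  refR <- .ensureNormalized(refR, totalCounts(imageR), "red")
  refG <- .ensureNormalized(refG, totalCounts(imageG), "green")
  dR <- differenceMatrix(imageR, refR)
  dG <- differenceMatrix(imageG, refG)
  .corResult(sum(imageValues(dR) * imageValues(dG)), "MPCC", imageR, imageG)
}

.ensureNormalized <- function(ref, nTarget, which) {
  if (abs(totalCounts(ref) - nTarget) <= 1e-9 * max(1, nTarget)) return(ref)
  warning(sprintf(
    "%s reference total (%.6g) does not match the image total (%.6g); re-normalizing",
    which, totalCounts(ref), nTarget))
  new("ReferenceMatrix", values = ref@values * nTarget / totalCounts(ref),
      grid = ref@grid, nTarget = as.numeric(nTarget), source = ref@source,
      nSource = ref@nSource)
}

#' Pixel-wise pairs of normalized difference elements
#'
#' One (red, green) pair per pixel in row-major order — the data behind the
#' diagnostic scatter plots whose slope sign mirrors the MPCC. The sum of
#' the products of the pairs equals the MPCC.
#'
#' @param diffR,diffG \linkS4class{NormalizedDifference}s on one grid.
#' @return data.frame with columns \code{red} and \code{green}, one row per
#'   pixel.
#' @export
scatterPairs <- function(diffR, diffG) {
  .checkSameGrid(diffR, diffG)
  data.frame(red = as.vector(t(imageValues(diffR))),
             green = as.vector(t(imageValues(diffG))))
}
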