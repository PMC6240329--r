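# Reference spatial patterns: three anti-correlation constructions, a
# perfect positive correlation, and independent random fills. These are the
# model distributions against which PCC and MPCC behaviour is validated.
#
# Region tie-breaks: a point exactly on a boundary plane goes to the
# right/central region; measure-zero and deterministic.

#' Anti-correlation Case I: left/right half split
#'
#' \code{nTotal} molecules are distributed uniformly in the cell volume;
#' those with x < 0 are designated red, those with x >= 0 green. Red and
#' green supports are disjoint, so the 2D projections are perfectly
#' anti-correlated; per-channel counts are Binomial(nTotal, 1/2).
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param nTotal total molecules to distribute (>= 2).
#' @param seed optional integer seed.
#' @return list with \code{red} and \code{green} \linkS4class{Points3D}.
#' @export
generateCaseI <- function(geom, nTotal, seed = NULL) {
  if (nTotal < 2)
    .mpccStop("nTotal must be at least 2", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  pts <- sampleUniformSpherocylinder(geom, nTotal)
  left <- pts@x < 0
  list(red = Points3D(pts@x[left], pts@y[left], pts@z[left], channel = "red"),
       green = Points3D(pts@x[!left], pts@y[!left], pts@z[!left],
                        channel = "green"))
}

#' Anti-correlation Case II: endcaps vs central region
#'
#' Red molecules occupy the two end regions \code{|x| > xSplit}, green the
#' central region \code{|x| <= xSplit}, with exactly \code{nPerChannel}
#' molecules each, uniform within their regions (rejection from the
#' whole-cell sampler). The default \code{xSplit} is the volume median of
#' |x|, so the two regions hold equal volume.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param nPerChannel molecules per channel.
#' @param xSplit boundary plane |x| position, in (0, L/2); \code{NULL} for
#'   the equal-volume default.
#' @param seed optional integer seed.
#' @return list with \code{red} and \code{green} \linkS4class{Points3D}.
#' @export
generateCaseII <- function(geom, nPerChannel, xSplit = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(xSplit)) xSplit <- caseIISplit(geom)
  L <- cellLength(geom)
  if (xSplit <= 0 || xSplit >= L / 2)
    .mpccStop("xSplit must lie strictly inside (0, L/2)", "mpccArgumentError")
  red <- .sampleRegion(geom, nPerChannel, function(p) abs(p@x) > xSplit, "red")
  green <- .sampleRegion(geom, nPerChannel, function(p) abs(p@x) <= xSplit,
                         "green")
  list(red = red, green = green)
}

#' @describeIn generateCaseII the equal-volume default split: |x| position
#'   such that half the cell volume lies beyond it.
#' @export
caseIISplit <- function(geom) {
  # volume of |x| > s is V - (V(s) - V(-s)) = V - 2*(V(s) - V/2) by symmetry
  V <- cellVolume(geom)
  stats::uniroot(function(s) 2 * (.axialVolume(geom, s) - V / 2) - V / 2,
                 lower = 1e-9, upper = cellLength(geom) / 2 - 1e-9,
                 tol = 1e-9 * cellLength(geom))$root
}

#' Anti-correlation Case III: leftmost 2/3 vs rightmost 1/3 of the volume
#'
#' Red molecules fill the region left of the plane holding 2/3 of the cell
#' volume; green fill the remainder. Equal channel counts over a 2:1 volume
#' ratio, so the green density is about twice the red.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param nPerChannel molecules per channel (>= 1).
#' @param seed optional integer seed.
#' @return list with \code{red}, \code{green} \linkS4class{Points3D} and
#'   the boundary \code{xBoundary}.
#' @export
generateCaseIII <- function(geom, nPerChannel, seed = NULL) {
  if (nPerChannel < 1)
    .mpccStop("nPerChannel must be at least 1", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  x23 <- .axialQuantile(geom, 2 / 3)
  red <- .sampleRegion(geom, nPerChannel, function(p) p@x < x23, "red")
  green <- .sampleRegion(geom, nPerChannel, function(p) p@x >= x23, "green")
  list(red = red, green = green, xBoundary = x23)
}

#' Perfect positive correlation: two independent left-half fills
#'
#' Two independent uniform fills of \code{nFillEach} molecules; in each,
#' only the molecules in the left half (x < 0) are kept — fill 1 gives the
#' red channel, fill 2 the green. Both channels sample the same spatial
#' density, so the expected MPCC is +1 (within counting noise).
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param nFillEach molecules per fill before deletion (>= 2).
#' @param seed optional integer seed.
#' @return list with \code{red} and \code{green} \linkS4class{Points3D},
#'   each about \code{nFillEach / 2} points.
#' @export
generateCorrelated <- function(geom, nFillEach, seed = NULL) {
  if (nFillEach < 2)
    .mpccStop("nFillEach must be at least 2", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  keepLeft <- function(pts, ch) {
    k <- pts@x < 0
    Points3D(pts@x[k], pts@y[k], pts@z[k], channel = ch)
  }
  list(red = keepLeft(sampleUniformSpherocylinder(geom, nFillEach), "red"),
       green = keepLeft(sampleUniformSpherocylinder(geom, nFillEach), "green"))
}

#' Independent random fills with localization error
#'
#' Two statistically independent uniform 3D fills, perturbed by
#' channel-specific localization error and projected to the camera plane —
#' the uncorrelated null construction used for Monte-Carlo calibration.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param nRed,nGreen molecules per channel (>= 0).
#' @param sigmaRed,sigmaGreen localization error sigma per channel,
#'   micrometers.
#' @param seed optional integer seed.
#' @return list with \code{red} and \code{green} \linkS4class{Points2D}.
#' @export
generateIndependent <- function(geom, nRed, nGreen, sigmaRed = 0,
                                sigmaGreen = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(n, sigma, ch) {
    pts <- sampleUniformSpherocylinder(geom, n, channel = ch)
    pts <- applyLocalizationError(pts, sigma)
    projectToPlane(pts, locSigma = sigma)
  }
  list(red = one(nRed, sigmaRed, "red"),
       green = one(nGreen, sigmaGreen, "green"))
}

# Uniform sample of exactly n points from the sub-region of the cell where
# `predicate(points)` holds, by rejection from the whole-cell sampler.
.sampleRegion <- function(geom, n, predicate, channel) {
  x <- y <- z <- numeric(0)
  while (length(x) < n) {
    pts <- sampleUniformSpherocylinder(geom, max(1000L, 2L * (n - length(x))))
    keep <- predicate(pts)
    if (!any(keep)) next
    x <- c(x, pts@x[keep]); y <- c(y, pts@y[keep]); z <- c(z, pts@z[keep])
  }
  Points3D(x[seq_len(n)], y[seq_len(n)], z[seq_len(n)], channel = channel)
}
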