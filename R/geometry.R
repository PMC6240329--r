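# Spherocylinder geometry: membership predicates, uniform 3D sampling,
# localization error, projection to the camera plane.
#
# Coordinate convention: cell long axis along x, origin at the cell center,
# optical axis along z. All lengths in micrometers.

#' Test whether 3D points lie inside the spherocylinder
#'
#' The cell interior is the closed set: cylinder
#' \eqn{y^2 + z^2 \le r^2, |x| \le L/2 - r} union the two hemispherical
#' caps centered at \eqn{(\pm(L/2 - r), 0, 0)}. Boundary points count as
#' inside.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param x,y,z numeric vectors of coordinates (micrometers), recycled to a
#'   common length.
#' @return logical vector.
#' @export
membership <- function(geom, x, y, z) {
  r <- cellRadius(geom)
  half <- cellLength(geom) / 2 - r
  rad2 <- y^2 + z^2
  inCyl <- abs(x) <= half & rad2 <= r^2
  dx <- abs(x) - half
  inCap <- dx^2 + rad2 <= r^2
  inCyl | inCap
}

#' Test whether 2D points lie inside the projected "stadium" footprint
#'
#' The z-projection of the spherocylinder is a rectangle of half-width r
#' flanked by two semicircular caps (a stadium). Boundary points count as
#' inside.
#'
#' @inheritParams membership
#' @return logical vector.
#' @export
footprintContains <- function(geom, x, y) {
  r <- cellRadius(geom)
  half <- cellLength(geom) / 2 - r
  inRect <- abs(x) <= half & abs(y) <= r
  dx <- abs(x) - half
  inCap <- dx^2 + y^2 <= r^2
  inRect | inCap
}

#' Sample points uniformly within a spherocylinder
#'
#' Rejection sampling from the axis-aligned bounding box
#' \eqn{[-L/2, L/2] \times [-r, r] \times [-r, r]}; acceptance probability
#' is volume/box (above 50\% for typical bacterial aspect ratios), so the
#' draw is unbiased and cheap.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param n number of points (non-negative integer).
#' @param channel channel label attached to the returned set.
#' @param seed optional integer; when given, \code{set.seed(seed)} is called
#'   so the draw is reproducible. When \code{NULL} the current RNG stream
#'   is used (so enclosing simulations stay reproducible from one seed).
#' @return a \linkS4class{Points3D} of exactly \code{n} i.i.d. uniform
#'   points.
#' @examples
#' cell <- Spherocylinder(3.5, diameter = 0.82)
#' pts <- sampleUniformSpherocylinder(cell, 1000, seed = 1)
#' all(membership(cell, coords(pts)$x, coords(pts)$y, coords(pts)$z))
#' @export
sampleUniformSpherocylinder <- function(geom, n, channel = "", seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 0)
    .mpccStop("n must be a single non-negative count", "mpccArgumentError")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  L <- cellLength(geom)
  r <- cellRadius(geom)
  x <- y <- z <- numeric(0)
  # accept/reject in batches sized by the expected acceptance rate
  rate <- cellVolume(geom) / (L * (2 * r)^2)
  while (length(x) < n) {
    m <- max(100L, ceiling((n - length(x)) / rate * 1.1))
    cx <- stats::runif(m, -L / 2, L / 2)
    cy <- stats::runif(m, -r, r)
    cz <- stats::runif(m, -r, r)
    keep <- membership(geom, cx, cy, cz)
    x <- c(x, cx[keep]); y <- c(y, cy[keep]); z <- c(z, cz[keep])
  }
  Points3D(x[seq_len(n)], y[seq_len(n)], z[seq_len(n)], channel = channel)
}

#' Apply Gaussian localization error in x and y
#'
#' Each point is perturbed independently in x and y by zero-mean Gaussian
#' noise of standard deviation \code{sigma}, emulating the positional
#' uncertainty of single-molecule localization. z is untouched (the
#' projection discards it). Perturbed points may fall outside the cell
#' footprint and are kept: they are the "measured" positions.
#'
#' @param points a \linkS4class{Points3D} or \linkS4class{Points2D}.
#' @param sigma localization error standard deviation, micrometers
#'   (non-negative).
#' @param seed optional integer seed (see
#'   \code{\link{sampleUniformSpherocylinder}}).
#' @return an object of the same class, with \code{locSigma} recorded when
#'   the input is 2D.
#' @export
applyLocalizationError <- function(points, sigma, seed = NULL) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    .mpccStop("sigma must be a single non-negative value", "mpccArgumentError")
  if (sigma == 0) return(points)
  if (!is.null(seed)) set.seed(seed)
  n <- nPoints(points)
  dx <- stats::rnorm(n, 0, sigma)
  dy <- stats::rnorm(n, 0, sigma)
  if (is(points, "Points3D")) {
    Points3D(points@x + dx, points@y + dy, points@z,
             channel = points@channel)
  } else {
    Points2D(points@x + dx, points@y + dy, channel = points@channel,
             locSigma = sqrt(points@locSigma^2 + sigma^2))
  }
}

#' Project a 3D point set onto the camera (xy) plane
#'
#' Models epi-illumination imaging: the microscope integrates fluorescence
#' along the optical (z) axis, so the projection simply drops z. x and y
#' are copied verbatim and the point count is preserved. Applying it to an
#' already-projected set is a contract error.
#'
#' @param points a \linkS4class{Points3D}.
#' @param locSigma localization sigma (micrometers) to record on the
#'   result, 0 if none was applied.
#' @return a \linkS4class{Points2D}.
#' @export
projectToPlane <- function(points, locSigma = 0) {
  if (!is(points, "Points3D"))
    .mpccStop("projectToPlane expects a Points3D (z present)",
              "mpccArgumentError")
  Points2D(points@x, points@y, channel = points@channel, locSigma = locSigma)
}

# Cumulative axial volume V(-L/2 .. x) of the spherocylinder.
# Cross-section area: pi r^2 in the cylinder, pi (r^2 - u^2) in the caps
# (u = axial distance past the cylinder end).
.axialVolume <- function(geom, x) {
  r <- cellRadius(geom)
  half <- cellLength(geom) / 2 - r
  capV <- 2 / 3 * pi * r^3
  sapply(x, function(xx) {
    if (xx <= -half) {
      u <- max(xx + half, -r)
      pi * (r^2 * u - u^3 / 3 + 2 / 3 * r^3)
    } else if (xx <= half) {
      capV + pi * r^2 * (xx + half)
    } else {
      u <- min(xx - half, r)
      capV + pi * r^2 * 2 * half + pi * (r^2 * u - u^3 / 3)
    }
  })
}

# Axial position x such that the volume left of x is `frac` of the total.
.axialQuantile <- function(geom, frac) {
  L <- cellLength(geom)
  V <- cellVolume(geom)
  stats::uniroot(function(x) .axialVolume(geom, x) - frac * V,
                 lower = -L / 2, upper = L / 2,
                 tol = 1e-6 * L)$root
}
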