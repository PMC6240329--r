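# Shared fixtures: the standard cell of the validation simulations
# (L = 3.5 um tip-to-tip, diameter 0.82 um) and its 200 nm grid.

stdCell <- function() Spherocylinder(length = 3.5, diameter = 0.82)

stdGrid <- function(pixelSize = 0.2) makeGrid(stdCell(), pixelSize)

# Monte-Carlo fraction of the cell volume left of plane x, via the sampler
# itself is NOT allowed as its own oracle; this is an independent
# quadrature of the axial cross-section area.
volumeFractionLeftOf <- function(geom, x0, nGrid = 20000) {
  L <- cellLength(geom); r <- cellRadius(geom)
  half <- L / 2 - r
  area <- function(x) {
    w2 <- ifelse(abs(x) <= half, r^2, r^2 - (abs(x) - half)^2)
    ifelse(w2 > 0, pi * w2, 0)
  }
  xs <- seq(-L / 2, L / 2, length.out = nGrid)
  cum <- cumsum(area(xs)) * (xs[2] - xs[1])
  tot <- cum[nGrid]
  stats::approx(xs, cum, xout = x0)$y / tot
}

# DensityImage on an enlarged window with the same pixel centers: used for
# the zero-padding invariance checks.
padImage <- function(image, geom, extraUm = c(1, 1)) {
  g <- pixelGrid(image)
  w <- c(ncol(imageValues(image)), nrow(imageValues(image))) * pixelSize(g) +
    2 * extraUm
  bigGrid <- makeGrid(geom, pixelSize(g), window = w)
  kx <- (bigGrid@nCols - g@nCols) / 2
  ky <- (bigGrid@nRows - g@nRows) / 2
  m <- matrix(0, bigGrid@nRows, bigGrid@nCols)
  m[ky + seq_len(g@nRows), kx + seq_len(g@nCols)] <- imageValues(image)
  DensityImage(m, bigGrid)
}
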