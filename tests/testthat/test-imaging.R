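# Pixelation, masks, reference matrices.

test_that("grid dimensions and in-cell pixel counts match the cell", {
  g <- stdGrid()
  expect_identical(gridDim(g), c(5L, 18L))
  np <- maskedPixelCount(g)
  expect_lt(abs(np - 75) / 75, 0.08)

  g2 <- makeGrid(Spherocylinder(3.74, diameter = 0.82), 0.105)
  expect_lt(abs(maskedPixelCount(g2) - 279) / 279, 0.08)

  # mask is symmetric under both reflections (grid centered on the cell)
  m <- gridMask(g2)
  expect_identical(m, m[rev(seq_len(nrow(m))), ])
  expect_identical(m, m[, rev(seq_len(ncol(m)))])

  coarse <- makeGrid(stdCell(), 3.5)
  expect_identical(gridDim(coarse)[2], 1L)

  expect_error(makeGrid(stdCell(), 0), "positive")
  expect_error(makeGrid(stdCell(), -0.2), "positive")
  expect_error(makeGrid(stdCell(), 0.2, window = c(2, 1)), "window")
})

test_that("pixelation conserves counts and places points correctly", {
  g <- stdGrid()
  one <- pixelate(Points2D(0.05, 0.05), g)
  expect_equal(totalCounts(one), 1)
  expect_equal(sum(imageValues(one) > 0), 1L)

  cell <- stdCell()
  pts <- projectToPlane(sampleUniformSpherocylinder(cell, 10000, seed = 1))
  img <- pixelate(pts, g)
  expect_equal(totalCounts(img), 10000)
  expect_equal(clampedCount(img), 0)

  # noise-free uniform fill: all mass inside the footprint, occupancy near
  # the 10,000/75 = 133.3 of the reference settings
  expect_lt(abs(meanOccupancy(img) - 133.3) / 133.3, 0.08)

  # half-open binning: a point on a shared edge goes to the upper bin
  gEdge <- makeGrid(cell, 0.2)
  onEdge <- pixelate(Points2D(0, 0), gEdge)   # 0 is an interior bin edge
  idx <- which(imageValues(onEdge) == 1, arr.ind = TRUE)
  cx <- gridOrigin(gEdge)[1] + (idx[2] - 0.5) * pixelSize(gEdge)
  expect_gt(cx, 0)

  # out-of-grid points are clamped with a warning, totals preserved
  expect_warning(far <- pixelate(Points2D(c(0, 5), c(0, 3)), g), "clamped")
  expect_equal(totalCounts(far), 2)
  expect_equal(clampedCount(far), 1)
})

test_that("simulated reference: occupancy, depth profile, symmetry, determinism", {
  cell <- stdCell()
  g <- stdGrid()
  ref <- buildReference(cell, g, sigma = 0, nReference = 100000, seed = 11)
  expect_equal(totalCounts(ref), 100000)
  expect_lt(abs(meanOccupancy(ref) - 1333) / 1333, 0.08)

  # projection depth: central columns collect more counts than cap columns
  m <- imageValues(ref)
  colMeansMasked <- vapply(seq_len(ncol(m)), function(j) {
    keep <- gridMask(g)[, j]
    if (any(keep)) mean(m[keep, j]) else NA_real_
  }, numeric(1))
  mid <- ncol(m) / 2
  central <- mean(colMeansMasked[c(mid, mid + 1)])
  caps <- range(colMeansMasked[!is.na(colMeansMasked)])
  expect_gt(central, caps[1] * 1.5)

  # reflection symmetry within 4 Poisson sd per pixel pair (the difference
  # of two Poisson counts has sd sqrt(a+b)); allow a single tail pair out
  # of the ~45, capped at 5 sd
  flipped <- m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  z <- abs(m - flipped) / sqrt(m + flipped + 1)
  expect_lte(sum(z > 4), 2L)   # each pair appears twice in the matrix
  expect_lt(max(z), 5)

  ref2 <- buildReference(cell, g, sigma = 0, nReference = 100000, seed = 11)
  expect_identical(imageValues(ref2), m)

  # low-count references are allowed but flagged as noisy
  expect_warning(buildReference(cell, g, nReference = 500, seed = 12),
                 "noisy")
})

test_that("reference normalization is linear and total-preserving", {
  ref <- buildReference(stdCell(), stdGrid(), nReference = 50000, seed = 3)
  nr <- normalizeReference(ref, 10000)
  expect_equal(totalCounts(nr), 10000)
  expect_equal(imageValues(nr), imageValues(ref) * 10000 / 50000)
  expect_true(all(imageValues(nr) >= 0))

  ident <- normalizeReference(ref, totalCounts(ref))
  expect_equal(imageValues(ident), imageValues(ref))

  empty <- DensityImage(matrix(0, 5, 18), stdGrid())
  expect_error(normalizeReference(empty, 10), class = "mpccEmptyReferenceError")
})

test_that("empirical reference agrees with the simulated one", {
  cell <- stdCell()
  g <- stdGrid()
  sim <- buildReference(cell, g, sigma = 0, nReference = 100000, seed = 21)
  kaede <- projectToPlane(sampleUniformSpherocylinder(cell, 100000, seed = 22))
  emp <- buildEmpiricalReference(kaede, g, nTarget = 100000)
  expect_identical(referenceSource(emp), "empirical")
  expect_equal(totalCounts(emp), 100000)

  a <- imageValues(sim)[gridMask(g)]
  b <- imageValues(emp)[gridMask(g)]
  z <- abs(a - b) / sqrt(a + b + 1)
  expect_lte(sum(z > 4), 1L)   # allow one tail pixel of the ~78
  expect_lt(max(z), 5)

  single <- buildEmpiricalReference(Points2D(0.05, 0.05), g, nTarget = 42)
  expect_equal(max(imageValues(single)), 42)
  expect_equal(totalCounts(single), 42)
  expect_error(
    buildEmpiricalReference(Points2D(numeric(0), numeric(0)), g, 10),
    class = "mpccEmptyReferenceError")
})

test_that("mean occupancy follows counts linearly and needs a mask", {
  g <- stdGrid()
  img <- DensityImage(matrix(0, 5, 18), g)
  expect_equal(meanOccupancy(img), 0)

  pts <- projectToPlane(sampleUniformSpherocylinder(stdCell(), 3000, seed = 2))
  i1 <- pixelate(pts, g)
  i2 <- DensityImage(2 * imageValues(i1), g)
  expect_equal(meanOccupancy(i2), 2 * meanOccupancy(i1))

  noMask <- new("PixelGrid", pixelSize = 0.2, nRows = 2L, nCols = 2L,
                origin = c(-0.2, -0.2), mask = matrix(FALSE, 2, 2))
  expect_error(meanOccupancy(DensityImage(matrix(1, 2, 2), noMask)),
               class = "mpccEmptyMaskError")
})
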