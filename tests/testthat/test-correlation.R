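# PCC, MPCC, difference matrices, scatter pairs.

# tiny hand-checkable grid with an all-TRUE mask
flatGrid <- function(nr, nc, p = 0.2) {
  new("PixelGrid", pixelSize = p, nRows = as.integer(nr),
      nCols = as.integer(nc), origin = c(-nc * p / 2, -nr * p / 2),
      mask = matrix(TRUE, nr, nc))
}

refOn <- function(values, grid, nTarget = sum(values),
                  source = "simulated") {
  new("ReferenceMatrix", values = values * nTarget / sum(values),
      grid = grid, nTarget = nTarget, source = source,
      nSource = sum(values))
}

test_that("pcc matches the hand-evaluated formula and its edge cases", {
  g <- flatGrid(2, 2)
  R <- DensityImage(matrix(c(1, 3, 2, 4), 2, 2), g)   # rows [[1,2],[3,4]]
  G <- DensityImage(matrix(c(1, 2, 3, 4), 2, 2), g)   # rows [[1,3],[2,4]]
  expect_equal(corValue(pcc(R, G, restrictToMask = FALSE)), 0.8)

  expect_equal(corValue(pcc(R, R)), 1)

  const <- DensityImage(matrix(5, 2, 2), g)
  expect_error(pcc(const, G), class = "mpccDegenerateError")
  other <- DensityImage(matrix(1, 3, 3), flatGrid(3, 3))
  expect_error(pcc(R, other), class = "mpccGridMismatchError")
})

test_that("difference matrix has unit norm and zero sum when totals match", {
  g <- stdGrid()
  img <- pixelate(projectToPlane(
    sampleUniformSpherocylinder(stdCell(), 5000, seed = 1)), g)
  ref <- normalizeReference(
    buildReference(stdCell(), g, nReference = 50000, seed = 2), 5000)
  d <- differenceMatrix(img, ref)
  expect_equal(sqrt(sum(imageValues(d)^2)), 1, tolerance = 1e-12)
  raw <- imageValues(img) - imageValues(ref)
  expect_lt(abs(sum(raw)), 1e-9)

  # image = 2 x reference: difference proportional to the reference
  dbl <- DensityImage(2 * imageValues(ref), g)
  d2 <- differenceMatrix(dbl, ref)
  expect_true(all(imageValues(d2)[imageValues(ref) > 0] > 0))

  same <- DensityImage(imageValues(ref), g)
  expect_error(differenceMatrix(same, ref), class = "mpccDegenerateError")
})

test_that("mpcc identity, symmetry, bounds and total re-normalization", {
  cell <- stdCell()
  g <- stdGrid()
  refC <- buildReference(cell, g, nReference = 100000, seed = 5)
  img <- pixelate(projectToPlane(
    sampleUniformSpherocylinder(cell, 8000, seed = 6)), g)
  ref <- normalizeReference(refC, 8000)
  expect_equal(corValue(mpcc(img, img, ref, ref)), 1)

  img2 <- pixelate(projectToPlane(
    sampleUniformSpherocylinder(cell, 6000, seed = 7)), g)
  ref2 <- normalizeReference(refC, 6000)
  ab <- corValue(mpcc(img, img2, ref, ref2))
  ba <- corValue(mpcc(img2, img, ref2, ref))
  expect_equal(ab, ba, tolerance = 1e-12)

  # mismatched reference total is re-normalized with a warning
  expect_warning(fixed <- mpcc(img, img2, ref2, ref2), "re-normalizing")
  expect_equal(corValue(fixed), ab, tolerance = 1e-12)

  # |MPCC| <= 1 and |PCC| <= 1 on randomized inputs
  set.seed(99)
  for (i in 1:25) {
    a <- DensityImage(matrix(rpois(90, lambda = sample(1:20, 1)), 5, 18), g)
    b <- DensityImage(matrix(rpois(90, lambda = sample(1:20, 1)), 5, 18), g)
    rA <- normalizeReference(refC, totalCounts(a))
    rB <- normalizeReference(refC, totalCounts(b))
    expect_lte(abs(corValue(mpcc(a, b, rA, rB))), 1)
    expect_lte(abs(corValue(pcc(a, b))), 1)
  }
})

test_that("mpcc ignores zero padding outside the cell; unmasked pcc does not", {
  cell <- stdCell()
  g <- stdGrid()
  pair <- generateIndependent(cell, 4000, 4000, seed = 13)
  imR <- pixelate(pair$red, g)
  imG <- pixelate(pair$green, g)
  refC <- buildReference(cell, g, nReference = 100000, seed = 14)
  refR <- normalizeReference(refC, 4000)
  refG <- normalizeReference(refC, 4000)
  base <- corValue(mpcc(imR, imG, refR, refG))

  bigR <- padImage(imR, cell); bigG <- padImage(imG, cell)
  bigRefC <- padImage(DensityImage(imageValues(refC), g), cell)
  bigRefR <- normalizeReference(bigRefC, 4000)
  bigRefG <- normalizeReference(bigRefC, 4000)
  padded <- corValue(mpcc(bigR, bigG, bigRefR, bigRefG))
  expect_lt(abs(padded - base), 1e-9)

  pccTight <- corValue(pcc(imR, imG, restrictToMask = FALSE))
  pccPad <- corValue(pcc(bigR, bigG, restrictToMask = FALSE))
  expect_gt(abs(pccPad - pccTight), 1e-3)  # padding inflates unmasked PCC
})

test_that("mpcc with a constant masked reference equals masked pcc", {
  cell <- stdCell()
  g <- stdGrid()
  mask <- gridMask(g)
  np <- sum(mask)
  # images supported on the mask only
  mk <- function(seed, n) {
    set.seed(seed)
    m <- matrix(0, 5, 18)
    m[mask] <- rpois(np, n / np)
    DensityImage(m, g)
  }
  imR <- mk(31, 9000); imG <- mk(32, 9000)
  constRef <- function(total) {
    v <- matrix(0, 5, 18); v[mask] <- total / np
    new("ReferenceMatrix", values = v, grid = g, nTarget = total,
        source = "simulated", nSource = np)
  }
  got <- corValue(mpcc(imR, imG, constRef(totalCounts(imR)),
                       constRef(totalCounts(imG))))
  want <- corValue(pcc(imR, imG, restrictToMask = TRUE))
  expect_lt(abs(got - want), 1e-9)
})

test_that("mpcc is invariant to a common positive scaling (widefield mode)", {
  cell <- stdCell()
  g <- stdGrid()
  pair <- generateIndependent(cell, 5000, 5000, seed = 41)
  imR <- pixelate(pair$red, g); imG <- pixelate(pair$green, g)
  refC <- buildReference(cell, g, nReference = 100000, seed = 42)
  base <- corValue(mpcc(imR, imG, normalizeReference(refC, 5000),
                        normalizeReference(refC, 5000)))
  k <- 0.0375  # e.g. photons-per-molecule calibration factor
  sR <- DensityImage(k * imageValues(imR), g)
  sG <- DensityImage(k * imageValues(imG), g)
  scaled <- corValue(mpcc(sR, sG, normalizeReference(refC, k * 5000),
                          normalizeReference(refC, k * 5000)))
  expect_equal(scaled, base, tolerance = 1e-9)
})

test_that("scatter pairs enumerate pixels row-major and reconstruct the MPCC", {
  cell <- stdCell()
  g <- stdGrid()
  pair <- generateCaseI(cell, 12000, seed = 51)
  imR <- pixelate(projectToPlane(pair$red), g)
  imG <- pixelate(projectToPlane(pair$green), g)
  refC <- buildReference(cell, g, nReference = 100000, seed = 52)
  refR <- normalizeReference(refC, totalCounts(imR))
  refG <- normalizeReference(refC, totalCounts(imG))
  dR <- differenceMatrix(imR, refR)
  dG <- differenceMatrix(imG, refG)
  sp <- scatterPairs(dR, dG)
  expect_equal(nrow(sp), prod(gridDim(g)))
  expect_equal(sp$red[1:18], imageValues(dR)[1, ])  # row-major order
  m <- corValue(mpcc(imR, imG, refR, refG))
  expect_equal(sum(sp$red * sp$green), m, tolerance = 1e-12)
  # anti-correlated construction: negative sample correlation of elements
  expect_lt(cor(sp$red, sp$green), 0)
})
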