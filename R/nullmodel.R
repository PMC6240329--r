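# Monte-Carlo calibration of the MPCC: null distribution under independent
# random fills, Gaussian fit, p-values, and the pixel-size and occupancy
# diagnostic sweeps.

#' Monte-Carlo MPCC null distribution
#'
#' Repeatedly scores pairs of independent uniform random fills of the cell
#' (with channel localization errors, projection and pixelation) with the
#' MPCC, against reference matrices built once per settings and reused
#' across trials (so reference noise does not inflate the trial-to-trial
#' variance). A Gaussian is fitted to the samples by sample mean and
#' standard deviation.
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param pixelSize pixel edge, micrometers.
#' @param nRed,nGreen molecules per channel per trial.
#' @param sigmaRed,sigmaGreen localization error sigma per channel,
#'   micrometers.
#' @param nTrials number of Monte-Carlo trials (>= 2; default 200).
#' @param nReference molecules in the simulated reference (default 100,000).
#' @param seed optional integer seed covering the whole computation.
#' @return a \linkS4class{NullDistribution}.
#' @export
nullDistribution <- function(geom, pixelSize, nRed, nGreen, sigmaRed = 0,
                             sigmaGreen = 0, nTrials = 200L,
                             nReference = 100000L, seed = NULL) {
  if (nTrials < 2)
    .mpccStop("nTrials must be at least 2", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  grid <- makeGrid(geom, pixelSize)
  refR <- normalizeReference(
    buildReference(geom, grid, sigmaRed, nReference, channel = "red"), nRed)
  refG <- normalizeReference(
    buildReference(geom, grid, sigmaGreen, nReference, channel = "green"),
    nGreen)
  samples <- vapply(seq_len(nTrials), function(i) {
    pr <- generateIndependent(geom, nRed, nGreen, sigmaRed, sigmaGreen)
    imR <- suppressWarnings(pixelate(pr$red, grid))
    imG <- suppressWarnings(pixelate(pr$green, grid))
    corValue(mpcc(imR, imG, refR, refG))
  }, numeric(1))
  fit <- fitGaussian(samples)
  new("NullDistribution", samples = samples, nTrials = as.integer(nTrials),
      fittedMean = fit$mean, fittedSigma = fit$sigma,
      settings = list(length = cellLength(geom), radius = cellRadius(geom),
                      pixelSize = pixelSize, nRed = nRed, nGreen = nGreen,
                      sigmaRed = sigmaRed, sigmaGreen = sigmaGreen,
                      nReference = nReference, seed = seed,
                      nPixelsMasked = maskedPixelCount(grid)))
}

#' Gaussian fit to a sample of statistic values
#'
#' Maximum-likelihood normal fit: sample mean and sample standard deviation
#' (1/(n-1) denominator). For Gaussian data this is equivalent to a
#' least-squares fit to the histogram but free of bin-width choices.
#'
#' @param samples numeric vector (>= 2 values, non-constant).
#' @return list with \code{mean} and \code{sigma}.
#' @export
fitGaussian <- function(samples) {
  if (length(samples) < 2L)
    .mpccStop("need at least 2 samples to fit", "mpccArgumentError")
  s <- stats::sd(samples)
  if (s == 0)
    .mpccStop("constant samples: Gaussian fit is degenerate",
              "mpccDegenerateError")
  list(mean = mean(samples), sigma = s)
}

#' Two-sided Gaussian p-value for an observed MPCC
#'
#' Probability that the uncorrelated-random null would produce an MPCC of
#' magnitude \code{|observed - mean|} or larger on either side of the
#' Gaussian: \eqn{p = 2(1 - \Phi(|obs - mean| / \sigma))}. The default
#' centers the null at 0, since the Monte-Carlo null is symmetric about
#' zero by construction; pass \code{mean = fittedMean(null)} to center at
#' the fitted mean instead.
#'
#' @param observed the measured MPCC.
#' @param sigma null standard deviation (> 0), e.g.
#'   \code{fittedSigma(null)}.
#' @param mean null center (default 0).
#' @return two-sided tail probability.
#' @examples
#' pValue(0.10, 0.13)  # 0.44
#' @export
pValue <- function(observed, sigma, mean = 0) {
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    .mpccStop("sigma must be a single positive value", "mpccArgumentError")
  2 * stats::pnorm(abs(observed - mean) / sigma, lower.tail = FALSE)
}

#' Empirical-quantile p-value from the Monte-Carlo samples
#'
#' Fraction of null samples at least as extreme (in magnitude) as the
#' observation, with the +1 add-one correction. Unlike the Gaussian tail it
#' makes no distributional assumption, but it is floored at
#' 1/(nTrials + 1), so far-tail significance still relies on the Gaussian
#' extrapolation.
#'
#' @param observed the measured MPCC.
#' @param samples Monte-Carlo null samples (or a
#'   \linkS4class{NullDistribution}).
#' @return empirical two-sided p-value.
#' @export
empiricalPValue <- function(observed, samples) {
  if (is(samples, "NullDistribution")) samples <- nullSamples(samples)
  (1 + sum(abs(samples) >= abs(observed))) / (length(samples) + 1)
}

#' Null width as a function of pixel size
#'
#' Runs one Monte-Carlo null per pixel size and tabulates the fitted width
#' against the in-cell pixel count \eqn{N_p}. For uncorrelated random
#' fills the width scales as \eqn{N_p^{-1/2}}, so finer pixelation gives
#' tighter significance thresholds (until sparseness bias intervenes for
#' structured images).
#'
#' @param geom a \linkS4class{Spherocylinder}.
#' @param pixelSizes numeric vector of pixel edges, micrometers (>= 1).
#' @param nRed,nGreen molecules per channel per trial.
#' @param sigmaRed,sigmaGreen localization sigmas, micrometers.
#' @param nTrialsEach Monte-Carlo trials per pixel size.
#' @param nReference reference molecules.
#' @param seed optional integer seed.
#' @return data.frame with one row per pixel size: \code{pixel_size},
#'   \code{n_pixels_masked}, \code{mean_occupancy}, \code{statistic_mean},
#'   \code{statistic_sd}, \code{n_replicates}.
#' @export
pixelSizeSweep <- function(geom, pixelSizes, nRed, nGreen, sigmaRed = 0,
                           sigmaGreen = 0, nTrialsEach = 100L,
                           nReference = 100000L, seed = NULL) {
  if (length(pixelSizes) < 1L)
    .mpccStop("need at least one pixel size", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(pixelSizes, function(p) {
    nd <- nullDistribution(geom, p, nRed, nGreen, sigmaRed, sigmaGreen,
                           nTrials = nTrialsEach, nReference = nReference)
    np <- nd@settings$nPixelsMasked
    data.frame(pixel_size = p, n_pixels_masked = np,
               mean_occupancy = (nRed + nGreen) / 2 / np,
               statistic_mean = fittedMean(nd), statistic_sd = fittedSigma(nd),
               n_replicates = nTrialsEach)
  })
  do.call(rbind, rows)
}

#' MPCC convergence vs occupancy by random deletion
#'
#' At fixed pixel size, the mean occupancy per pixel is reduced by deleting
#' molecules uniformly at random (without replacement, independently per
#' channel and replicate); references are re-normalized to the reduced
#' totals and the MPCC recomputed. Sparse images bias |MPCC| toward zero,
#' so the sweep shows how many molecules per pixel a trustworthy estimate
#' needs.
#'
#' @param pointsR,pointsG \linkS4class{Points2D} localizations per channel.
#' @param grid the \linkS4class{PixelGrid} to bin on.
#' @param refCountsR,refCountsG raw (unnormalized) reference
#'   \linkS4class{DensityImage}s for the two channels.
#' @param keepFractions fractions of molecules to keep, each in (0, 1].
#' @param nReplicates random-deletion replicates per fraction.
#' @param seed optional integer seed.
#' @return data.frame with one row per keep fraction: \code{keep_fraction},
#'   \code{n_pixels_masked}, \code{mean_occupancy} (per-channel average),
#'   \code{statistic_mean}, \code{statistic_sd}, \code{n_replicates}.
#' @export
occupancySweep <- function(pointsR, pointsG, grid, refCountsR, refCountsG,
                           keepFractions, nReplicates = 20L, seed = NULL) {
  if (any(keepFractions <= 0 | keepFractions > 1))
    .mpccStop("keepFractions must lie in (0, 1]", "mpccArgumentError")
  if (!is.null(seed)) set.seed(seed)
  nR <- nPoints(pointsR); nG <- nPoints(pointsG)
  np <- maskedPixelCount(grid)
  rows <- lapply(keepFractions, function(f) {
    kR <- round(f * nR); kG <- round(f * nG)
    if (kR < 1 || kG < 1)
      .mpccStop(sprintf("keep fraction %.3g leaves no molecules", f),
                "mpccArgumentError")
    vals <- vapply(seq_len(nReplicates), function(i) {
      iR <- if (kR == nR) seq_len(nR) else sample.int(nR, kR)
      iG <- if (kG == nG) seq_len(nG) else sample.int(nG, kG)
      imR <- suppressWarnings(pixelate(
        Points2D(pointsR@x[iR], pointsR@y[iR], channel = pointsR@channel,
                 locSigma = pointsR@locSigma), grid))
      imG <- suppressWarnings(pixelate(
        Points2D(pointsG@x[iG], pointsG@y[iG], channel = pointsG@channel,
                 locSigma = pointsG@locSigma), grid))
      corValue(mpcc(imR, imG, normalizeReference(refCountsR, kR),
                    normalizeReference(refCountsG, kG)))
    }, numeric(1))
    data.frame(keep_fraction = f, n_pixels_masked = np,
               mean_occupancy = (kR + kG) / 2 / np,
               statistic_mean = mean(vals),
               statistic_sd = if (nReplicates > 1) stats::sd(vals) else NA_real_,
               n_replicates = nReplicates)
  })
  do.call(rbind, rows)
}
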