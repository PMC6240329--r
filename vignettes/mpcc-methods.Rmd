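---
title: "Colocalization in spherocylindrical cells: the modified Pearson correlation coefficient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colocalization in spherocylindrical cells: the modified Pearson correlation coefficient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpcc)
```

## The problem

Two-color fluorescence microscopy of bacteria asks whether a red-labelled
and a green-labelled species co-locate, avoid each other, or ignore each
other. Under epi-illumination the microscope integrates fluorescence along
the optical (z) axis, so the camera records a 2D projection of a 3D
distribution. For a rod-shaped cell — modelled here as a spherocylinder of
tip-to-tip length $L$ and radius $r$ — a distribution that is perfectly
random in 3D does **not** project to a uniform 2D image: pixels over the
cell midline integrate a chord of length up to $2r$, while pixels near the
edges and the hemispherical endcaps integrate much less. The projected
intensity varies several-fold across the footprint, and it does so
systematically.

The standard Pearson correlation coefficient of two images $\mathbf R$,
$\mathbf G$,

$$\mathrm{PCC} = \frac{\sum_{ij} (R_{ij} - \bar R)(G_{ij} - \bar G)}
{\sqrt{\sum_{ij} (R_{ij} - \bar R)^2}\,\sqrt{\sum_{ij} (G_{ij} - \bar G)^2}},$$

compares each image to a *constant* reference $\bar R$. In a
spherocylinder both channels share the same systematic projection profile:
central pixels sit above their channel mean and peripheral pixels below
it, in both channels at once, so the products in the numerator are
systematically positive. Two *independent* random 3D fills therefore
produce PCC close to +1 (we measure about +0.96 over the in-cell pixels at
the reference settings below), and a perfectly anti-correlated pair is
dragged from $-1$ up to roughly $-0.5$. The statistic fails before the
biology is even consulted.

## The modified coefficient

The fix is to compare each image to the reference it actually deviates
from: the pixelated 2D projection $\tilde{\mathbf U}$ of a very large
uniform random fill of the same cell volume, rescaled so its total equals
the number of molecules imaged in that channel,

$$\tilde U^R_{ij} = U_{ij} \times N_R / N_{\mathrm{ref}},$$

with $N_{\mathrm{ref}} = 100{,}000$ simulated molecules by default. Each
difference matrix $\Delta^R = \mathbf R - \tilde{\mathbf U}^R$ is scaled
to unit Frobenius norm, $\hat\Delta^R = \Delta^R / \lVert \Delta^R
\rVert$, and the modified Pearson correlation coefficient is the Frobenius
inner product

$$\mathrm{MPCC} = \sum_{ij} \hat\Delta^R_{ij}\, \hat\Delta^G_{ij}
\in [-1, +1].$$

Because the reference carries the projection profile, deviations from it
are free of the shared systematic component: independent random fills
score 0 on average, and the perfectly anti- and positively correlated
constructions recover $-1$ and $+1$. Pixels outside the cell are zero in
both the image and the reference, contribute nothing to any sum, and so
the MPCC is invariant to empty margins around the cell — the
zero-inflation artifact that plagues the PCC cannot occur. For that reason
`mpcc()` always evaluates the full matrix, while `pcc()` defaults to the
in-cell pixel mask and exposes `restrictToMask = FALSE` to demonstrate the
artifact.

## Model and parameters

- **Geometry** (`Spherocylinder`): tip-to-tip length `length` and
  `radius`, in micrometers. The validation conditions used throughout the
  package are $L = 3.5\ \mu m$, $2r = 0.82\ \mu m$ — a typical
  exponentially growing *E. coli* cell. The long axis is x, the origin is
  the cell center, z is optical.
- **Sampling** (`sampleUniformSpherocylinder`): rejection sampling from
  the bounding box $[-L/2, L/2] \times [-r, r]^2$. Acceptance equals the
  volume fraction (about 72% at the reference geometry), the draw is
  exactly uniform, and boundary points count as inside (a closed surface
  is a deterministic, measure-zero choice).
- **Localization error** (`applyLocalizationError`): zero-mean Gaussian
  noise of standard deviation $\sigma$ applied independently in x and y —
  the planar localization uncertainty of single-molecule imaging
  (typically 20–60 nm). z is untouched and noisy positions falling outside
  the footprint are *kept*: they are measured positions. The validation
  null uses $\sigma_R = \sigma_G = 50$ nm; the anti- and
  positively-correlated generators default to $\sigma = 0$ (noise is
  configurable but unnecessary for those constructions).
- **Pixelation** (`makeGrid`, `pixelate`): square pixels (default 200 nm)
  on a grid covering the footprint bounding box, centered on the cell;
  bins are half-open `[edge, edge + p)`. A pixel is "in-cell" when its
  center lies inside the stadium footprint; at the reference settings this
  yields 78 in-cell pixels (the count is convention-dependent — any
  reasonable rule gives 70–80). Localizations that noise pushes outside
  the grid are clamped to the nearest edge pixel (with a warning and a
  counter) so channel totals are conserved, as the reference
  normalization requires. An optional `window` argument enlarges the grid
  to a camera region of interest.
- **Reference** (`buildReference`, `normalizeReference`): 100,000
  molecules by default, i.e. about 1300 molecules per 200 nm pixel, so
  reference shot noise is negligible against image shot noise. The
  reference is built **once** per settings and re-normalized per image;
  re-normalizing one high-count reference (rather than simulating one per
  trial) keeps reference noise out of the trial-to-trial variance of the
  null. `buildEmpiricalReference` accepts measured localizations of a
  freely diffusing fluorophore instead — useful when the 3D shape is hard
  to model — and agrees with the simulated reference to within counting
  noise at comparable totals.
- **Widefield mode**: all operations accept non-integer intensity
  matrices (background-subtracted photon counts). The MPCC is invariant
  under a common positive rescaling of an image and its reference, so the
  photon-per-molecule calibration factor drops out.

## Significance calibration

`nullDistribution()` scores pairs of independent uniform fills — same
molecule counts, localization errors and pixel size as the data — with
the MPCC. 200 trials at the reference settings give a null that is
symmetric about zero with fitted $\sigma_{\mathrm{MPCC}} \approx 0.12$.
The Gaussian is fitted by sample mean and standard deviation (the maximum
likelihood estimate); a least-squares fit to a histogram is equivalent
for Gaussian data but introduces a bin-width choice, so it is not used.

`pValue(obs, sigma)` returns the two-sided tail
$p = 2\,(1 - \Phi(|obs - \mu|/\sigma))$ with $\mu = 0$ by default: the
null is centered at zero by construction, and the reference checks
(0.10, 0.13) → 0.44, (0.39, 0.061) → 1.6×10⁻¹⁰, (0.25, 0.033) →
3.6×10⁻¹⁴ back-compute from exactly this formula. Centering at the
fitted mean is available via the `mean` argument.
`empiricalPValue()` reports the add-one-corrected fraction of null
samples at least as extreme; it is assumption-free but floored at
$1/(n_{\mathrm{trials}}+1)$, so far-tail claims still rest on the
Gaussian extrapolation.

Two diagnostic sweeps guide the pixel-size choice:

- `pixelSizeSweep()`: the null width scales as $N_p^{-1/2}$ in the
  in-cell pixel count $N_p$ (log–log slope $-0.5$, holding even at 500
  molecules per channel), so finer pixels give tighter significance
  thresholds for *random* images.
- `occupancySweep()`: for *structured* images, sparseness biases |MPCC|
  toward zero — empty and near-empty pixels in the two channels start to
  correlate spuriously. Deleting molecules at random from the
  anti-correlated construction shows the bias directly: at a mean
  occupancy of ~7 molecules per in-cell pixel the recovered MPCC is about
  $-0.9$ rather than $-0.99$, converging to the asymptote as occupancy
  grows. Working above ~7 molecules/pixel (more for weakly structured
  images) and choosing the smallest pixel that keeps a simulated
  perfectly-correlated control near its asymptote is the recommended
  practice.

## Evaluating the standard PCC: a caution on image extent

The PCC — unlike the MPCC — depends on which pixels enter the sums. Three
conventions appear in practice: the in-cell mask, the tight bounding box,
and the camera window with its empty margin. For the perfectly
anti-correlated left/right construction at the reference settings these
give about $-0.69$, $-0.59$ and $-0.50$ (4×1 µm window) respectively, and
$+0.96$ to $+0.98$ for independent random fills; published values for
such constructions are reproduced by the camera-window convention, which
is how acquired images are usually fed to PCC software. The package
defaults `pcc()` to the in-cell mask — the only convention with a
defensible definition of "the image of the cell" — and the acceptance
checks of the window convention construct the window explicitly with
`makeGrid(geom, p, window = c(4, 1))`. None of this ambiguity affects the
MPCC, which is the point of using it.

## Synthetic validation patterns

`generateCaseI` (left half red, right half green, binomial split of one
uniform fill), `generateCaseII` (endcaps vs center, equal-volume split at
the volume median of $|x|$ by default, override via `xSplit`),
`generateCaseIII` (leftmost 2/3 of the volume vs rightmost 1/3, boundary
located by root-finding on the closed-form cumulative axial volume to
$10^{-6} L$) are perfectly anti-correlated constructions with disjoint
supports; all three score MPCC $\approx -0.99$ at 10,000 molecules per
channel and 200 nm pixels. `generateCorrelated` (two *independent* fills,
each keeping its left half) scores $+0.99$. `generateIndependent` is the
null construction. Region boundaries assign boundary points to the
right/central region — deterministic and measure-zero. Sub-region fills
re-use the whole-cell sampler under a region predicate, so uniformity
within regions is inherited, not re-derived.

What the generators deliberately do not emulate: cell-to-cell shape
variation, clustered (non-Poisson) molecule placement, membrane vs
cytoplasm compartments, drift or channel mis-registration, and the
irregular, non-axially-symmetric nucleoid shapes of real cells. Passing
the validation suite therefore demonstrates the statistic's behaviour
under its own model assumptions, not that a particular experimental MPCC
is unbiased.

## Numerical choices

- All computations in double precision; at $\le 10^5$ pixels plain
  accumulation is accurate to well below the $10^{-9}$ tolerances the
  tests assert; unit Frobenius norms are verified to $10^{-9}$.
- Degenerate inputs (constant image in PCC, image equal to its reference
  in MPCC, constant null samples) raise typed errors
  (`mpccDegenerateError`) rather than returning NaN: silent NaN
  propagation hides misconfiguration.
- A reference whose total differs from its image's total is re-normalized
  with a warning rather than rejected.
- Reproducibility: every stochastic entry point takes an optional `seed`;
  inner draws consume the stream sequentially, so one seed fixes an
  entire pipeline bit-exactly.

## Problem sizes in the test suite

The suite regenerates everything programmatically: 20-seed batches at the
full validation scale (20,000-molecule fills, 100,000-molecule
references) for the headline coefficients, a 200-trial null for the
width calibration, 80-trial nulls per pixel size for the scaling law, and
50,000-point draws for the sampler uniformity checks — a few minutes in
total on one core. These sizes reproduce every asserted quantity at its
stated tolerance; enlarging them tightens nothing but the runtime.

## Known limitations

- A 2D MPCC near zero does not rule out 3D structure: projection loses
  information, and 3D-correlated distributions generally project to
  *less* correlated images.
- The spherocylinder is an idealization; for strongly curved or irregular
  cells, build the reference empirically from a freely diffusing
  fluorophore (`buildEmpiricalReference`).
- The Gaussian tail p-value at many sigma is an extrapolation; the
  empirical p-value is reported alongside it for honesty about that.
- Composite (multi-cell) images must already be registered into a common
  cell frame; the package does no segmentation or alignment.
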