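# mpcc — modified Pearson correlation for two-color imaging of rod-shaped cells

`mpcc` quantifies colocalization between two fluorescence channels in
spherocylindrical bacterial cells (*E. coli*, *B. subtilis*, ...). It is
aimed at single-molecule localization microscopy (lists of x,y molecule
positions per channel) but works equally on background-subtracted
widefield intensity images.

## Why the standard PCC fails here

Epi-illumination projects the 3D fluorophore distribution along the
optical axis. In a spherocylinder of length *L* and radius *r*, a pixel
over the midline integrates a chord of up to 2*r* of cytoplasm while
pixels near the edges and endcaps integrate far less — so even a
*random* 3D distribution projects to a strongly non-uniform 2D image.
The standard Pearson correlation coefficient,

    PCC = Σ (R_ij − R̄)(G_ij − Ḡ) / (‖R − R̄‖ ‖G − Ḡ‖),

compares each image to its constant mean, and the shared projection
profile pushes both channels above the mean in the center and below it
at the periphery simultaneously: two completely independent
distributions score PCC ≈ +0.96, and a perfectly anti-correlated pair is
dragged from −1 up to about −0.5.

The **modified PCC** replaces the constant mean with the proper
reference: the pixelated projection **Ũ** of a large (default 100,000
molecule) uniform random fill of the same cell geometry, rescaled to the
channel's molecule count (Ũ<sup>R</sup> = U · N_R / N_ref). With
difference matrices Δ<sup>R</sup> = R − Ũ<sup>R</sup> scaled to unit
Frobenius norm,

    MPCC = Σ_ij Δ̂^R_ij Δ̂^G_ij  ∈ [−1, +1],

which restores 0 for independent distributions, ±1 for perfectly
(anti-)correlated ones, and is provably insensitive to empty pixels
outside the cell.

## Worked example

Two independent random channels of 10,000 molecules each (50 nm
localization error) in a 3.5 × 0.82 µm cell, 200 nm pixels:

```r
library(mpcc)

cell <- Spherocylinder(length = 3.5, diameter = 0.82)
grid <- makeGrid(cell, 0.2)
grid
#> PixelGrid: 5 x 18 pixels of 0.2 um (78 in-cell pixels)

ref  <- buildReference(cell, grid, sigma = 0.05, nReference = 100000, seed = 1)
pair <- generateIndependent(cell, 10000, 10000,
                            sigmaRed = 0.05, sigmaGreen = 0.05, seed = 2)
imR <- pixelate(pair$red, grid)
imG <- pixelate(pair$green, grid)

mpcc(imR, imG, normalizeReference(ref, totalCounts(imR)),
               normalizeReference(ref, totalCounts(imG)))
#> MPCC = +0.1117
#>   n_red = 10000, n_green = 10000, pixel 0.2 um, 78 in-cell pixels
#>   mean occupancy/pixel: red 128, green 128

pcc(imR, imG)
#> PCC = +0.9677
```

The PCC reports near-perfect correlation for molecules that ignore each
other; the MPCC reports +0.11. Is +0.11 significant? Calibrate against
the Monte-Carlo null (independent fills at the same settings):

```r
nd <- nullDistribution(cell, 0.2, 10000, 10000, 0.05, 0.05,
                       nTrials = 200, nReference = 100000, seed = 3)
nd
#> NullDistribution: 200 trials, fitted mean +0.01283, sigma 0.1208

pValue(0.1117, fittedSigma(nd))
#> [1] 0.3549433
empiricalPValue(0.1117, nd)
#> [1] 0.3880597
```

p ≈ 0.35: an MPCC of that size arises by chance about one time in three —
correctly not significant. The anti-correlated and correlated
constructions (`generateCaseI/II/III`, `generateCorrelated`) score −0.99
and +0.99 at these settings, and `pixelSizeSweep()` /
`occupancySweep()` diagnose the pixel-size and molecules-per-pixel
choices (the null width scales as N_p^(−1/2); below ~7 molecules per
in-cell pixel, sparse-image bias shrinks |MPCC| toward zero).

A command-line front end wrapping the same functions is installed at
`system.file("exec", "mpcc-tool", package = "mpcc")` with subcommands
`simulate`, `pixelate`, `pcc`, `mpcc`, `null`, `sweep`; localization
tables and matrices are plain TSV, reports are JSON.

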