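---
title: "Logarithmic Mueller matrix decomposition and whole-image collagen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logarithmic Mueller matrix decomposition and whole-image collagen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and the model

A transmission Mueller matrix image assigns to every pixel a real 4x4
matrix $M$ describing how the sample transforms the polarization state of
light; $M_{00}$ is the total transmittance.  For a thin slab that is
homogeneous along the beam, $M$ obeys $dM/dz = m\,M$ for a constant
differential matrix $m$, so the accumulated matrix is a matrix
exponential and the decomposition task is a per-pixel principal matrix
logarithm, $L = \ln M$.

The Minkowski metric $G = \mathrm{diag}(1,-1,-1,-1)$ splits $L$ exactly
into two parts of opposite $G$-symmetry,

$$L_m = \tfrac12\,(L - G L^T G), \qquad L_u = \tfrac12\,(L + G L^T G),$$

where $L_m$ (G-antisymmetric) carries the mean polarization properties —
linear $(x\!-\!y)$ and $(\pm 45^\circ)$ dichroism $p_1,p_2$, circular
dichroism $p_3$, linear retardances $p_4,p_5$, circular retardance $p_6$
— and $L_u$ (G-symmetric) carries the isotropic attenuation $d_0 = \ln
M_{00}$ and the depolarization coefficients $d_1..d_9$.  For a
fluctuating medium the mean properties accumulate linearly with thickness
$z$ while their variances, i.e. the depolarization, accumulate
quadratically.

The collagen-scoring maps are derived per pixel:

* **total linear retardance** $R_L = \sqrt{p_4^2 + p_5^2}$ (rad),
  invariant under in-plane sample rotation — a proxy for the density of
  aligned collagen fibers via form birefringence;
* **azimuth** $\theta = \tfrac12\,\mathrm{atan2}(p_5, p_4)$, the in-plane
  optical-axis orientation, an axial quantity with a $180^\circ$ period
  tracking the local fiber direction;
* **linear depolarization** $\alpha_{22}$, the attenuation-free linear
  $(x\!-\!y)$ diagonal element of $L_u$: zero for a non-depolarizing
  sample, increasingly negative with stronger depolarization.

On the $\alpha_{22}$ convention: the $(1,1)$ diagonal slot of $L_u$ is
$d_0 - d_7$, which mixes the isotropic attenuation $d_0$ into the
depolarization readout.  The package reports $\alpha_{22} = -d_7 =
L_u[1,1] - L_u[0,0]$ (0-based indices), i.e. the same element after
removing $d_0$ — equivalently the $(1,1)$ element of the logarithm of the
$M_{00}$-normalized matrix.  Only this attenuation-free form scales
quadratically with thickness, sits on the $\sim -0.01$ scale observed in
50-micron tissue sections, and vanishes for a purely attenuating,
non-depolarizing sample; with $d_0$ left in, the readout would be
dominated by $\ln M_{00} \approx -1$ and the thickness-normalization
ratios below would not cancel.

The reported quantities are thickness-accumulated (the differential
densities integrated over the section), not per-unit-length: no division
by a physical thickness is performed, since the local thickness is
exactly the nuisance the fusion step cancels.

## Thickness normalization and fusion

Sectioning leaves residual thickness fluctuations that modulate every
accumulated map.  With $R_L = A z$, $\alpha_{22} = -B z^2$ and the
Beer–Lambert relation $\ln M_{00} = -\mu_T z$, the pixel-wise ratios

$$\frac{R_L}{|\ln M_{00}|} = \frac{A}{\mu_T}, \qquad
  \frac{\ln^2 M_{00}}{\alpha_{22}} = -\frac{\mu_T^2}{B}, \qquad
  \frac{\alpha_{22}}{R_L^2} = -\frac{B}{A^2}$$

depend only on the local optical densities.  Division guards (`eps_ln =
1e-3`, `eps_alpha = 1e-5`, `eps_R = 1e-4` rad) mask pixels whose
denominator is numerically meaningless — transparent pixels, pure
retarders, vanishing retardance — rather than raising errors; masked
pixels are reported in the guard mask.  The guard defaults are set well
below the tissue scale of each quantity (three orders of magnitude below
typical $|\ln M_{00}| \approx 1$, an order below the $10^{-4}$ retardance
noise floor), so on realistic data they only remove pixels that carry no
usable ratio.

## Matrix logarithm: numerical choices

The per-pixel logarithm uses complex eigendecomposition with the
principal branch, implemented in compiled code.  The logarithm is
realified by discarding the imaginary component; its maximum magnitude is
recorded per pixel and compared against `tol_imag` (default `1e-6` for
noiseless synthetic input, `1e-2` recommended for measured data, where
noise pushes eigenvalues slightly complex).  A pixel is invalidated — with
a recorded cause, never an exception — when $M_{00}$ is at or below the
transmittance floor (`1e-4`), when an eigenvalue has zero modulus or lies
on the closed negative real axis (no principal logarithm), when the
eigenvector basis is numerically singular, or when the discarded
imaginary magnitude exceeds `tol_imag`.  Only an image with *no* valid
pixel raises an error, which then reports the histogram of causes.

## Whole-image scoring

All statistics are computed over every decomposition-valid pixel of the
image, with no region-of-interest selection; this makes the score
operator-independent and is why the statistics must cope with the large
zero-retardance background population (canal, fornix, glass).  Scoring
depends only on the multiset of valid pixel values, never on pixel
positions.

* **Moments** — mean, population standard deviation (1/n normalization;
  images provide $n \gg 30$), skewness $m_3/m_2^{3/2}$ and *excess*
  kurtosis $m_4/m_2^2 - 3$.  The excess convention is the one consistent
  with reported tissue values (retardance kurtosis of order 1 alongside
  skewness of order 1); a flag switches to raw kurtosis for comparisons.
* **Two-Gaussian fits** — the density histogram (default 100 bins over
  the data range; density rather than counts, so bin width does not
  rescale amplitudes) is fit with $a_1 e^{-(x-c_1)^2/2\sigma_1^2} + a_2
  e^{-(x-c_2)^2/2\sigma_2^2}$ by bounded Levenberg–Marquardt.
  Initialization is deterministic: centers at the 25th/75th pixel
  percentiles, widths at half the interquartile range, amplitudes at the
  densities nearest the initial centers; centers are bounded to the data
  range, widths to `[bin_width/2, range]`, amplitudes to `[0, Inf)`.
  Components are reordered so $c_1 \le c_2$; near-coincident centers
  ($|c_2 - c_1| < \max\sigma/2$) raise a degeneracy flag, and
  non-convergence is flagged rather than raised.  The second component
  tracks the aligned-collagen pixel population; its center is the
  headline remodeling score.  Depolarization histograms are fit on raw
  (negative) $\alpha_{22}$, preserving the "0 = no depolarization"
  anchor.
* **Circular azimuth statistics** — axial angles are doubled onto the
  full circle, trigonometric moments give the resultant length, circular
  variance, skewness and kurtosis, and the mean direction is mapped back
  to $[0, 180)$.  These are computed for completeness and as a negative
  control: a circumferential fiber ring covers all orientations exactly
  as uniformly as random fibers do, so whole-image azimuth statistics are
  expected *not* to separate ordered from remodeled tissue.

## What the phantom generator emulates

No raw images are distributed with the instrument study this pipeline
addresses, so validation runs on a synthetic phantom whose structure
carries the features the analysis depends on:

* **anatomy** — nested regions of a transverse cervix cross-section: an
  X-shaped cervical canal (two crossed rectangles at $\pm 45^\circ$; only
  the nested-zone topology matters to whole-image statistics, not lumen
  fidelity), subepithelial stroma, a midstroma ring, fornix lobes, and an
  opaque background annulus outside the section;
* **optics** — per-region densities $A$ (retardance, rad/z), $\mu_T$
  (attenuation, 1/z), $B$ (depolarization, 1/z²), composed through the
  differential-matrix forward model $M = \exp[(m_m + d_0 I)z + (m_u - d_0
  I)z^2]$, which realizes the linear/quadratic accumulation laws exactly
  rather than by stacking random layers (exactness and speed; a
  Monte-Carlo layer stack would only add sampling noise around the same
  limit);
* **alignment** — a "day 6" preset with circumferentially aligned stroma
  (azimuth concentrated around the ring tangent, von-Mises-like
  concentration 8) and a "day 18" preset with fully random orientation
  (concentration 0, smooth angle field with a 2-pixel correlation length
  — fine-grained disorder chosen so the orientation marginal is
  effectively uniform at whole-image scale);
* **remodeling** — day 18 reduces the retardance densities (0.12 to 0.07
  rad/z in the midstroma, 0.05 to 0.03 in the subepithelial stroma) and
  makes them *patchy* (multiplicative smooth field, coefficient of
  variation 0.6 vs 0.15 at day 6, clipped at zero).  The patchiness is a
  modeling choice worth stating: a pure rescaling of $A$ cannot change
  the shape of the retardance distribution (skewness and kurtosis are
  scale-invariant), while remodeling that dissolves the aligned ring
  unevenly both lowers the mean and skews the distribution towards the
  zero-retardance population — the direction reported for late-gestation
  tissue.  The canal epithelium depolarizes more strongly at day 18
  (B 0.045 vs 0.030);
* **nuisance** — a smooth thickness field ($z_0 = 1$, 15% fluctuation,
  correlation length 10% of the image) exercising the fusion ratios, and
  additive Gaussian noise of 0.005 relative to $M_{00}$ on all sixteen
  coefficients.

Defaults put the noiseless day-6 whole-image retardance mean in the
0.05–0.07 rad regime and $\alpha_{22}$ near $-0.013$, the scales reported
for real 50-micron sections; $\mu_T$ and $B$ at 533 nm are not available
from the study and are order-of-magnitude choices constrained by that
$\alpha_{22}$ scale.  A cohort generator emulates the study design (five
day-6 and three day-18 animals) with per-animal geometry jitter and
reproducibly derived seeds.

What the phantom does **not** emulate: radiative transfer or multiple
scattering (depolarization is generated directly in the exponent),
backscattering geometry, diattenuation (set to zero, as none was
measurable in this tissue), instrument calibration residuals, or
real lumen/fornix shapes.  Passing tests therefore demonstrate that the
*analysis chain* is correct and that the scoring statistics respond to
alignment randomization and density loss in the stated directions — not
that the specific default densities equal those of mouse cervix.

## Problem sizes used in validation

The test-suite and acceptance computations use 1,000 random 4x4 media
for the log/exp round trip, a 30x200-pixel thickness ramp for the
scaling laws, $10^5$-draw mixtures over 20 seeds for the fit-recovery
rate, $10^6$ Gaussian draws for the moment estimators, and a 300x300
five-plus-three phantom cohort for the stage contrasts — sizes at which
each check is decisive (the estimator standard errors and fit spreads are
far below the asserted tolerances) while the whole suite remains quick to
run routinely.

## Known limitations

* The eigendecomposition logarithm assumes diagonalizable matrices;
  numerically defective pixels are invalidated rather than handled by a
  Schur fallback.  On tissue-like data they are vanishingly rare.
* Retardance near $\pi$ sits at the principal-branch boundary; azimuth
  recovery degrades gracefully but retardances beyond $\pi$ alias, as in
  any single-wavelength measurement.
* The two-Gaussian model is a description of bimodality, not a mixture
  estimated from pixel likelihoods; with a dominant zero-retardance spike
  the fitted $R^2$ can be small even when both components are
  well-placed.  The degeneracy and convergence flags should be consulted
  before interpreting centers.
* Whole-image scoring deliberately forgoes spatial information; the
  azimuth maps retain it for qualitative inspection, but no regional
  statistics are produced.
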