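# lmmd — logarithmic Mueller matrix decomposition and collagen scoring

`lmmd` quantifies the arrangement of collagen fibers in transmission
Mueller matrix images of thin tissue sections — the measurement used to
track cervical extracellular-matrix remodeling across gestation, where
progressive randomization of the circumferential collagen ring is a
candidate marker of preterm-birth risk.  It is aimed at polarimetric
imaging groups who record per-pixel 4×4 Mueller matrices and want a
reproducible, segmentation-free scoring pipeline, plus a physically
grounded phantom simulator for validating it.

## What it computes

For every pixel, the principal matrix logarithm `L = ln M` is split by
the Minkowski metric `G = diag(1,−1,−1,−1)` into

    L_m = (L − G Lᵀ G)/2        (mean polarization: dichroism p1..p3,
                                 retardances p4..p6)
    L_u = (L + G Lᵀ G)/2        (attenuation d0 = ln M00 and
                                 depolarization d1..d9)

from which the scoring maps follow: total linear retardance
`R_L = √(p4² + p5²)` (rad), optical-axis azimuth
`θ = ½·atan2(p5, p4)` (degrees, 180° period; a proxy for local fiber
orientation), and linear depolarization `α22 = −d7` (0 = none, more
negative = stronger).

Because accumulated properties scale with local section thickness `z`
(`R_L = A·z`, `α22 = −B·z²`, `ln M00 = −μ_T·z`), the pixel-wise ratios
`R_L/|ln M00|`, `ln²M00/α22` and `α22/R_L²` cancel `z` and respond only
to tissue optics.  Whole-image statistics — moments, density histograms
with two-Gaussian fits, circular azimuth statistics — are computed over
all valid pixels with no region-of-interest selection, and aggregated
across animals per study group.

## Worked example

```r
library(lmmd)

ph   <- simulate_phantom(phantom_spec("day6", image_size = 300, seed = 5))
dec  <- matrix_log_field(ph$image, tol_imag = 1e-2)
dec
#> Logarithmic Mueller matrix decomposition 'day6_seed5'
#>   300 x 300 pixels, 57268 valid (63.6%)
#>   invalid causes: M00<=floor = 32732
#>   max discarded imaginary magnitude (valid px): 2.87e-14
```

The 32,732 invalid pixels are the opaque background outside the tissue
section; every tissue pixel decomposed cleanly (the discarded imaginary
part is at machine precision).  Scoring the retardance map:

```r
report <- score_image(extract_maps(dec))
report$moments$R_L
#> Moments of 'R_L' (n = 57268 pixels)
#>   mean 0.05915  std 0.052427  skewness 0.4074  excess kurtosis -1.201
report$fits$R_L
#> Two-Gaussian histogram fit
#>   component 1: a = 9.069  center = 0.00090861  width = 0.091972
#>   component 2: a = 2.508  center = 0.14445  width = 0.0082296
#>   R^2 = 0.088506 over 100 bins
```

The mean retardance (0.059 rad) is small because averaging covers the
whole image including the canal and fornix, which carry no aligned
collagen; that zero-retardance population is the fit's first component,
while the second component (center 0.144 rad) tracks the birefringent
aligned-collagen ring.  The azimuth, in contrast, is a deliberate null:

```r
report$circular
#> Circular azimuth statistics (n = 57268)
#>   mean direction 38.09 deg  resultant length 0.0032
#>   variance 0.9968  skewness -0.01673  kurtosis -0.02159
```

A circumferential ring covers all orientations as uniformly as random
fibers do (resultant length ≈ 0), which is why whole-image azimuth
statistics cannot separate ordered from remodeled tissue.

A full study-style run — five day-6 and three day-18 phantoms,
decomposed, fused, scored and aggregated — is one call:

```r
res <- run_pipeline(run_config(phantom = list(n_day6 = 5, n_day18 = 3,
                                              image_size = 300),
                               output_dir = "demo_out", seed = 1))
res$group_table[, c("group", "n_animals", "c2_mean", "c2_sd")]
#>   group n_animals c2_mean   c2_sd
#> 1  day6         5 0.16416 0.03816
#> 2 day18         3 0.01912 0.01614
```

The second-peak center collapses from day 6 to day 18 — the remodeling
signal — while per-image maps, fused maps, histogram CSVs, quick-look
renders and a manifest land in `demo_out/`.  The same pipeline runs from
the shell via `inst/scripts/lmmd.R` (subcommands `simulate`, `decompose`,
`fuse`, `score`, `all`), and measured images are ingested from 16-page
float TIFF (+ JSON sidecar) or the exact `.mmraw` container.

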