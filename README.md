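# sonomt

Automatic muscle-thickness (MT) estimation for longitudinal B-mode
ultrasound of skeletal muscle, plus the agreement statistics used to
evaluate such measurements.

In a longitudinal sonogram of a pennate muscle the superficial and deep
aponeuroses appear as two bright, quasi-horizontal bands; MT is the distance
between them and tracks muscle contraction. Manual calliper readings are
slow and subjective. sonomt automates the measurement with a four-stage
pipeline:

1. **Enhancement** of coherent tubular structure, by either a
   reliability-gated **Gabor filter bank** (orientation field + ridge
   frequency map + even-symmetric Gabor kernels, blocks with orientation
   reliability below 50% ignored) or **multiscale vessel enhancement
   filtering** (Frangi vesselness): with Hessian eigenvalues
   |λ₁| ≤ |λ₂|, response `exp(-R_B²/2β²)(1 − exp(-S²/2c²))` for λ₂ < 0,
   where `R_B = λ₁/λ₂`, `S = √(λ₁²+λ₂²)`, maximized over Gaussian scales.
2. **Otsu binarization** into a binary edge map.
3. **Revoting Hough transform (RVHT)**: find the global accumulator peak
   over `(ρ, θ)` (a pixel lies on a line when `x cosθ + y sinθ = ρ`),
   remove edge pixels within a half-width of the detected line,
   re-accumulate, repeat.
4. **Thickness**: the line pair with maximum mean separation is the
   superficial/deep aponeurosis pair; MT is the mean middle-line distance,
   in mm via the pixel calibration.

Per-frame series can be median-smoothed with outlier flagging (difference
from the smooth version > 0.5 mm), and a synthetic speckle-phantom generator
with known band geometry provides ground truth for validation. The
reliability module implements ICC(A,1) (single-measure, absolute agreement,
with F-based confidence intervals), SEM = s·√(1−ICC),
MDC = SEM·1.96·√2, Bland-Altman limits of agreement, and squared Pearson
correlation.

## Worked example

```r
library(sonomt)

# a speckled phantom with known geometry: bands at rows 100/250,
# 0.1 mm/px, so ground-truth MT = 15 mm
cfg <- phantom_config(speckle_scale = 0.3)
ph  <- phantom_image(cfg, seed = 7)

estimate_mt(ph$image, method = "mvef", pixel_spacing_mm = 0.1)
#> <mt_result> frame 1 (mvef): MT = 14.90 mm (149.0 px)
#>   superficial: rho 104.0, theta 89.0 deg, 385 votes
#>   deep:        rho 253.0, theta 89.0 deg, 384 votes
```

The detected lines sit on the two bands (rho ≈ band rows, theta ≈ 90° =
horizontal), each supported by ~385 votes (the image width), and the
measured 14.90 mm is within one pixel of the 15 mm truth.

A sequence with a spiked frame, measured and smoothed:

```r
seqs <- phantom_sequence(cfg, mt_trajectory = c(rep(15, 3), 19, rep(15, 3)),
                         seed = 1)
mt <- run_pipeline(seqs$frames, method = "mvef", pixel_spacing_mm = 0.1,
                   smooth = TRUE, window = 5)
mt[, c("frame", "mt_mm", "smoothed_mm", "outlier")]
#>   frame    mt_mm smoothed_mm outlier
#> 1     1 15.00000    15.00000   FALSE
#> 4     4 18.90000    15.26901    TRUE
#> 7     7 14.90000    14.90000   FALSE
```

Frame 4 (the 19 mm excursion) is the only frame whose raw value departs
from the running median by more than the 0.5 mm rule, so it alone is
flagged. `autoplot(mt)` draws the series; `tidy()`/`autoplot()` methods
also cover `bland_altman()` results.

Reliability statistics from a printed summary (SD = 1.63 mm, ICC = 0.953):

```r
round(sem(1.63, 0.953), 2)   # 0.35 mm
round(mdc(0.35), 2)          # 0.97 mm
```

A command-line front end with `phantom`, `enhance`, `binarize`, `measure`,
`batch` and `stats` subcommands is installed at
`system.file("cli", "sonomt.R", package = "sonomt")`.

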