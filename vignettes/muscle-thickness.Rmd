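---
title: "Automatic muscle thickness from B-mode ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic muscle thickness from B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonomt)
```

## The measurement problem

In a longitudinal B-mode sonogram of a pennate muscle such as the
gastrocnemius, the superficial and deep aponeuroses appear as two bright
(hyperechoic), quasi-horizontal bands bounding the muscle belly. Muscle
thickness (MT) — the distance between those two bands — tracks contraction
and is a basic outcome measure in musculoskeletal ultrasound. Reading it
manually with on-screen callipers frame by frame is slow and subjective;
sonomt automates it.

The pipeline has four stages:

1. **Enhancement** of tubular, coherently oriented structure, by one of two
   established methods: a reliability-gated **Gabor filter bank**
   (orientation field, ridge-frequency map, even-symmetric Gabor kernels),
   or **multiscale vessel enhancement filtering (MVEF)** — Frangi-style
   Hessian-eigenvalue vesselness maximized over Gaussian scales.
2. **Binarization** by Otsu's criterion into a binary "edge map".
3. **Line detection** by the **revoting Hough transform (RVHT)**: take the
   global accumulator peak, delete edge pixels within a half-width of the
   detected line, re-accumulate, repeat.
4. **Thickness**: among the detected lines, the pair with the maximum mean
   separation is taken as the superficial/deep aponeuroses, and MT is the
   mean middle-line distance between them, converted to millimetres by the
   pixel calibration.

`estimate_mt()` runs all four stages on one frame; `run_pipeline()` maps it
over a sequence with per-frame failure isolation; `smooth_mt_series()`
median-filters the resulting series and flags frames whose raw value departs
from the smooth version by more than 0.5 mm.

## Models and formulas

**Orientation field.** For each block, with gradient second moments
$G_{xx}=\sum g_x^2$, $G_{yy}=\sum g_y^2$, $G_{xy}=\sum g_x g_y$, the ridge
orientation is $\tfrac12\,\mathrm{atan2}(2G_{xy},\,G_{xx}-G_{yy})+\pi/2$
(mod $\pi$) and the coherence (orientation reliability) is
$\sqrt{(G_{xx}-G_{yy})^2+4G_{xy}^2}/(G_{xx}+G_{yy})$, defined as 0 for
blocks with no gradient energy. Gradients are computed with zero-sum
Gaussian-derivative kernels ($\sigma=1$): bare central differences let
speckle inflate the isotropic part of the structure tensor and collapse the
coherence of genuinely oriented blocks. Blocks with coherence below the
reliability threshold (default 0.5, i.e. 50%) are ignored — their output is
zero.

**Ridge frequency.** Block intensities are projected onto the axis
orthogonal to the local orientation; the dominant period is the mean spacing
of the projection's peaks. Strong but aperiodic ridges (the aponeuroses
themselves) get the median frequency of the valid blocks, so the bands are
not left unfiltered.

**Vesselness.** With Hessian eigenvalues $|\lambda_1|\le|\lambda_2|$ from
scale-normalized ($\sigma^2$-weighted) Gaussian second-derivative
convolutions, the bright-structure response is
$\exp(-R_B^2/2\beta^2)\,\bigl(1-\exp(-S^2/2c^2)\bigr)$ with
$R_B=\lambda_1/\lambda_2$, $S=\sqrt{\lambda_1^2+\lambda_2^2}$, and 0
wherever $\lambda_2\ge 0$. The multiscale output is the pixel-wise maximum
over the scale set.

**RVHT.** A pixel $(x,y)$ (0-based, row index downward) lies on line
$(\rho,\theta)$ when $x\cos\theta+y\sin\theta=\rho$. Every on-pixel votes
once per $\theta$ bin into the nearest $\rho$ bin, so each accumulation
conserves votes exactly ($n_{on}\times n_{\theta}$), and removal-only
revoting makes successive peak counts non-increasing. Peaks are returned at
bin centres with deterministic tie-breaking (smallest $\theta$ bin, then
smallest $\rho$ bin); no sub-bin refinement is applied.

**Thickness.** For lines $a, b$, each line's row $y(x)$ is evaluated per
column and MT is $\mathrm{mean}_x\,|y_a-y_b|\cdot|\sin((\theta_a+\theta_b)/2)|$
— the vertical gap projected perpendicular to the mean orientation. Columns
where a line leaves the image are excluded (with a warning below 50%
overlap); near-vertical lines ($|\sin\theta|<0.1$) are treated as detection
failures, since an aponeurosis is quasi-horizontal by anatomy.

**Reliability statistics.** `icc_a1()` is the single-measure,
absolute-agreement two-way ICC,
$(MS_R-MS_E)/(MS_R+(k-1)MS_E+\tfrac{k}{n}(MS_C-MS_E))$, with the standard
F-based confidence interval (Satterthwaite degrees of freedom).
`sem()` is $s_x\sqrt{1-\mathrm{ICC}}$ and `mdc()` is
$\mathrm{SEM}\times1.96\times\sqrt2$. `reliability_report()` reproduces the
conventional per-subject summary; by default it computes the MDC from the
SEM rounded to two decimals, which is how such printed tables are
internally consistent — set `round_sem = FALSE` for full precision.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `block_size` (Gabor) | 16 | px | a block spans ~1 fascicle period |
| `sigma_x`, `sigma_y` | 4 | px | kernel envelope; truncated at 3 sigma |
| `reliability_threshold` | 0.5 | — | 50% orientation-reliability gate |
| `scales` (MVEF) | 1.5, 3, 5, 7 | px | aponeuroses are a few px thick at typical resolutions |
| `beta` | 0.5 | — | standard blobness weight |
| `c` | auto | — | half the max Hessian norm per scale |
| `rho_step`, `theta_step` | 1 px, 1 degree | | standard Hough quantization |
| `halfwidth` (removal) | 6 | px | must cover the *binarized, enhanced* band (see below) |
| `n_lines` | 2 | — | the aponeuroses are expected to be the first two lines |
| `window` (median) | 5 | frames | removes single-frame spikes |
| `outlier_threshold_mm` | 0.5 | mm | flagging rule for implausible frames |
| `pixel_spacing_mm` | 0.1 | mm/px | scanner calibration; always supply your own |

The removal half-width deserves a note: a natural first choice is the
aponeurosis half-thickness (~3 px), but enhancement widens the band — the
multiscale maximum responds out to roughly its largest scale — so the
binarized band is ~9 px thick. A removal narrower than that leaves a
residual strip of the *same* band, which wins the next vote and produces a
catastrophic near-zero thickness. The default (6 px) covers the enhanced
band; it is configurable for edge maps with different structure widths.

## The synthetic phantom

`phantom_image()` renders what the pipeline needs to be tested against known
truth: two bright bands with Gaussian cross-profiles (sigma = half-width/2)
at configurable rows and slopes, oblique raised-cosine fascicle streaks
strictly between the bands, and fully developed multiplicative speckle
(unit-mean Gamma factors, dispersion `speckle_scale`; shape
$1/\text{scale}^2$). Identical configuration and seed give bit-identical
images. Defaults: 384 x 384 px, bands at rows 100/250, horizontal, band
half-width 3 px, band intensity 0.85 over a 0.12 background, fascicles at 18
degrees with period 14 px and contrast 0.2, speckle 0.25, calibration 0.1
mm/px (no calibration was available to copy, so the default is an arbitrary
round value — always set your own). At that calibration the default
geometry corresponds to a 15 mm muscle, the magnitude observed in an aged
subject's gastrocnemius.

What the phantom does *not* emulate matters for interpreting green tests:

* No depth attenuation or gain variation, no acoustic point-spread function,
  no off-muscle anatomy (skin, subcutaneous fat interfaces, bone shadow).
* Its fascicles are fainter than its aponeuroses, so Otsu binarization of
  the *raw* phantom already isolates the bands; direct binarization
  therefore succeeds on phantoms far more often than it does on clinical
  images, where competing echogenic structure defeats it. The
  enhancement-vs-none comparison on phantoms is accordingly a direction
  check (enhancement never hurts), not a reproduction of the clinical
  failure rate of the unenhanced pipeline.
* Recovery on phantoms bounds implementation error, not clinical accuracy.

## Numerical choices

* Gaussian-derivative kernels are normalized to zero sum so they annihilate
  constant images exactly; otherwise discrete-sampling bias (~1e-4) leaks
  spurious "structure" into flat regions, which matters because the
  vesselness `c` auto-tunes to the per-scale maximum Hessian norm.
  Structure-tensor blocks with gradient energy at round-off level are
  assigned coherence 0, and a vanishing auto-tuned `c` short-circuits to a
  zero response.
* Convolution kernels are capped at the image size; Hessian estimation on
  images smaller than ~5 px errors out.
* Hough peak localization on a thick band: every on-row of a full-width
  horizontal band produces the same vote count at the true theta, and a bin
  tilted by one theta step genuinely out-votes it once the band is thicker
  than `width * tan(theta_step)`. The bin-centre line is therefore localized
  to about half the binarized band thickness, not to the rho step. Both
  aponeuroses shift together, so the thickness estimate is much more
  accurate than either line's absolute position; tests assert exactly that.
* The phantom's default bands are horizontal. A band sloped between theta
  bins interacts with the aliasing above; sloped geometry is exercised
  analytically (the distance formulas are exact for any slope) rather than
  through the default study conditions.
* Degenerate inputs are first-class: constant images binarize to an empty
  map with a warning, empty maps accumulate to all-zero (peak extraction
  errors), frames with fewer than two detectable lines raise a detection
  failure that `run_pipeline()` records without aborting the run.

## Known limitations

* The middle-line MT definition differs from the manual border-to-border
  calliper convention by roughly the aponeurosis wall thickness (~1.4-1.5
  mm in the source study); the bias is documented, not corrected.
* Orientation and frequency are block-constant (no interpolation across
  blocks), which is sufficient for the coarse enhancement RVHT needs.
* Only 2-D single-channel frames are supported; no DICOM/cine ingestion.
* Test problem sizes: pipeline-level properties run on 256 x 256 phantoms
  (100 noise-free geometries swept over 80-200 px of thickness, 20 seeds x
  5 levels at speckle 0.3, 20 seeds at speckle 0.5), which keeps the full
  suite to a few minutes while spanning the geometry range of interest.
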