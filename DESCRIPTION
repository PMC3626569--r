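Package: sonomt
Title: Automatic Muscle Thickness Estimation from B-Mode Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic estimation of skeletal muscle thickness from B-mode
    ultrasound images. Enhances hyperechoic aponeurosis bands with either a
    reliability-gated Gabor filter bank or Frangi-style multiscale vessel
    enhancement filtering, binarizes the enhanced image, detects the dominant
    line structures with a revoting Hough transform, selects the superficial
    and deep aponeuroses as the maximally separated line pair, and reports
    muscle thickness in millimetres. Includes a synthetic speckle-phantom
    generator with known aponeurosis geometry for validation, time-series
    smoothing with outlier flagging, and the agreement statistics used to
    evaluate such measurements (intraclass correlation, standard error of
    measurement, minimal detectable change, Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
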