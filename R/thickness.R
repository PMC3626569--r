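#' Mean distance between two quasi-horizontal lines
#'
#' Evaluates both lines' row coordinate `y(x) = (rho - x cos(theta)) /
#' sin(theta)` at every column in `[0, width)`, averages the absolute vertical
#' separation, and projects it perpendicular to the mean line orientation by
#' the factor `|sin((theta_a + theta_b) / 2)|`. This is the middle-line
#' distance the automatic pipeline reports as muscle thickness; it differs by
#' roughly the aponeurosis wall thickness from manual border-to-border
#' calliper readings.
#'
#' Near-vertical lines (|sin(theta)| < 0.1) raise a geometry error: an
#' aponeurosis detection should be quasi-horizontal, so a vertical line is a
#' failure signal, not a measurable pair member. If `height` is given, columns
#' where either line leaves the image are excluded from the mean, with a
#' warning when fewer than half the columns remain.
#'
#' @param a,b Lines: one-row data frames (or lists) with `rho`, `theta`.
#' @param width Number of columns to average over, >= 1.
#' @param height Optional image height used to clip off-image columns.
#'
#' @return Mean separation in pixels (scalar).
#' @export
mean_line_distance <- function(a, b, width, height = NULL) {
  if (width < 1) stop("width must be >= 1", call. = FALSE)
  eps <- 0.1
  if (abs(sin(a$theta)) < eps || abs(sin(b$theta)) < eps) {
    stop("near-vertical line: cannot measure a quasi-horizontal separation",
         call. = FALSE)
  }
  x <- 0:(width - 1)
  ya <- (a$rho - x * cos(a$theta)) / sin(a$theta)
  yb <- (b$rho - x * cos(b$theta)) / sin(b$theta)
  keep <- rep(TRUE, length(x))
  if (!is.null(height)) {
    keep <- ya >= 0 & ya < height & yb >= 0 & yb < height
    if (!any(keep)) {
      stop("lines do not overlap the image over any column", call. = FALSE)
    }
    if (mean(keep) < 0.5) {
      warning("lines overlap the image over less than half the width")
    }
  }
  mean(abs(ya[keep] - yb[keep])) * abs(sin((a$theta + b$theta) / 2))
}

#' Select the aponeurosis pair from detected lines
#'
#' Among all pairs of detected lines, picks the pair with the maximum
#' [mean_line_distance()] — in a longitudinal muscle sonogram the maximally
#' separated line pair is the superficial/deep aponeurosis pair; ties are
#' broken by the higher combined vote count.
#' The member with the smaller mean row coordinate is labelled superficial.
#' Pairs containing a near-vertical line are skipped.
#'
#' @param lines Tibble of lines (`rho`, `theta`, `votes`), >= 2 rows.
#' @param width Image width in pixels.
#' @param height Optional image height for off-image clipping.
#'
#' @return List with one-row tibbles `superficial` and `deep`, and `mt_px`.
#' @export
select_aponeuroses <- function(lines, width, height = NULL) {
  if (is.null(lines) || nrow(lines) < 2) {
    stop("detection failure: need at least 2 lines to select aponeuroses",
         call. = FALSE)
  }
  pairs <- utils::combn(nrow(lines), 2)
  best <- NULL
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- tryCatch(
      mean_line_distance(lines[i, ], lines[j, ], width, height),
      error = function(e) NA_real_
    )
    if (is.na(d)) next
    v <- lines$votes[i] + lines$votes[j]
    if (is.null(best) || d > best$d + 1e-12 ||
        (abs(d - best$d) <= 1e-12 && v > best$v)) {
      best <- list(i = i, j = j, d = d, v = v)
    }
  }
  if (is.null(best)) {
    stop("detection failure: no measurable line pair", call. = FALSE)
  }
  x <- 0:(width - 1)
  row_mean <- function(ln) mean((ln$rho - x * cos(ln$theta)) / sin(ln$theta))
  i <- best$i; j <- best$j
  if (row_mean(lines[j, ]) < row_mean(lines[i, ])) { k <- i; i <- j; j <- k }
  list(superficial = lines[i, ], deep = lines[j, ], mt_px = best$d)
}

#' Automatic muscle thickness from a single ultrasound frame
#'
#' Runs the full four-step pipeline: (1) enhancement by a reliability-gated
#' Gabor filter bank or multiscale vessel enhancement filtering, (2) Otsu
#' binarization into an edge map, (3) revoting Hough transform line detection,
#' (4) maximum-distance pair selection and mean middle-line distance,
#' converted to millimetres through the pixel calibration.
#'
#' @param image Numeric matrix in [0, 1] (see [read_frame()]).
#' @param method `"mvef"` (default; much cheaper) or `"gabor"`, or `"none"` to
#'   binarize the raw frame without enhancement.
#' @param pixel_spacing_mm Calibration in mm per pixel, > 0.
#' @param n_lines Lines searched by the revoting Hough transform.
#' @param frame_index Frame label carried into the result.
#' @param gabor,mvef,rvht Named lists overriding stage parameters (see
#'   [gabor_enhance()], [mvef_enhance()], [rvht_detect()]).
#'
#' @return Object of class `mt_result`: fields `superficial`, `deep` (one-row
#'   line tibbles), `mt_px`, `mt_mm`, `threshold`, `method`, `frame_index`.
#'   Use [tidy()] to get a one-row tibble.
#' @examples
#' ph <- phantom_image(phantom_config(speckle_scale = 0), seed = 1)
#' res <- estimate_mt(ph$image, method = "mvef", pixel_spacing_mm = 0.1)
#' res$mt_mm
#' @export
estimate_mt <- function(image, method = c("mvef", "gabor", "none"),
                        pixel_spacing_mm, n_lines = 2L, frame_index = 1L,
                        gabor = list(), mvef = list(), rvht = list()) {
  method <- match.arg(method)
  if (pixel_spacing_mm <= 0) {
    stop("pixel_spacing_mm must be positive", call. = FALSE)
  }
  enhanced <- switch(method,
    gabor = do.call(gabor_enhance, c(list(image), gabor)),
    mvef = do.call(mvef_enhance, c(list(image), mvef)),
    none = image
  )
  em <- binarize(enhanced, method = "otsu")
  lines <- do.call(rvht_detect, c(list(em, n_lines = n_lines), rvht))
  if (nrow(lines) < 2) {
    stop("detection failure: fewer than 2 lines found", call. = FALSE)
  }
  sel <- select_aponeuroses(lines, width = ncol(image), height = nrow(image))
  structure(list(
    superficial = sel$superficial, deep = sel$deep,
    mt_px = sel$mt_px, mt_mm = sel$mt_px * pixel_spacing_mm,
    threshold = em$threshold, method = method,
    n_lines = nrow(lines), frame_index = frame_index
  ), class = "mt_result")
}

#' @export
print.mt_result <- function(x, ...) {
  cat(sprintf(
    "<mt_result> frame %s (%s): MT = %.2f mm (%.1f px)\n",
    x$frame_index, x$method, x$mt_mm, x$mt_px))
  cat(sprintf("  superficial: rho %.1f, theta %.1f deg, %d votes\n",
              x$superficial$rho, x$superficial$theta * 180 / pi,
              x$superficial$votes))
  cat(sprintf("  deep:        rho %.1f, theta %.1f deg, %d votes\n",
              x$deep$rho, x$deep$theta * 180 / pi, x$deep$votes))
  invisible(x)
}

#' Tidy a single-frame thickness result
#'
#' @param x An `mt_result`.
#' @param ... Unused.
#' @return One-row tibble with frame, method, thickness and line parameters
#'   (theta reported in degrees).
#' @export
tidy.mt_result <- function(x, ...) {
  tibble::tibble(
    frame = x$frame_index, method = x$method,
    mt_mm = x$mt_mm, mt_px = x$mt_px,
    rho1 = x$superficial$rho, theta1_deg = x$superficial$theta * 180 / pi,
    votes1 = x$superficial$votes,
    rho2 = x$deep$rho, theta2_deg = x$deep$theta * 180 / pi,
    votes2 = x$deep$votes,
    threshold = x$threshold
  )
}

#' Smooth a muscle-thickness time series and flag outliers
#'
#' Applies a running median of odd width `window` (window shrinking at the
#' series ends) to the per-frame thickness values and flags frames whose
#' original value differs from the smoothed value by more than
#' `outlier_threshold_mm` (default 0.5 mm, the criterion used to mark
#' implausible single-frame estimates during dynamic contractions).
#'
#' @param series Data frame with at least a numeric `mt_mm` column (a `frame`
#'   column is added if missing).
#' @param window Odd median window, >= 3, not larger than the series.
#' @param outlier_threshold_mm Flagging threshold in mm.
#'
#' @return The input tibble with columns `smoothed_mm` and `outlier` added,
#'   classed `mt_series` for [autoplot()].
#' @examples
#' s <- tibble::tibble(mt_mm = c(15, 15, 15, 40, 15, 15, 15))
#' smooth_mt_series(s, window = 5)
#' @export
smooth_mt_series <- function(series, window = 5L,
                             outlier_threshold_mm = 0.5) {
  if (!is.data.frame(series) || !"mt_mm" %in% names(series)) {
    stop("series must be a data frame with an mt_mm column", call. = FALSE)
  }
  n <- nrow(series)
  window <- as.integer(window)
  if (window %% 2 == 0 || window < 3) {
    stop("window must be an odd integer >= 3", call. = FALSE)
  }
  if (window > n) {
    stop("window must not exceed the series length", call. = FALSE)
  }
  out <- tibble::as_tibble(series)
  if (!"frame" %in% names(out)) {
    out <- dplyr::mutate(out, frame = dplyr::row_number(), .before = 1)
  }
  out$smoothed_mm <- as.numeric(
    stats::runmed(out$mt_mm, k = window, endrule = "median"))
  out$outlier <- abs(out$mt_mm - out$smoothed_mm) > outlier_threshold_mm
  class(out) <- c("mt_series", class(out))
  attr(out, "outlier_threshold_mm") <- outlier_threshold_mm
  out
}
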