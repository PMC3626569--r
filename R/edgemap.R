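#' Binarize an enhanced image into an edge map
#'
#' Thresholds the image into the binary "edge map" whose on-pixels vote in the
#' Hough accumulator. The threshold is either chosen by Otsu's criterion
#' (maximal between-class variance over a 256-bin histogram) or supplied as a
#' fixed level; pixels strictly above the threshold are on.
#'
#' @param image Numeric matrix with values in [0, 1].
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param level Threshold in [0, 1]; required for `method = "fixed"`.
#'
#' @return A list of class `edge_map` with `mask` (logical matrix), `n_on`
#'   (number of on-pixels) and `threshold` (the level used).
#' @examples
#' em <- binarize(matrix(c(0.1, 0.9), 8, 8))
#' em$n_on
#' @export
binarize <- function(image, method = c("otsu", "fixed"), level = NULL) {
  method <- match.arg(method)
  if (any(image < 0) || any(image > 1)) {
    stop("binarize expects intensities in [0, 1]", call. = FALSE)
  }
  if (method == "fixed") {
    if (is.null(level)) stop("method = 'fixed' requires level", call. = FALSE)
    thr <- level
  } else {
    rng <- range(image)
    if (rng[1] == rng[2]) {
      warning("constant image: Otsu threshold degenerates, edge map is empty")
      thr <- rng[1]
    } else {
      thr <- EBImage::otsu(image, range = c(0, 1), levels = 256)
    }
  }
  mask <- image > thr
  new_edge_map(mask, threshold = thr)
}

new_edge_map <- function(mask, threshold = NA_real_) {
  structure(list(mask = mask, n_on = sum(mask), threshold = threshold),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map> %d x %d, %d on-pixels (threshold %.4g)\n",
              nrow(x$mask), ncol(x$mask), x$n_on, x$threshold))
  invisible(x)
}
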