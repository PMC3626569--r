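#' Read an ultrasound frame from disk
#'
#' Reads a PNG or TIFF image as a numeric matrix in [0, 1], row 0 at the top.
#' RGB(A) input is collapsed to Rec. 709 luminance. 8- and 16-bit files map to
#' [0, 1] by their full bit range.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (use PNG or TIFF): %s",
                 ext, path), call. = FALSE)
  )
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3) {
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Write a frame to a PNG file
#'
#' @param image Numeric matrix; values are clipped to [0, 1].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_frame <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Crop a frame to a rectangular region
#'
#' @param image Numeric matrix.
#' @param rows,cols Length-2 integer vectors, 1-based inclusive bounds of the
#'   region to keep.
#' @return The sub-matrix.
#' @examples
#' crop_frame(matrix(0, 480, 640), rows = c(1, 373), cols = c(1, 403))
#' @export
crop_frame <- function(image, rows, cols) {
  if (length(rows) != 2 || length(cols) != 2 ||
      rows[1] < 1 || cols[1] < 1 ||
      rows[2] > nrow(image) || cols[2] > ncol(image) ||
      rows[1] > rows[2] || cols[1] > cols[2]) {
    stop("crop region must be a nonempty rectangle inside the image",
         call. = FALSE)
  }
  image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

#' Read a flat key = value pipeline configuration file
#'
#' Parses a plain-text file of `key = value` lines (`#` comments allowed).
#' Values that parse as numbers become numeric; comma-separated numeric lists
#' become vectors; everything else stays character.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    }
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else val
  }
  out
}

#' Run the thickness pipeline over a sequence of frames
#'
#' Applies [estimate_mt()] to every input, isolating per-frame failures: a
#' frame that cannot be read or where fewer than two lines are detected is
#' recorded and skipped, and the run continues. Inputs may be file paths or
#' in-memory matrices.
#'
#' @param inputs Character vector of image paths, or a list of numeric
#'   matrices.
#' @param method Enhancement method, `"mvef"`, `"gabor"` or `"none"`.
#' @param pixel_spacing_mm Calibration in mm per pixel.
#' @param smooth If `TRUE` (default when more than `window` frames succeed),
#'   adds running-median smoothing and outlier flags via [smooth_mt_series()].
#' @param window,outlier_threshold_mm Smoothing parameters.
#' @param out_csv Optional path; when given the result table is written as a
#'   CSV with a `# sonomt results v1` header comment.
#' @param ... Passed to [estimate_mt()] (e.g. `n_lines`, `rvht = list(...)`).
#'
#' @return Tibble with one row per successful frame (columns as in
#'   [tidy.mt_result()], plus smoothing columns when applied); failures are
#'   attached as a tibble in `attr(, "failures")`.
#' @export
run_pipeline <- function(inputs, method = "mvef", pixel_spacing_mm = 0.1,
                         smooth = NULL, window = 5L,
                         outlier_threshold_mm = 0.5, out_csv = NULL, ...) {
  n <- length(inputs)
  rows <- vector("list", n)
  fails <- list()
  if (n == 0) warning("empty input list: nothing to measure")
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- if (is.character(inputs)) read_frame(inputs[[i]]) else
        inputs[[i]]
      r <- estimate_mt(img, method = method,
                       pixel_spacing_mm = pixel_spacing_mm,
                       frame_index = i, ...)
      tidy(r)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1]] <- tibble::tibble(
        frame = i,
        input = if (is.character(inputs)) inputs[[i]] else sprintf("<frame %d>", i),
        error = conditionMessage(res)
      )
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(), method = character(),
                          mt_mm = numeric(), mt_px = numeric())
  }
  if (is.null(smooth)) smooth <- nrow(out) >= window
  if (smooth && nrow(out) >= window) {
    out <- smooth_mt_series(out, window = window,
                            outlier_threshold_mm = outlier_threshold_mm)
  }
  attr(out, "failures") <- dplyr::bind_rows(fails)
  if (!is.null(out_csv)) {
    con <- file(out_csv, "w")
    writeLines("# sonomt results v1", con)
    utils::write.csv(as.data.frame(out), con, row.names = FALSE)
    close(con)
  }
  out
}
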