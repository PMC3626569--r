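#' Configuration for a synthetic muscle ultrasound phantom
#'
#' Builds and validates the parameter set for [phantom_image()] and
#' [phantom_sequence()]. The phantom emulates a longitudinal B-mode sonogram
#' of a pennate muscle: two bright quasi-horizontal aponeurosis bands, oblique
#' periodic fascicle streaks strictly between them, and fully developed
#' multiplicative speckle.
#'
#' Coordinates are 0-based with the row index increasing downward (deeper
#' tissue), matching the convention used by the Hough-transform stage. The
#' superficial band must sit above (smaller row than) the deep band.
#'
#' @param height,width Image size in pixels.
#' @param superficial_row,deep_row Band centre rows (0-based) at the left edge.
#' @param band_slope Band slope, delta-row per column; applied to both bands
#'   unless `deep_slope` is given.
#' @param deep_slope Optional separate slope for the deep band.
#' @param band_halfwidth Band half-thickness in pixels; bands are rendered with
#'   a Gaussian cross-profile of sigma `band_halfwidth / 2`.
#' @param band_intensity Peak band brightness added over background, in [0, 1].
#' @param fascicle_angle Fascicle inclination from horizontal, degrees.
#' @param fascicle_period Across-fascicle spacing in pixels (>= 2).
#' @param fascicle_contrast Peak fascicle brightness over background, in [0, 1].
#' @param speckle_scale Dispersion of the multiplicative speckle factor
#'   (unit-mean Gamma with shape `1 / speckle_scale^2`); 0 gives a noise-free
#'   image.
#' @param background_level Background echo level in [0, 1].
#' @param pixel_spacing_mm Calibration, millimetres per pixel.
#'
#' @return A list of class `phantom_config`.
#' @seealso [phantom_image()], [phantom_sequence()]
#' @export
phantom_config <- function(height = 384L,
                           width = 384L,
                           superficial_row = 100,
                           deep_row = 250,
                           band_slope = 0,
                           deep_slope = NULL,
                           band_halfwidth = 3,
                           band_intensity = 0.85,
                           fascicle_angle = 18,
                           fascicle_period = 14,
                           fascicle_contrast = 0.2,
                           speckle_scale = 0.25,
                           background_level = 0.12,
                           pixel_spacing_mm = 0.1) {
  cfg <- list(
    height = as.integer(height), width = as.integer(width),
    superficial_row = superficial_row, deep_row = deep_row,
    band_slope = band_slope,
    deep_slope = if (is.null(deep_slope)) band_slope else deep_slope,
    band_halfwidth = band_halfwidth, band_intensity = band_intensity,
    fascicle_angle = fascicle_angle, fascicle_period = fascicle_period,
    fascicle_contrast = fascicle_contrast, speckle_scale = speckle_scale,
    background_level = background_level, pixel_spacing_mm = pixel_spacing_mm
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (cfg$height < 8 || cfg$width < 8) {
    stop("phantom_config: height and width must be at least 8 pixels",
         call. = FALSE)
  }
  if (!(0 <= cfg$superficial_row && cfg$superficial_row < cfg$deep_row &&
        cfg$deep_row < cfg$height)) {
    stop("phantom_config: need 0 <= superficial_row < deep_row < height",
         call. = FALSE)
  }
  if (cfg$band_halfwidth < 1) {
    stop("phantom_config: band_halfwidth must be >= 1", call. = FALSE)
  }
  if (cfg$fascicle_period < 2) {
    stop("phantom_config: fascicle_period must be >= 2", call. = FALSE)
  }
  if (cfg$speckle_scale < 0) {
    stop("phantom_config: speckle_scale must be >= 0", call. = FALSE)
  }
  if (cfg$pixel_spacing_mm <= 0) {
    stop("phantom_config: pixel_spacing_mm must be positive", call. = FALSE)
  }
  invisible(cfg)
}

# (rho, theta) normal form of the band centreline row = row0 + slope * col,
# with theta in [0, pi) and x cos(theta) + y sin(theta) = rho.
band_line <- function(row0, slope) {
  nrm <- sqrt(1 + slope^2)
  theta <- atan2(1, -slope) %% pi
  list(rho = row0 / nrm, theta = theta)
}

#' Generate a synthetic muscle ultrasound phantom
#'
#' Renders the two aponeurosis bands with Gaussian cross-profiles, adds
#' oblique raised-cosine fascicle streaks strictly between the bands,
#' multiplies by unit-mean Gamma speckle, and clips to [0, 1]. The same
#' `(config, seed)` pair always returns a bit-identical image.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for the speckle field.
#'
#' @return A list with elements
#'   * `image`: numeric matrix in [0, 1], rows are depth;
#'   * `truth`: one-row tibble with the ground-truth line parameters
#'     (`rho1`, `theta1` superficial; `rho2`, `theta2` deep), `mt_px`
#'     (mean vertical band separation over columns) and `mt_mm`.
#' @examples
#' ph <- phantom_image(phantom_config(speckle_scale = 0), seed = 1)
#' ph$truth$mt_px
#' @export
phantom_image <- function(config = phantom_config(), seed = 1L) {
  validate_phantom_config(config)
  h <- config$height; w <- config$width
  x <- matrix(rep(0:(w - 1), each = h), h, w)   # column coord
  y <- matrix(rep(0:(h - 1), times = w), h, w)  # row coord (depth)

  sig <- config$band_halfwidth / 2
  c_sup <- config$superficial_row + config$band_slope * x
  c_deep <- config$deep_row + config$deep_slope * x
  img <- config$background_level +
    config$band_intensity * exp(-(y - c_sup)^2 / (2 * sig^2)) +
    config$band_intensity * exp(-(y - c_deep)^2 / (2 * sig^2))

  # fascicle texture confined to the muscle belly between the bands
  margin <- 2 * config$band_halfwidth
  belly <- (y > c_sup + margin) & (y < c_deep - margin)
  if (any(belly) && config$fascicle_contrast > 0) {
    a <- config$fascicle_angle * pi / 180
    u <- x * sin(a) + y * cos(a)
    streaks <- (0.5 * (1 + cos(2 * pi * u / config$fascicle_period)))^3
    img <- img + config$fascicle_contrast * streaks * belly
  }

  if (config$speckle_scale > 0) {
    shape <- 1 / config$speckle_scale^2
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    img <- img * matrix(stats::rgamma(h * w, shape = shape, rate = shape), h, w)
  }
  img <- pmin(pmax(img, 0), 1)

  l1 <- band_line(config$superficial_row, config$band_slope)
  l2 <- band_line(config$deep_row, config$deep_slope)
  xm <- mean(0:(w - 1))
  mt_px <- (config$deep_row - config$superficial_row) +
    (config$deep_slope - config$band_slope) * xm
  truth <- tibble::tibble(
    rho1 = l1$rho, theta1 = l1$theta,
    rho2 = l2$rho, theta2 = l2$theta,
    mt_px = mt_px, mt_mm = mt_px * config$pixel_spacing_mm
  )
  list(image = img, truth = truth)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Generate a phantom frame sequence following a thickness trajectory
#'
#' Frame `i` keeps the superficial band fixed and moves the deep band so the
#' ground-truth thickness equals `mt_trajectory[i]` (in mm, converted through
#' `config$pixel_spacing_mm`). Speckle is drawn independently per frame from
#' seeds derived from `seed`.
#'
#' @param config A [phantom_config()]; its `deep_row` is overridden per frame.
#' @param mt_trajectory Numeric vector of target thicknesses in mm, one per
#'   frame.
#' @param seed Integer base seed.
#'
#' @return A list with `frames` (list of image matrices) and `truth` (tibble,
#'   one row per frame with a `frame` column, 1-based).
#' @export
phantom_sequence <- function(config = phantom_config(), mt_trajectory,
                             seed = 1L) {
  n <- length(mt_trajectory)
  if (n == 0) {
    return(list(frames = list(), truth = tibble::tibble(
      frame = integer(), rho1 = numeric(), theta1 = numeric(),
      rho2 = numeric(), theta2 = numeric(),
      mt_px = numeric(), mt_mm = numeric()
    )))
  }
  mt_px <- mt_trajectory / config$pixel_spacing_mm
  deep <- config$superficial_row + mt_px
  if (any(deep >= config$height - 2 * config$band_halfwidth)) {
    stop("phantom_sequence: trajectory places the deep aponeurosis outside ",
         "the image", call. = FALSE)
  }
  out <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$deep_row <- deep[i]
    ph <- phantom_image(cfg_i, seed = as.integer(seed) + i - 1L)
    out[[i]] <- ph$image
    truths[[i]] <- dplyr::mutate(ph$truth, frame = i, .before = 1)
  }
  list(frames = out, truth = dplyr::bind_rows(truths))
}
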