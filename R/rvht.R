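#' Hough accumulator for straight lines
#'
#' Standard (rho, theta) Hough accumulation over an edge map. Pixel
#' coordinates are 0-based, `x` = column, `y` = row (increasing downward); a
#' pixel lies on line `(rho, theta)` when `x cos(theta) + y sin(theta) = rho`.
#' Theta bins cover `[0, pi)` at `theta_step`; rho bins cover `[-D, D]`
#' (`D` = image diagonal) at `rho_step`. Every on-pixel casts exactly one vote
#' per theta bin, into the nearest rho bin, so the accumulator total is always
#' `n_on * n_theta_bins`.
#'
#' @param edge An [binarize()] `edge_map` (or logical matrix).
#' @param rho_step Rho bin width in pixels, > 0.
#' @param theta_step Theta bin width in radians, > 0.
#'
#' @return A list of class `hough_accumulator`: `counts` (n_rho x n_theta
#'   integer matrix), bin centre vectors `rho` and `theta`, and the steps.
#' @export
hough_accumulate <- function(edge, rho_step = 1, theta_step = pi / 180) {
  edge <- as_edge_map(edge)
  if (rho_step <= 0 || theta_step <= 0) {
    stop("rho_step and theta_step must be positive", call. = FALSE)
  }
  h <- nrow(edge$mask); w <- ncol(edge$mask)
  grid <- hough_grid(h, w, rho_step, theta_step)
  counts <- matrix(0L, length(grid$rho), length(grid$theta))
  if (edge$n_on > 0) {
    on <- which(edge$mask, arr.ind = TRUE)
    x <- on[, 2] - 1
    y <- on[, 1] - 1
    for (j in seq_along(grid$theta)) {
      r <- x * cos(grid$theta[j]) + y * sin(grid$theta[j])
      bin <- as.integer(round((r - grid$rho_min) / rho_step)) + 1L
      counts[, j] <- tabulate(bin, nbins = length(grid$rho))
    }
  }
  structure(list(counts = counts, rho = grid$rho, theta = grid$theta,
                 rho_step = rho_step, theta_step = theta_step,
                 dim = c(h, w)),
            class = "hough_accumulator")
}

hough_grid <- function(h, w, rho_step, theta_step) {
  d <- ceiling(sqrt((h - 1)^2 + (w - 1)^2))
  rho_min <- -d
  n_rho <- floor(2 * d / rho_step) + 1L
  list(rho = rho_min + (seq_len(n_rho) - 1L) * rho_step,
       rho_min = rho_min,
       theta = (seq_len(max(1L, floor(pi / theta_step))) - 1L) * theta_step)
}

as_edge_map <- function(edge) {
  if (inherits(edge, "edge_map")) return(edge)
  if (is.logical(edge) && is.matrix(edge)) return(new_edge_map(edge))
  stop("expected an edge_map or a logical matrix", call. = FALSE)
}

#' Global peak of a Hough accumulator
#'
#' Returns the line at the maximal accumulator bin. Ties are broken
#' deterministically: smallest theta bin first, then smallest rho bin.
#'
#' @param acc A [hough_accumulate()] result.
#'
#' @return One-row tibble with `rho`, `theta`, `votes`.
#' @export
hough_peak <- function(acc) {
  mx <- max(acc$counts)
  if (mx == 0) {
    stop("empty accumulator: no line can be detected", call. = FALSE)
  }
  hits <- which(acc$counts == mx, arr.ind = TRUE)
  k <- order(hits[, 2], hits[, 1])[1]
  tibble::tibble(rho = acc$rho[hits[k, 1]],
                 theta = acc$theta[hits[k, 2]],
                 votes = as.integer(mx))
}

#' Remove edge pixels close to a detected line
#'
#' Turns off every on-pixel whose perpendicular distance to the line,
#' `|x cos(theta) + y sin(theta) - rho|`, is at most `halfwidth`. This is the
#' "revoting" step: the pruned map is re-accumulated to find the next line.
#'
#' @param edge An `edge_map`.
#' @param line One-row data frame (or list) with `rho` and `theta`.
#' @param halfwidth Removal half-width in pixels, >= 0.
#'
#' @return A new `edge_map` with `n_on` less than or equal to the input's.
#' @export
remove_line_pixels <- function(edge, line, halfwidth = 3) {
  edge <- as_edge_map(edge)
  if (halfwidth < 0) stop("halfwidth must be >= 0", call. = FALSE)
  if (edge$n_on == 0) return(edge)
  mask <- edge$mask
  on <- which(mask, arr.ind = TRUE)
  d <- abs((on[, 2] - 1) * cos(line$theta) + (on[, 1] - 1) * sin(line$theta) -
             line$rho)
  mask[on[d <= halfwidth, , drop = FALSE]] <- FALSE
  new_edge_map(mask, threshold = edge$threshold)
}

#' Revoting Hough transform line detection
#'
#' Detects up to `n_lines` dominant lines by iterating: accumulate the full
#' Hough transform of the current edge map, take the global peak, then remove
#' all edge pixels within `halfwidth` of the detected line and re-accumulate.
#' Because removal only deletes votes, the vote counts of successive lines are
#' non-increasing. Stops early (returning fewer lines) if the edge map empties.
#'
#' @param edge An `edge_map` (or logical matrix).
#' @param n_lines Number of lines to search for, >= 1.
#' @param rho_step,theta_step Accumulator quantization; defaults 1 px and 1
#'   degree.
#' @param halfwidth Removal half-width in pixels. The default (6) covers the
#'   full thickness a few-pixel aponeurosis band reaches after enhancement and
#'   binarization; a removal narrower than the binarized band leaves a
#'   residual strip of the same structure that wins the next vote.
#'
#' @return Tibble with one row per detected line: `rho`, `theta`, `votes`.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[3, ] <- TRUE; m[9, ] <- TRUE
#' rvht_detect(m, n_lines = 2)
#' @export
rvht_detect <- function(edge, n_lines = 2L, rho_step = 1,
                        theta_step = pi / 180, halfwidth = 6) {
  if (n_lines < 1) stop("n_lines must be >= 1", call. = FALSE)
  edge <- as_edge_map(edge)
  lines <- vector("list", n_lines)
  for (i in seq_len(n_lines)) {
    if (edge$n_on == 0) break
    acc <- hough_accumulate(edge, rho_step, theta_step)
    ln <- hough_peak(acc)
    lines[[i]] <- ln
    edge <- remove_line_pixels(edge, ln, halfwidth)
  }
  found <- dplyr::bind_rows(lines)
  if (nrow(found) == 0) {
    found <- tibble::tibble(rho = numeric(), theta = numeric(),
                            votes = integer())
  }
  found
}
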