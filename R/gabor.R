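#' Block-wise ridge orientation from gradient second moments
#'
#' Estimates a dominant local orientation for every non-overlapping
#' `block_size` x `block_size` block from the gradient structure tensor:
#' with block sums `Gxx = sum(gx^2)`, `Gyy = sum(gy^2)`, `Gxy = sum(gx gy)`,
#' the ridge orientation is `0.5 * atan2(2 Gxy, Gxx - Gyy) + pi/2` (mod pi) and
#' the coherence (orientation reliability) is
#' `sqrt((Gxx - Gyy)^2 + 4 Gxy^2) / (Gxx + Gyy)`, defined as 0 for blocks with
#' no gradient energy. Orientations are undirected, wrapping modulo pi; a
#' horizontal ridge has orientation 0.
#'
#' @param image Numeric matrix in [0, 1].
#' @param block_size Block side in pixels, >= 3.
#'
#' @return A list of class `orientation_field` with matrices `theta` (radians
#'   in [0, pi)) and `coherence` (in [0, 1]), one entry per block, plus
#'   `block_size`.
#' @export
estimate_orientation <- function(image, block_size = 16L) {
  block_size <- as.integer(block_size)
  if (block_size < 3) stop("block_size must be >= 3", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  nby <- h %/% block_size; nbx <- w %/% block_size
  if (nby < 1 || nbx < 1) {
    stop("image smaller than one block", call. = FALSE)
  }
  g <- image_gradients(image)
  # per-block sums via index folding
  hh <- nby * block_size; ww <- nbx * block_size
  fold <- function(m) {
    m <- m[seq_len(hh), seq_len(ww), drop = FALSE]
    br <- (seq_len(hh) - 1L) %/% block_size
    bc <- (seq_len(ww) - 1L) %/% block_size
    idx <- outer(br, bc, function(r, c) r + nby * c) + 1L
    matrix(rowsum(as.vector(m), as.vector(idx)), nby, nbx)
  }
  gxx <- fold(g$gx^2); gyy <- fold(g$gy^2); gxy <- fold(g$gx * g$gy)
  denom <- gxx + gyy
  # blocks with no gradient energy (constant up to round-off) have no
  # orientation: coherence is defined as 0 there
  flat <- denom <= block_size^2 * 1e-16
  coh <- ifelse(flat, 0, sqrt((gxx - gyy)^2 + 4 * gxy^2) / denom)
  theta <- (0.5 * atan2(2 * gxy, gxx - gyy) + pi / 2) %% pi
  theta[flat] <- 0
  structure(list(theta = theta, coherence = coh, block_size = block_size),
            class = "orientation_field")
}

# Gaussian-derivative gradient estimator (sigma 1): regularizes the structure
# tensor against speckle, which bare central differences inflate isotropically.
image_gradients <- function(image, sigma = 1) {
  r <- max(2L, ceiling(3 * sigma))
  t <- seq(-r, r)
  g0 <- exp(-t^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  g1 <- -t / sigma^2 * g0
  g1 <- g1 - mean(g1)  # zero-sum: constants have exactly zero gradient
  list(gx = EBImage::filter2(image, outer(g0, g1), boundary = "replicate"),
       gy = EBImage::filter2(image, outer(g1, g0), boundary = "replicate"))
}

#' Block-wise ridge frequency from the across-ridge signature
#'
#' For each block whose coherence passes `min_coherence`, intensities in a
#' window around the block are projected onto the axis orthogonal to the local
#' ridge orientation (the "x-signature"); the dominant spatial frequency is
#' the reciprocal of the mean spacing between signature peaks. Blocks with
#' fewer than two detectable peaks, a period outside `(2, 1/min_freq]` pixels,
#' or insufficient coherence are marked invalid.
#'
#' @param image Numeric matrix.
#' @param orient An `orientation_field` computed on the same block grid.
#' @param block_size Block side in pixels (must match `orient`).
#' @param min_coherence Coherence below which a block is not analysed.
#'
#' @return A list of class `frequency_map` with matrices `freq`
#'   (cycles/pixel, NA where invalid) and `valid` (logical).
#' @export
estimate_frequency <- function(image, orient, block_size = 16L,
                               min_coherence = 0.1) {
  block_size <- as.integer(block_size)
  if (!inherits(orient, "orientation_field") ||
      orient$block_size != block_size) {
    stop("orient must be an orientation_field on the same block grid",
         call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  nby <- nrow(orient$theta); nbx <- ncol(orient$theta)
  freq <- matrix(NA_real_, nby, nbx)
  valid <- matrix(FALSE, nby, nbx)
  half <- block_size  # analysis window extends half a block beyond each side
  for (bi in seq_len(nby)) {
    for (bj in seq_len(nbx)) {
      if (orient$coherence[bi, bj] < min_coherence) next
      r0 <- (bi - 1L) * block_size + 1L
      c0 <- (bj - 1L) * block_size + 1L
      rows <- max(1L, r0 - half %/% 2):min(h, r0 + block_size - 1L + half %/% 2)
      cols <- max(1L, c0 - half %/% 2):min(w, c0 + block_size - 1L + half %/% 2)
      f <- signature_frequency(image[rows, cols, drop = FALSE],
                               orient$theta[bi, bj])
      if (!is.na(f) && f > 0 && f <= 0.5) {
        freq[bi, bj] <- f
        valid[bi, bj] <- TRUE
      }
    }
  }
  structure(list(freq = freq, valid = valid, block_size = block_size),
            class = "frequency_map")
}

# Dominant frequency of the projection of a patch onto the axis orthogonal to
# ridge orientation theta; NA when no periodicity is detectable.
signature_frequency <- function(patch, theta) {
  h <- nrow(patch); w <- ncol(patch)
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  proj <- -x * sin(theta) + y * cos(theta)
  k <- round(proj - min(proj)) + 1L
  s <- as.vector(rowsum(as.vector(patch), as.vector(k)) /
                   tabulate(as.vector(k)))
  n <- length(s)
  if (n < 5) return(NA_real_)
  s <- s - mean(s)
  # 3-tap smoothing to stabilise peak picking under speckle
  sm <- stats::filter(s, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  i <- 2:(n - 1)
  pk <- i[sm[i] > sm[i - 1] & sm[i] >= sm[i + 1] & sm[i] > 0]
  if (length(pk) < 2) return(NA_real_)
  period <- mean(diff(pk))
  if (period < 2) return(NA_real_)
  1 / period
}

#' Reliability-gated Gabor enhancement
#'
#' Enhances coherently oriented tubular structure: each block with orientation
#' coherence at or above `reliability_threshold` is filtered with an
#' even-symmetric, zero-mean Gabor kernel tuned to the block's orientation and
#' ridge frequency; blocks below the threshold are zeroed (ignored). Blocks
#' that pass the coherence gate but have no measurable frequency (typical on a
#' strong but aperiodic ridge such as an aponeurosis) are filtered with the
#' median frequency of the valid blocks. The response is clamped at zero and
#' rescaled to [0, 1].
#'
#' @param image Numeric matrix in [0, 1].
#' @param block_size Block side in pixels.
#' @param sigma_x,sigma_y Gaussian envelope sigmas of the kernel, pixels.
#' @param reliability_threshold Coherence gate in [0, 1]; default 0.5.
#'
#' @return Numeric matrix, same dimensions, values in [0, 1].
#' @export
gabor_enhance <- function(image, block_size = 16L, sigma_x = 4, sigma_y = 4,
                          reliability_threshold = 0.5) {
  if (reliability_threshold < 0 || reliability_threshold > 1) {
    stop("reliability_threshold must be in [0, 1]", call. = FALSE)
  }
  orient <- estimate_orientation(image, block_size)
  fmap <- estimate_frequency(image, orient, block_size, min_coherence = 0.1)
  pass <- orient$coherence >= reliability_threshold
  out <- matrix(0, nrow(image), ncol(image))
  if (!any(pass)) return(out)

  freq <- fmap$freq
  if (any(fmap$valid)) {
    freq[!fmap$valid] <- stats::median(freq[fmap$valid])
  } else {
    # no periodicity anywhere: fall back to the envelope's own bandwidth
    freq[] <- 1 / (4 * sigma_x)
  }

  # quantize (orientation, period) so one full-image convolution serves all
  # blocks sharing a kernel
  n_orient <- 16L
  th_q <- (round(orient$theta / (pi / n_orient)) %% n_orient) * (pi / n_orient)
  per_q <- pmax(3L, pmin(64L, as.integer(round(1 / freq))))
  nby <- nrow(pass); nbx <- ncol(pass)
  combos <- unique(data.frame(th = as.vector(th_q)[as.vector(pass)],
                              per = as.vector(per_q)[as.vector(pass)]))
  h <- nrow(image); w <- ncol(image)
  hh <- nby * block_size; ww <- nbx * block_size
  for (ci in seq_len(nrow(combos))) {
    kern <- gabor_kernel(combos$th[ci], 1 / combos$per[ci], sigma_x, sigma_y)
    resp <- EBImage::filter2(image, kern, boundary = "replicate")
    sel <- pass & th_q == combos$th[ci] & per_q == combos$per[ci]
    for (bi in seq_len(nby)) {
      for (bj in seq_len(nbx)) {
        if (!sel[bi, bj]) next
        rows <- ((bi - 1L) * block_size + 1L):(bi * block_size)
        cols <- ((bj - 1L) * block_size + 1L):(bj * block_size)
        # last block row/column absorbs the remainder pixels
        if (bi == nby) rows <- c(rows, seq_len(h - hh) + hh)
        if (bj == nbx) cols <- c(cols, seq_len(w - ww) + ww)
        out[rows, cols] <- resp[rows, cols]
      }
    }
  }
  out <- pmax(out, 0)
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out
}

# Even-symmetric zero-mean Gabor kernel; theta is the ridge orientation, so
# the cosine modulates along the orthogonal (across-ridge) axis.
gabor_kernel <- function(theta, freq, sigma_x = 4, sigma_y = 4) {
  r <- ceiling(3 * max(sigma_x, sigma_y))
  g <- seq(-r, r)
  x <- matrix(rep(g, each = length(g)), length(g))   # column offset
  y <- matrix(rep(g, times = length(g)), length(g))  # row offset
  u <- -x * sin(theta) + y * cos(theta)  # across-ridge
  v <- x * cos(theta) + y * sin(theta)   # along-ridge
  k <- exp(-0.5 * (u^2 / sigma_x^2 + v^2 / sigma_y^2)) * cos(2 * pi * freq * u)
  k - mean(k)
}
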