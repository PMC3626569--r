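#' Scale-normalized Hessian eigenvalues
#'
#' Computes the 2x2 Hessian at every pixel by convolution with Gaussian
#' second-derivative kernels at scale `sigma`, normalized by `sigma^2`
#' (gamma = 1), and returns the eigenvalue fields ordered by magnitude,
#' `|lambda1| <= |lambda2|`.
#'
#' @param image Numeric matrix.
#' @param sigma Gaussian scale in pixels, > 0.
#'
#' @return A list of class `hessian_eigen` with matrices `lambda1`, `lambda2`
#'   and the `sigma` used.
#' @export
hessian_eigen <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  r <- max(2L, ceiling(4 * sigma))
  # the convolution kernel cannot exceed the image
  r <- min(r, (min(dim(image)) - 1L) %/% 2L)
  if (r < 2) stop("image too small for Hessian estimation", call. = FALSE)
  t <- seq(-r, r)
  g0 <- exp(-t^2 / (2 * sigma^2))
  g0 <- g0 / sum(g0)
  g1 <- -t / sigma^2 * g0
  g1 <- g1 - mean(g1)
  # zero-sum so the sampled kernel annihilates constants exactly
  g2 <- (t^2 - sigma^2) / sigma^4 * g0
  g2 <- g2 - mean(g2)
  conv <- function(kr, kc) {
    # outer(row kernel, column kernel): rows vary down (y), columns across (x)
    EBImage::filter2(image, outer(kr, kc), boundary = "replicate")
  }
  s2 <- sigma^2
  ixx <- conv(g0, g2) * s2
  iyy <- conv(g2, g0) * s2
  ixy <- conv(g1, g1) * s2
  mu <- (ixx + iyy) / 2
  d <- sqrt(((ixx - iyy) / 2)^2 + ixy^2)
  e1 <- mu + d
  e2 <- mu - d
  swap <- abs(e1) > abs(e2)
  lambda1 <- ifelse(swap, e2, e1)
  lambda2 <- ifelse(swap, e1, e2)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, sigma = sigma),
            class = "hessian_eigen")
}

#' Frangi vesselness response at a single scale
#'
#' Bright-structure (negative `lambda2`) vesselness: with blobness ratio
#' `R_B = lambda1 / lambda2` and structureness `S = sqrt(lambda1^2 +
#' lambda2^2)`, the response is
#' `exp(-R_B^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, and 0 wherever
#' `lambda2 >= 0`.
#'
#' @param eig A [hessian_eigen()] result.
#' @param beta Blobness weight, > 0.
#' @param c Structureness weight; `NULL` auto-tunes to half the maximum
#'   Frobenius norm of the Hessian over the image at this scale.
#'
#' @return Numeric matrix in [0, 1].
#' @export
vesselness <- function(eig, beta = 0.5, c = NULL) {
  if (!inherits(eig, "hessian_eigen")) {
    stop("eig must come from hessian_eigen()", call. = FALSE)
  }
  if (beta <= 0) stop("beta must be > 0", call. = FALSE)
  l1 <- eig$lambda1
  l2 <- eig$lambda2
  s <- sqrt(l1^2 + l2^2)
  if (is.null(c)) c <- max(s) / 2
  # no structure anywhere (constant image up to round-off): zero response
  if (c <= 1e-12) return(matrix(0, nrow(l1), ncol(l1)))
  rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s^2 / (2 * c^2)))
  v[l2 >= 0] <- 0
  v
}

#' Multiscale vessel enhancement filtering
#'
#' Pixel-wise maximum of the Frangi vesselness response over a set of Gaussian
#' scales; the standard multiscale ridge enhancement for bright tubular
#' structures such as aponeuroses and fascicles in B-mode ultrasound.
#'
#' @param image Numeric matrix in [0, 1].
#' @param scales Gaussian sigmas in pixels, all > 0.
#' @param beta Blobness weight.
#' @param c Structureness weight; `NULL` auto-tunes per scale.
#'
#' @return Numeric matrix in [0, 1], same dimensions as `image`.
#' @export
mvef_enhance <- function(image, scales = c(1.5, 3, 5, 7), beta = 0.5,
                         c = NULL) {
  if (length(scales) == 0 || any(scales <= 0)) {
    stop("scales must be a nonempty vector of positive sigmas", call. = FALSE)
  }
  out <- matrix(0, nrow(image), ncol(image))
  for (s in scales) {
    out <- pmax(out, vesselness(hessian_eigen(image, s), beta = beta, c = c))
  }
  out
}
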