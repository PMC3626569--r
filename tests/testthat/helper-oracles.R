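# Shared fixtures and independent oracles used across the test files.

# Small phantom used by pipeline-level tests: 256 px wide so a full run stays
# fast while the geometry (band thickness, fascicle period) matches defaults.
test_phantom_config <- function(mt_px = 140, speckle = 0, ...) {
  phantom_config(height = 256, width = 256, superficial_row = 30,
                 deep_row = 30 + mt_px, speckle_scale = speckle, ...)
}

# Brute-force Hough oracle: explicit loop over the discretized (rho, theta)
# grid, scoring each cell by the number of on-pixels whose nearest rho bin at
# that theta is the cell. Independent of the package's vectorized accumulator.
oracle_hough_counts <- function(mask, rho_step = 1, theta_step = pi / 180) {
  h <- nrow(mask); w <- ncol(mask)
  d <- ceiling(sqrt((h - 1)^2 + (w - 1)^2))
  n_rho <- floor(2 * d / rho_step) + 1
  thetas <- (seq_len(floor(pi / theta_step)) - 1) * theta_step
  rhos <- -d + (seq_len(n_rho) - 1) * rho_step
  on <- which(mask, arr.ind = TRUE)
  counts <- matrix(0L, n_rho, length(thetas))
  for (j in seq_along(thetas)) {
    for (p in seq_len(nrow(on))) {
      r <- (on[p, 2] - 1) * cos(thetas[j]) + (on[p, 1] - 1) * sin(thetas[j])
      i <- as.integer(round((r - (-d)) / rho_step)) + 1L
      counts[i, j] <- counts[i, j] + 1L
    }
  }
  list(counts = counts, rho = rhos, theta = thetas)
}

# Oracle peak with the same deterministic tie rule the implementation
# documents: smallest theta bin, then smallest rho bin.
oracle_hough_peak <- function(oc) {
  mx <- max(oc$counts)
  hits <- which(oc$counts == mx, arr.ind = TRUE)
  k <- order(hits[, 2], hits[, 1])[1]
  c(rho = oc$rho[hits[k, 1]], theta = oc$theta[hits[k, 2]], votes = mx)
}

# Independent ICC(A,1) oracle built on stats::aov mean squares rather than the
# package's closed-form sums of squares.
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(
    value = as.vector(m),
    row = factor(rep(seq_len(n), times = k)),
    col = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(value ~ row + col, data = long))[[1]]
  msr <- tab["row", "Mean Sq"]
  msc <- tab["col", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Oriented sinusoidal stripe fixture: ridges run at angle `a` (radians) from
# horizontal in image coordinates (row index downward), period `p` pixels.
stripe_image <- function(n = 96, a = 0, p = 8) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  u <- x * sin(a) - y * cos(a)
  0.5 + 0.4 * cos(2 * pi * u / p)
}

# Circular difference between two orientations (mod pi).
angle_diff <- function(t1, t2) {
  d <- abs(t1 - t2) %% pi
  pmin(d, pi - d)
}
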