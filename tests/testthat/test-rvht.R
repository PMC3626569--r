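test_that("accumulation conserves votes and honours the line convention", {
  # a single on-pixel votes once in each of the 180 theta bins
  m <- matrix(FALSE, 16, 16)
  m[7, 11] <- TRUE
  acc <- hough_accumulate(m)
  expect_equal(sum(acc$counts), 180)
  expect_length(acc$theta, 180)

  # vertical segment at column x = 5 (0-based), rows 0..9: peak (rho 5,
  # theta 0) with 10 votes
  v <- matrix(FALSE, 16, 16)
  v[1:10, 6] <- TRUE
  accv <- hough_accumulate(v)
  expect_equal(sum(accv$counts), 10 * 180)
  pk <- hough_peak(accv)
  expect_equal(pk$rho, 5)
  expect_equal(pk$theta, 0)
  expect_equal(pk$votes, 10L)

  # empty map: all-zero accumulator is valid, peak extraction errors
  acc0 <- hough_accumulate(matrix(FALSE, 8, 8))
  expect_equal(sum(acc0$counts), 0)
  expect_error(hough_peak(acc0), "empty")
})

test_that("random edge maps match the brute-force accumulator bin-for-bin", {
  set.seed(101)
  for (rep in 1:3) {
    m <- matrix(FALSE, 24, 24)
    m[sample(24 * 24, 20)] <- TRUE
    acc <- hough_accumulate(m)
    oc <- oracle_hough_counts(m)
    expect_identical(unname(acc$counts), unname(oc$counts))
  }
})

test_that("peak ties break to the smaller theta bin then smaller rho bin", {
  acc <- hough_accumulate(matrix(FALSE, 8, 8))
  acc$counts[5, 10] <- 7L
  acc$counts[3, 20] <- 7L
  pk <- hough_peak(acc)
  expect_equal(pk$theta, acc$theta[10])
  acc$counts[9, 10] <- 7L
  pk2 <- hough_peak(acc)
  expect_equal(pk2$rho, acc$rho[5])
})

test_that("line-pixel removal deletes exactly the close pixels", {
  v <- matrix(FALSE, 16, 16)
  v[1:10, 6] <- TRUE
  em <- binarize(matrix(0, 16, 16) + v, method = "fixed", level = 0.5)
  line <- tibble::tibble(rho = 5, theta = 0)

  # a line through no on-pixels changes nothing
  far <- remove_line_pixels(em, tibble::tibble(rho = 12, theta = 0), 1)
  expect_identical(far$mask, em$mask)

  # the segment's own line at halfwidth 1 clears the map (all distances 0)
  self <- remove_line_pixels(em, line, 1)
  expect_equal(self$n_on, 0)

  # removal is idempotent
  again <- remove_line_pixels(self, line, 1)
  expect_identical(again$mask, self$mask)

  # halfwidth >= diagonal clears any map
  all_gone <- remove_line_pixels(em, tibble::tibble(rho = 0, theta = pi / 4),
                                 halfwidth = 23)
  expect_equal(all_gone$n_on, 0)
})

test_that("revoting recovers two disjoint axis-aligned segments in order", {
  m <- matrix(FALSE, 48, 48)
  m[5, 3:38] <- TRUE   # horizontal segment, 36 px at y = 4
  m[25:36, 9] <- TRUE  # vertical segment, 12 px at x = 8
  lines <- rvht_detect(m, n_lines = 2, halfwidth = 2)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$votes, c(36L, 12L))
  expect_true(all(diff(lines$votes) <= 0))
  expect_lt(abs(lines$rho[1] - 4), 1 + 1e-9)
  expect_lt(angle_diff(lines$theta[1], pi / 2), pi / 180 + 1e-9)
  expect_lt(abs(lines$rho[2] - 8), 1 + 1e-9)
  expect_lt(angle_diff(lines$theta[2], 0), pi / 180 + 1e-9)

  # n_lines = 1 reduces to the standard Hough peak
  one <- rvht_detect(m, n_lines = 1)
  expect_equal(one, hough_peak(hough_accumulate(m)))

  # empty initial map yields an empty result
  expect_equal(nrow(rvht_detect(matrix(FALSE, 8, 8), n_lines = 2)), 0)
})

test_that("every revoting iteration equals the brute-force grid argmax", {
  # oracle equivalence on random small maps, including the revoting step
  set.seed(2024)
  for (rep in 1:5) {
    m <- matrix(FALSE, 20, 20)
    m[sample(400, 30)] <- TRUE
    detected <- rvht_detect(m, n_lines = 2, halfwidth = 2)
    # replay the iterations with the oracle
    mask <- m
    for (i in seq_len(nrow(detected))) {
      pk <- oracle_hough_peak(oracle_hough_counts(mask))
      expect_equal(detected$rho[i], unname(pk["rho"]))
      expect_equal(detected$theta[i], unname(pk["theta"]))
      expect_equal(as.numeric(detected$votes[i]), unname(pk["votes"]))
      on <- which(mask, arr.ind = TRUE)
      d <- abs((on[, 2] - 1) * cos(pk["theta"]) +
                 (on[, 1] - 1) * sin(pk["theta"]) - pk["rho"])
      mask[on[d <= 2, , drop = FALSE]] <- FALSE
    }
    expect_true(all(diff(detected$votes) <= 0))
  }
})

test_that("enhanced phantoms yield the aponeuroses as the first two lines", {
  cfg <- test_phantom_config(mt_px = 140, speckle = 0)
  ph <- phantom_image(cfg, seed = 1)
  truth_rho <- c(ph$truth$rho1, ph$truth$rho2)
  truth_theta <- c(ph$truth$theta1, ph$truth$theta2)

  # Every on-row of a full-width horizontal band ties at the true theta, so
  # the bin-centre line is only determined to about half the thickness the
  # band binarizes to; theta is localized to one bin.
  for (method in c("gabor", "mvef")) {
    enh <- if (method == "gabor") gabor_enhance(ph$image) else
      mvef_enhance(ph$image)
    em <- binarize(enh)
    half_thick <- max(colSums(em$mask[1:(cfg$superficial_row + 20), ])) / 2
    ln <- rvht_detect(em, n_lines = 2)
    ln <- ln[order(ln$rho), ]
    expect_true(all(abs(ln$rho - truth_rho) <= half_thick + 1),
                label = sprintf("%s rho localization", method))
    expect_true(all(angle_diff(ln$theta, truth_theta) <= pi / 180 + 1e-9),
                label = sprintf("%s theta localization", method))
  }
})
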