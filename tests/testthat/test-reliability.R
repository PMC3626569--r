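test_that("icc_a1 matches the ANOVA oracle digit for digit", {
  tab <- matrix(c(41.2, 42.8, 40.1, 43.5, 41.9, 40.6,
                  41.0, 43.1, 40.5, 43.0, 42.3, 40.2), ncol = 2)
  fit <- icc_a1(tab)
  expect_equal(fit$icc, oracle_icc_a1(tab), tolerance = 1e-12)
  expect_true(fit$ci_low <= fit$icc && fit$icc <= fit$ci_high)
})

test_that("icc_a1 agrees with the ANOVA oracle on random tables", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:25, 1); k <- sample(2:5, 1)
    subject <- rnorm(n, 40, 2)
    m <- matrix(rnorm(n * k, 0, runif(1, 0.1, 2)), n, k) + subject
    m <- m + matrix(rnorm(k, 0, 0.5), n, k, byrow = TRUE)  # rater bias
    expect_equal(icc_a1(m)$icc, oracle_icc_a1(m), tolerance = 1e-6)
  }
})

test_that("icc_a1 handles agreement extremes and degenerate input", {
  x <- rnorm(10, 40, 2)
  expect_equal(icc_a1(cbind(x, x))$icc, 1)
  expect_error(icc_a1(matrix(5, 6, 2)), "degenerate")
  expect_error(icc_a1(matrix(rnorm(4), 1, 4)), "at least 2")

  # pure noise columns with no subject effect: ICC near 0 on average
  set.seed(21)
  iccs <- replicate(1000, icc_a1(matrix(rnorm(40), 20, 2))$icc)
  expect_lt(abs(mean(iccs)), 0.05)
})

test_that("icc_a1 is shift-invariant and scale-equivariant", {
  set.seed(9)
  m <- matrix(rnorm(24, 40, 2), 12, 2) + rnorm(12, 0, 1.5)
  base <- icc_a1(m)$icc
  expect_equal(icc_a1(m + 100)$icc, base, tolerance = 1e-10)
  expect_equal(icc_a1(m * 3.7)$icc, base, tolerance = 1e-10)
})

test_that("SEM and MDC reproduce their closed forms and printed values", {
  # closed forms
  expect_equal(sem(1, 0.75), 0.5)
  expect_equal(sem(3, 1), 0)
  expect_equal(mdc(0), 0)
  expect_equal(mdc(1), 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(mdc(1), 3), 2.772)

  # measured subject-level values: SD 1.63 mm with ICC 0.953 gives SEM 0.35
  # and MDC 0.97 under the rounded-SEM convention
  expect_equal(round(sem(1.63, 0.953), 2), 0.35)
  expect_equal(round(mdc(round(sem(1.63, 0.953), 2)), 2), 0.97)

  # degree-1 homogeneity in sd
  expect_equal(sem(2 * 1.2, 0.9), 2 * sem(1.2, 0.9))
  expect_equal(mdc(2 * 0.4), 2 * mdc(0.4))
  # MDC decreases as reliability rises at fixed sd
  iccs <- c(0.5, 0.8, 0.95, 0.99)
  expect_true(all(diff(mdc(sem(1.5, iccs))) < 0))

  expect_error(sem(1, 1.2), "icc")
  expect_error(sem(-1, 0.5), "sd")
})

test_that("bland_altman recovers bias and limits of agreement", {
  a <- c(40.2, 41.5, 39.8, 42.0)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  # constant offset: bias exactly -1.4, zero spread
  ba1 <- bland_altman(a, a + 1.4)
  expect_equal(ba1$bias, -1.4)
  expect_equal(ba1$sd_diff, 0)

  # simulation with the agreement structure of automatic-vs-manual readings
  set.seed(33)
  n <- 300
  manual <- rnorm(n, 42, 1.6)
  auto <- manual - 1.45 + rnorm(n, 0, 0.48)
  ba <- bland_altman(manual, auto)
  expect_lt(abs(ba$bias - 1.45), 3 * 0.48 / sqrt(n))
  td <- tidy(ba)
  expect_equal(td$n, n)
  expect_equal(td$bias, ba$bias)

  expect_error(bland_altman(1:4, 1:5), "equal length")
})

test_that("pearson_r2 behaves on exact, independent and sign-flipped data", {
  a <- rnorm(50, 40, 2)
  expect_equal(pearson_r2(a, 2 * a + 1), 1)
  expect_equal(pearson_r2(a, -a), 1)
  set.seed(5)
  expect_lt(pearson_r2(rnorm(1000), rnorm(1000)), 0.01)
  expect_error(pearson_r2(a, rep(1, 50)), "zero variance")
  expect_error(pearson_r2(1:2, 1:2), "length")
})

test_that("reliability_report summarises per subject and pooled", {
  set.seed(17)
  sim_subject <- function(id, mu) {
    truth <- rnorm(60, mu, 1.6)
    tibble::tibble(
      subject = id,
      frame = rep(1:60, 2),
      rater = rep(c("m1", "m2"), each = 60),
      mt_mm = c(truth + rnorm(60, 0, 0.3), truth + rnorm(60, 0, 0.3))
    )
  }
  dat <- dplyr::bind_rows(sim_subject("S1", 42), sim_subject("S2", 41.6),
                          sim_subject("S3", 40.8))
  rep_tab <- reliability_report(dat)
  expect_equal(rep_tab$group, c("S1", "S2", "S3", "Overall"))
  expect_true(all(rep_tab$icc > 0.8))
  expect_true(all(rep_tab$sem > 0))
  # mdc follows the rounded-SEM convention by default
  expect_equal(rep_tab$mdc, round(rep_tab$sem, 2) * 1.96 * sqrt(2))
  expect_true(all(rep_tab$mdc_pct > 0 & rep_tab$mdc_pct < 10))

  # a group with a single frame is skipped with a warning
  tiny <- tibble::tibble(subject = "S9", frame = 1,
                         rater = c("m1", "m2"), mt_mm = c(40, 41))
  expect_warning(out <- reliability_report(dplyr::bind_rows(dat, tiny)),
                 "skipped")
  expect_false("S9" %in% out$group)
})
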