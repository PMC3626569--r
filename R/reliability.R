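#' Intraclass correlation ICC(A,1): single-measure, absolute agreement
#'
#' Two-way model ICC for an n-targets by k-raters table, the model used to
#' assess agreement between repeated thickness readings. From the two-way
#' ANOVA mean squares (rows `MSR`, columns `MSC`, error `MSE`):
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the standard F-based confidence interval for single-measure absolute
#' agreement (McGraw-Wong two-way case, Satterthwaite degrees of freedom).
#'
#' @param table Numeric matrix or data frame, rows = targets (frames),
#'   columns = raters/methods; n >= 2, k >= 2, no missing values.
#' @param confidence Confidence level, default 0.95.
#'
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, the mean squares, `n`,
#'   `k`.
#' @examples
#' set.seed(1)
#' truth <- rnorm(12, 40, 2)
#' tab <- cbind(truth + rnorm(12, 0, 0.3), truth + rnorm(12, 0, 0.3))
#' icc_a1(tab)
#' @export
icc_a1 <- function(table, confidence = 0.95) {
  m <- as.matrix(table)
  if (any(is.na(m))) stop("ratings table must have no missing values",
                          call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 targets and 2 raters",
                           call. = FALSE)
  gm <- mean(m)
  if (all(m == gm)) stop("degenerate data: zero total variance", call. = FALSE)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - gm)^2)
  ssc <- n * sum((col_m - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - confidence
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  tibble::tibble(icc = icc, ci_low = lo, ci_high = hi,
                 msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Standard error of measurement
#'
#' `SEM = sd * sqrt(1 - ICC)`: the within-subject measurement noise implied by
#' an observed standard deviation and reliability.
#'
#' @param sd Standard deviation of the measurements, mm (>= 0).
#' @param icc Reliability coefficient, <= 1.
#' @return SEM in mm (vectorized).
#' @examples
#' sem(1.63, 0.953) # 0.35 to 2 d.p.
#' @export
sem <- function(sd, icc) {
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(icc > 1)) stop("icc must be <= 1", call. = FALSE)
  sd * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC = SEM * 1.96 * sqrt(2)`: the smallest change between two measurements
#' that exceeds measurement noise with 95% confidence.
#'
#' @param sem_value SEM in mm (>= 0).
#' @return MDC in mm (vectorized).
#' @examples
#' mdc(0.35) # 0.97 to 2 d.p.
#' @export
mdc <- function(sem_value) {
  if (any(sem_value < 0)) stop("sem_value must be >= 0", call. = FALSE)
  sem_value * 1.96 * sqrt(2)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference), SD of differences and 95% limits of agreement
#' `bias +/- 1.96 sd` for two paired measurement series.
#'
#' @param a,b Numeric vectors of equal length >= 2 (mm).
#' @return Object of class `bland_altman`; [tidy()] gives a one-row tibble
#'   (`bias`, `sd_diff`, `loa_low`, `loa_high`, `n`), [autoplot()] draws the
#'   mean-difference plot.
#' @examples
#' ba <- bland_altman(c(40, 41, 42, 43), c(41.4, 42.3, 43.5, 44.4))
#' tidy(ba)
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length",
                                   call. = FALSE)
  if (length(a) < 2) stop("need at least 2 paired values", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    data = tibble::tibble(mean = (a + b) / 2, difference = d)
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f mm (SD %.3f), LoA [%.3f, %.3f]\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 n = nrow(x$data))
}

#' Squared Pearson correlation between two measurement series
#'
#' @param a,b Numeric vectors, equal length >= 3, each with nonzero variance.
#' @return r-squared in [0, 1].
#' @export
pearson_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("a and b must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate data: zero variance", call. = FALSE)
  }
  stats::cor(a, b)^2
}

#' Per-subject and pooled reliability report
#'
#' For each group (subject) and for the pooled data, reports mean, SD,
#' ICC(A,1) with its confidence interval, SEM, MDC, and MDC as a percentage of
#' the mean thickness — the summary table used to characterise measurement
#' reliability per subject.
#'
#' @param data Long-format data frame with one thickness reading per row.
#' @param value Column of readings in mm (default `mt_mm`).
#' @param rater Column identifying the rater/method (default `rater`).
#' @param id Column identifying the target/frame within a group (default
#'   `frame`).
#' @param group Column identifying the subject (default `subject`); groups
#'   with fewer than 2 complete targets are skipped with a warning.
#' @param round_sem If `TRUE` (default), the MDC is computed from the SEM
#'   rounded to 2 decimals, matching how such tables are conventionally
#'   printed; set `FALSE` for full precision.
#' @param confidence Confidence level for the ICC interval.
#'
#' @return Tibble with one row per group plus an `"Overall"` row: `group`,
#'   `n`, `k`, `mean`, `sd`, `icc`, `ci_low`, `ci_high`, `sem`, `mdc`,
#'   `mdc_pct`.
#' @export
reliability_report <- function(data, value = "mt_mm", rater = "rater",
                               id = "frame", group = "subject",
                               round_sem = TRUE, confidence = 0.95) {
  for (col in c(value, rater, id, group)) {
    if (!col %in% names(data)) {
      stop(sprintf("column '%s' not found in data", col), call. = FALSE)
    }
  }
  groups <- unique(data[[group]])
  one <- function(d, label) {
    wide <- tidyr::pivot_wider(
      d[, c(id, rater, value)],
      names_from = dplyr::all_of(rater), values_from = dplyr::all_of(value)
    )
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(m) < 2 || ncol(m) < 2 || any(is.na(m))) {
      warning(sprintf("group '%s': fewer than 2 complete targets, skipped",
                      label))
      return(NULL)
    }
    fit <- icc_a1(m, confidence = confidence)
    s <- stats::sd(as.vector(m))
    se <- sem(s, fit$icc)
    se_for_mdc <- if (round_sem) round(se, 2) else se
    md <- mdc(se_for_mdc)
    tibble::tibble(
      group = label, n = nrow(m), k = ncol(m),
      mean = mean(m), sd = s,
      icc = fit$icc, ci_low = fit$ci_low, ci_high = fit$ci_high,
      sem = se, mdc = md, mdc_pct = 100 * md / mean(m)
    )
  }
  rows <- lapply(groups, function(g) {
    one(data[data[[group]] == g, , drop = FALSE], as.character(g))
  })
  pooled <- data
  # make frame ids unique across groups before pooling
  pooled[[id]] <- paste(pooled[[group]], pooled[[id]], sep = "_")
  rows <- c(rows, list(one(pooled, "Overall")))
  dplyr::bind_rows(rows)
}
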