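#' Plot a muscle-thickness time series
#'
#' Raw per-frame thickness, its running-median smooth, and flagged outlier
#' frames.
#'
#' @param object An `mt_series` from [smooth_mt_series()] (or [run_pipeline()]
#'   with smoothing).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mt_series <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mt_mm), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_mm),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Frame", y = "Muscle thickness (mm)") +
    ggplot2::theme_minimal()
  if (any(object$outlier)) {
    p <- p + ggplot2::geom_point(
      data = object[object$outlier, ],
      ggplot2::aes(y = .data$mt_mm), colour = "firebrick", size = 2
    )
  }
  p
}

#' Bland-Altman mean-difference plot
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot: per-pair mean vs difference with the bias line (solid)
#'   and 95% limits of agreement (dashed).
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Mean of methods (mm)", y = "Difference (mm)") +
    ggplot2::theme_minimal()
}

#' Normal P-P plot of a measurement series
#'
#' Plots empirical cumulative probabilities against the normal CDF fitted by
#' mean and SD — the quick visual normality check used before reliability
#' analysis. No test statistic is computed.
#'
#' @param x Numeric vector.
#' @return A ggplot.
#' @export
plot_pp <- function(x) {
  n <- length(x)
  s <- sort(x)
  emp <- (seq_len(n) - 0.5) / n
  theo <- stats::pnorm(s, mean = mean(x), sd = stats::sd(x))
  ggplot2::ggplot(tibble::tibble(theo = theo, emp = emp),
                  ggplot2::aes(x = .data$theo, y = .data$emp)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Theoretical cumulative probability",
                  y = "Empirical cumulative probability") +
    ggplot2::theme_minimal()
}

#' Overlay detected lines on a frame
#'
#' @param image Numeric matrix in [0, 1].
#' @param lines Tibble of lines (`rho`, `theta`) as returned by
#'   [rvht_detect()], or NULL for the bare image.
#' @return A ggplot raster with the detected lines drawn over it.
#' @export
plot_detection <- function(image, lines = NULL) {
  h <- nrow(image); w <- ncol(image)
  df <- tibble::tibble(
    x = rep(0:(w - 1), each = h),
    y = rep(0:(h - 1), times = w),
    value = as.vector(image)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(lines) && nrow(lines) > 0) {
    segs <- lapply(seq_len(nrow(lines)), function(i) {
      th <- lines$theta[i]; rho <- lines$rho[i]
      if (abs(sin(th)) < 0.1) {
        tibble::tibble(x0 = rho / cos(th), x1 = rho / cos(th),
                       y0 = 0, y1 = h - 1)
      } else {
        x <- c(0, w - 1)
        y <- (rho - x * cos(th)) / sin(th)
        tibble::tibble(x0 = x[1], x1 = x[2], y0 = y[1], y1 = y[2])
      }
    })
    p <- p + ggplot2::geom_segment(
      data = dplyr::bind_rows(segs),
      ggplot2::aes(x = .data$x0, xend = .data$x1,
                   y = .data$y0, yend = .data$y1),
      colour = "yellow", inherit.aes = FALSE
    )
  }
  p
}
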