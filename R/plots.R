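#' Plot an idealized intensity trace
#'
#' Intensity versus time with the Viterbi idealization (scaled to the
#' fitted levels) overlaid.
#'
#' @param object An `ideal_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ideal_trace <- function(object, ...) {
  df <- object$data
  df$ideal <- object$mu[df$state + 1L]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity),
                       color = "grey55", linewidth = 0.3) +
    ggplot2::geom_step(ggplot2::aes(y = .data$ideal), color = "#d62728") +
    ggplot2::labs(x = "time (s)", y = "intensity (counts)") +
    ggplot2::theme_minimal()
}

#' Plot a dwell-time CDF fit
#'
#' Empirical cumulative distribution at unique dwell values with the
#' fitted exponential CDF.
#'
#' @param object An `exp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exp_fit <- function(object, ...) {
  df <- tibble::tibble(x = object$ecdf_x, F = object$ecdf_F,
                       fitted = object$ecdf_F - object$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$F), size = 0.8,
                        color = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "#1f77b4") +
    ggplot2::labs(x = "dwell time (s)", y = "cumulative frequency",
                  subtitle = sprintf("order %d, tau = %.3g s, R2 = %.4f",
                                     object$order, object$tau,
                                     object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot Fano factor versus window length
#'
#' Points at each window length with the chi-square 95% null band for a
#' Poisson process.
#'
#' @param object A `fano_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fano_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$T_s, y = .data$fano)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey40") +
    ggplot2::geom_point(size = 2, color = "#1f77b4") +
    ggplot2::geom_line(color = "#1f77b4") +
    ggplot2::labs(x = "window T (s)", y = "Fano factor") +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-trace median dwell times
#'
#' The classic kinetic-fingerprint scatter: median bound versus median
#' unbound dwell per trace on log scales, optionally colored by
#' acceptance or population label.
#'
#' @param stats Fingerprint tibble (needs `tau_on_median`,
#'   `tau_off_median`; uses `accepted` or `label` for color when
#'   present).
#' @return A ggplot object.
#' @export
plot_fingerprint_scatter <- function(stats) {
  color_var <- if ("label" %in% names(stats)) "label"
               else if ("accepted" %in% names(stats)) "accepted"
               else NULL
  p <- ggplot2::ggplot(stats,
                       ggplot2::aes(x = .data$tau_off_median,
                                    y = .data$tau_on_median))
  p <- if (is.null(color_var)) p + ggplot2::geom_point(alpha = 0.6)
  else p + ggplot2::geom_point(ggplot2::aes(color = .data[[color_var]]),
                               alpha = 0.6)
  p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "median unbound dwell (s)",
                  y = "median bound dwell (s)") +
    ggplot2::theme_minimal()
}

#' Plot a fluctuation map with detected ROIs
#'
#' @param map A `fluctuation_map` matrix.
#' @param rois Optional ROI tibble from [detect_rois()].
#' @return A ggplot object.
#' @export
plot_fluctuation_map <- function(map, rois = NULL) {
  df <- expand.grid(row = seq_len(nrow(map)) - 1L,
                    col = seq_len(ncol(map)) - 1L)
  df$value <- as.vector(map)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "fluctuation") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
  if (!is.null(rois) && nrow(rois))
    p <- p + ggplot2::geom_point(data = rois,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE, shape = 1,
                                 color = "red", size = 3)
  p
}
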