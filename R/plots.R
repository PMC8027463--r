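#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics glance
#' @export
generics::glance

#' @export
generics::tidy

#' Plot a spatio-temporal image
#'
#' Raster of `I(x, t)`: arc-length position against time. Moving
#' erythrocyte columns appear as oblique streaks; the steeper the streak in
#' this orientation, the slower the flow.
#'
#' @param object An `sti`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sti <- function(object, ...) {
  M <- object$intensity
  df <- tidyr::expand_grid(x = seq_len(nrow(M)), t = seq_len(ncol(M)))
  df$intensity <- as.vector(M)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$x,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "frame", y = "position along centreline (samples)",
                  title = object$segment_id) +
    ggplot2::theme_minimal()
}

#' Plot a vessel map
#'
#' Reference frame with the detected skeleton and segment centrelines
#' overlaid, coloured by estimated diameter.
#'
#' @param frame Reference intensity matrix.
#' @param segments Tibble from [split_segments()].
#' @return A ggplot.
#' @export
plot_vessel_map <- function(frame, segments) {
  df <- tidyr::expand_grid(row = seq_len(nrow(frame)),
                           col = seq_len(ncol(frame)))
  df$intensity <- as.vector(frame)
  segs <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    p <- segments$points[[i]]
    tibble::tibble(segment_id = segments$segment_id[i],
                   diameter_um = segments$diameter_um[i],
                   row = p[, 1], col = p[, 2])
  })
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      alpha = .data$intensity),
                         fill = "grey30") +
    ggplot2::geom_point(data = segs,
                        ggplot2::aes(x = .data$col, y = .data$row,
                                     colour = .data$diameter_um), size = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_alpha(range = c(0, 1), guide = "none") +
    ggplot2::labs(colour = "D (um)", x = NULL, y = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Box plot of a hemodynamic parameter by cohort and vessel group
#'
#' @param table A [cohort_table()].
#' @param parameter One of `"D"`, `"Va"`, `"Q"`, `"WSR"`.
#' @return A ggplot.
#' @export
plot_cohort <- function(table, parameter = "Va") {
  col <- param_column(parameter)
  ggplot2::ggplot(table,
                  ggplot2::aes(x = factor(.data$group), y = .data[[col]],
                               fill = .data$cohort)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "vessel group", y = parameter) +
    ggplot2::theme_minimal()
}

#' Bland-Altman style plot of a repeatability assessment
#'
#' Paired differences against pair means, with the mean difference and the
#' repeatability interval (mean difference plus/minus the coefficient of
#' repeatability).
#'
#' @param object A `repeatability_result` (needs the original pairs passed
#'   via `m1`, `m2`).
#' @param m1,m2 The paired measurements used to build `object`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeatability_result <- function(object, m1, m2, ...) {
  df <- tibble::tibble(mean = (m1 + m2) / 2, diff = m1 - m2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(object$ci_low, object$ci_high),
                        colour = "red", linetype = 3) +
    ggplot2::labs(x = "pair mean", y = "difference",
                  title = sprintf("%s: CR = %.3g", object$parameter,
                                  object$cr)) +
    ggplot2::theme_minimal()
}
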