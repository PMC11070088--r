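#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_raster geom_errorbar geom_text geom_path labs scale_x_log10
#'   scale_fill_viridis_c coord_equal theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot the depth-from-boundary field
#'
#' @param field A [interior_distance_field()] result.
#' @param roi Optional [boundary_roi()] overlaid as a path.
#' @return A ggplot.
#' @export
plot_distance_field <- function(field, roi = NULL) {
  stopifnot(inherits(field, "distance_field"))
  df <- tibble::tibble(
    x = rep(seq_len(field$shape[2]) - 1, each = field$shape[1]),
    y = rep(seq_len(field$shape[1]) - 1, times = field$shape[2]),
    depth = as.vector(field$depth_um)
  )
  p <- ggplot(df[!is.na(df$depth), ], aes(.data$x, .data$y, fill = .data$depth)) +
    geom_raster() +
    scale_fill_viridis_c(name = "depth (um)") +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)") +
    theme_minimal()
  if (!is.null(roi)) {
    v <- as.data.frame(unclass(roi))
    v <- rbind(v, v[1, ])
    p <- p + geom_path(data = v, aes(.data$x, .data$y), inherit.aes = FALSE)
  }
  p
}

#' Plot a per-shell infiltration profile
#'
#' @param metrics Output of [infiltration_metric()].
#' @return A ggplot of the eGFP/DAPI metric against shell depth.
#' @export
plot_infiltration_profile <- function(metrics) {
  mid <- (metrics$depth_min + metrics$depth_max) / 2
  df <- tibble::tibble(depth = mid, metric = metrics$metric)
  ggplot(df, aes(.data$depth, .data$metric)) +
    geom_line() + geom_point() +
    labs(x = "shell depth from boundary", y = "mean eGFP / mean DAPI") +
    theme_minimal()
}

#' @export
autoplot.fit_4pl <- function(object, n_curve = 200, ...) {
  df <- object$data
  p <- ggplot(df, aes(.data$dose, .data$response)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "dose", y = "response") +
    theme_minimal()
  if (object$converged) {
    grid <- tibble::tibble(
      dose = 10^seq(min(df$l10d), max(df$l10d), length.out = n_curve)
    )
    grid$response <- predict(object, grid)
    p <- p + geom_line(data = grid, aes(.data$dose, .data$response))
  }
  p
}

#' @export
autoplot.comparison_family <- function(object, ...) {
  cmp <- object$comparisons
  df <- tibble::tibble(
    comparison = factor(cmp$comparison, levels = cmp$comparison),
    estimate = cmp$estimate,
    lo = cmp$estimate - 1.96 * cmp$std.error,
    hi = cmp$estimate + 1.96 * cmp$std.error,
    stars = cmp$stars
  )
  ggplot(df, aes(.data$comparison, .data$estimate)) +
    geom_col(fill = "grey70") +
    geom_errorbar(aes(ymin = .data$lo, ymax = .data$hi), width = 0.2) +
    geom_text(aes(y = .data$hi, label = .data$stars), vjust = -0.5) +
    labs(x = NULL, y = "estimated difference") +
    theme_minimal()
}
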