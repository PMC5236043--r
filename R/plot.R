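#' Plot recovery-coefficient tables
#'
#' `autoplot()` on an `rc_table` picks the natural layout: RC versus true
#' sphere-to-background ratio (contrast sweeps), RC versus iterations
#' (iteration sweeps), or RC versus diameter otherwise. Curves are colored
#' by sphere diameter and faceted by reconstruction variant (and post-filter
#' width when it varies).
#'
#' @param object An `rc_table` tibble.
#' @param metric Which recovery coefficient to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rc_table
#' @export
autoplot.rc_table <- function(object, metric = "rc_50bg", ...) {
  has_var <- function(v) v %in% names(object) &&
    length(unique(object[[v]])) > 1
  if (has_var("true_ratio") && has_var("frame")) {
    return(plot_rc_vs_ratio(object, metric))
  }
  if (has_var("iterations")) {
    return(plot_rc_vs_iterations(object, metric))
  }
  plot_rc_vs_diameter(object, metric)
}

#' @rdname autoplot.rc_table
#' @param table An `rc_table` tibble.
#' @export
plot_rc_vs_ratio <- function(table, metric = "rc_50bg") {
  df <- summarise_rc(table, c("recon", "frame", "true_ratio"), metric)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_ratio, y = .data$rc,
                                   color = factor(.data$diameter),
                                   group = factor(.data$diameter))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, color = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rc - .data$sd,
                                          ymax = .data$rc + .data$sd),
                             size = 0.25) +
    ggplot2::facet_wrap(~recon) +
    ggplot2::labs(x = "true sphere-to-background ratio", y = metric,
                  color = "diameter (mm)") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.rc_table
#' @export
plot_rc_vs_iterations <- function(table, metric = "rc_50bg") {
  df <- summarise_rc(table, c("recon", "iterations", "postfilter_fwhm"),
                     metric)
  df$postfilter <- sprintf("post-filter %g mm", df$postfilter_fwhm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iterations, y = .data$rc,
                                   color = factor(.data$diameter))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, color = "grey40") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(postfilter ~ recon) +
    ggplot2::labs(x = "iterations", y = metric, color = "diameter (mm)") +
    ggplot2::theme_bw()
}

#' @rdname autoplot.rc_table
#' @export
plot_rc_vs_diameter <- function(table, metric = "rc_50bg") {
  df <- summarise_rc(table, "recon", metric)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$diameter), y = .data$rc,
                                   color = .data$recon, group = .data$recon)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3, color = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rc - .data$sd,
                                          ymax = .data$rc + .data$sd)) +
    ggplot2::labs(x = "sphere diameter (mm)", y = metric, color = NULL) +
    ggplot2::theme_bw()
}

# pooled mean/SD of one metric per group x diameter
summarise_rc <- function(table, keys, metric) {
  keys <- intersect(keys, names(table))
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "diameter")))) |>
    dplyr::summarise(rc = mean(.data[[metric]]),
                     sd = ifelse(dplyr::n() > 1, stats::sd(.data[[metric]]), 0),
                     .groups = "drop")
}

#' Plot a reconstructed slice
#'
#' Transaxial heat map of the slice through the sphere string — a quick look
#' at the reconstruction and its edge artifacts.
#'
#' @param object A `recon_result`.
#' @param slice Slice index along the third axis (default: middle).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recon_result
#' @export
autoplot.recon_result <- function(object, slice = NULL, ...) {
  img <- object$image
  if (is.null(slice)) slice <- ceiling(img$grid$dims[3] / 2)
  df <- expand.grid(x = grid_axis(img$grid, 1), y = grid_axis(img$grid, 2))
  df$value <- as.vector(img$values[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = object$params$label) +
    ggplot2::theme_minimal()
}
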