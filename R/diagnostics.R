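#' Monotonicity diagnostics of RC versus sphere diameter
#'
#' The physically expected pattern is a recovery coefficient that falls
#' monotonically as the sphere diameter decreases; resolution-modelled
#' reconstruction can instead produce an interior maximum (around 8 mm).
#' For every group of the table (recon variant crossed with whatever of
#' `frame`, `iterations`, `postfilter_fwhm` is present and varies), this
#' averages the chosen metric per unique diameter (duplicate spheres and
#' replicates pooled) and reports: a monotone flag (non-decreasing in
#' diameter within tolerance `tol`, ties allowed), the diameter attaining
#' the maximum RC (ties resolved to the largest diameter), the maximum RC,
#' and how many diameters exceed RC = 1.
#'
#' @param table An `rc_table`.
#' @param metric `"rc_50bg"`, `"rc_max"` or `"rc_avg"`.
#' @param tol Tolerance band for monotonicity (RC units) absorbing sampling
#'   jitter; dips no deeper than `tol` do not break the flag.
#' @return A tibble, one row per group, with `is_monotone`,
#'   `argmax_diameter`, `max_rc`, `n_above_1` and the group keys.
#' @export
monotonicity_diagnostics <- function(table, metric = "rc_50bg", tol = 0.02) {
  stopifnot(metric %in% c("rc_50bg", "rc_max", "rc_avg"))
  keys <- intersect(c("recon", "psf_modeled", "frame", "true_ratio",
                      "iterations", "postfilter_fwhm"), names(table))
  table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$diameter) |>
    dplyr::summarise(rc = mean(.data[[metric]]), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(.data$diameter, .by_group = TRUE) |>
    dplyr::summarise(
      n_diameters = dplyr::n(),
      is_monotone = all(diff(.data$rc) >= -tol),
      argmax_diameter = max(.data$diameter[.data$rc >= max(.data$rc) - 1e-12]),
      max_rc = max(.data$rc),
      n_above_1 = sum(.data$rc > 1),
      .groups = "drop")
}

#' Smallest post-filter restoring monotone RC versus size
#'
#' Scans the post-filter widths present in an iteration-sweep table (at a
#' fixed iteration count) and returns the smallest width for which the
#' PSF-modelled reconstruction's RC-versus-diameter curve is monotone within
#' tolerance — optionally also requiring every RC to stay at or below 1.
#' This is the resolution-versus-artifact trade-off: wider filters suppress
#' the edge overshoot at the cost of spatial resolution.
#'
#' @param table An `rc_table` from [run_iteration_sweep()] (or of the same
#'   shape) containing a `postfilter_fwhm` column.
#' @param iterations Iteration count at which to evaluate (default: the
#'   largest common value in the table).
#' @param metric,tol As in [monotonicity_diagnostics()].
#' @param require_unity Also require `max_rc <= 1 + tol`.
#' @param psf_only Restrict to PSF-modelled rows (the non-PSF curves are
#'   monotone already, so their answer is the smallest tested filter).
#' @return The restoring post-filter FWHM in mm (`NA` if no tested width
#'   qualifies), with the per-filter diagnostics attached as attribute
#'   `"diagnostics"`.
#' @export
find_minimal_restoring_filter <- function(table, iterations = NULL,
                                          metric = "rc_50bg", tol = 0.02,
                                          require_unity = FALSE,
                                          psf_only = TRUE) {
  stopifnot("postfilter_fwhm" %in% names(table))
  if (!is.null(iterations)) {
    table <- dplyr::filter(table, .data$iterations == !!iterations)
  } else if ("iterations" %in% names(table)) {
    table <- dplyr::filter(table, .data$iterations == max(.data$iterations))
  }
  if (psf_only && "psf_modeled" %in% names(table)) {
    table <- dplyr::filter(table, .data$psf_modeled)
  }
  diag <- monotonicity_diagnostics(table, metric = metric, tol = tol)
  ok <- diag$is_monotone
  if (require_unity) ok <- ok & diag$max_rc <= 1 + tol
  # a filter restores the expected pattern if every group at that width is ok
  per_filter <- tibble::tibble(
    postfilter_fwhm = sort(unique(diag$postfilter_fwhm)))
  per_filter$restores <- vapply(per_filter$postfilter_fwhm, function(pf) {
    sel <- diag$postfilter_fwhm == pf
    all(ok[sel])
  }, TRUE)
  hit <- per_filter$postfilter_fwhm[per_filter$restores]
  out <- if (length(hit)) min(hit) else NA_real_
  attr(out, "diagnostics") <- diag
  attr(out, "per_filter") <- per_filter
  out
}

#' Write experiment reports to disk
#'
#' Writes each RC table as CSV, a JSON file of monotonicity diagnostics,
#' and (optionally) the standard figures as PNG.
#'
#' @param tables Named list of `rc_table` tibbles.
#' @param dir Output directory (created if needed).
#' @param plots Also write autoplot figures as PNG.
#' @return Invisibly, the paths written.
#' @export
generate_report <- function(tables, dir, plots = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
    dj <- monotonicity_diagnostics(tables[[nm]])
    pj <- file.path(dir, paste0(nm, "_diagnostics.json"))
    jsonlite::write_json(dj, pj, digits = NA, auto_unbox = TRUE)
    paths <- c(paths, pj)
    if (plots) {
      pp <- file.path(dir, paste0(nm, ".png"))
      ggplot2::ggsave(pp, ggplot2::autoplot(tables[[nm]]),
                      width = 8, height = 5, dpi = 120)
      paths <- c(paths, pp)
    }
  }
  invisible(paths)
}
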