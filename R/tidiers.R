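#' Tidy and glance methods for reconstruction results
#'
#' `tidy()` returns the per-iteration log-likelihood trace (one row per full
#' iteration; empty if the reconstruction was run without
#' `track_loglik = TRUE`). `glance()` returns a one-row summary of the
#' reconstruction: its configuration, data totals and image range.
#'
#' @param x A `recon_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy recon_result
#' @export
tidy.recon_result <- function(x, ...) {
  ll <- x$loglik
  if (is.null(ll) || length(ll) == 0) {
    return(tibble::tibble(iteration = integer(), loglik = numeric()))
  }
  tibble::tibble(iteration = seq_along(ll), loglik = ll)
}

#' @rdname tidy.recon_result
#' @method glance recon_result
#' @export
glance.recon_result <- function(x, ...) {
  tibble::tibble(
    label = x$params$label,
    iterations = x$params$iterations,
    subsets = x$params$subsets,
    psf_modeled = x$params$psf_modeled,
    psf_fwhm = x$params$psf_fwhm,
    postfilter_fwhm = x$params$postfilter_fwhm,
    frame_start = x$frame_start,
    frame_duration = x$frame_duration,
    total_counts = x$total_counts,
    final_loglik = if (length(x$loglik)) x$loglik[length(x$loglik)] else NA_real_,
    min_value = min(x$image$values),
    max_value = max(x$image$values))
}

#' Wide-to-long reshaping of an RC table
#'
#' Pivots the three recovery coefficients into a long `metric`/`rc` pair —
#' convenient for faceting all metrics at once.
#'
#' @param table An `rc_table`.
#' @return A long tibble.
#' @export
rc_long <- function(table) {
  tidyr::pivot_longer(table, cols = c("rc_max", "rc_50bg", "rc_avg"),
                      names_to = "metric", values_to = "rc")
}
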