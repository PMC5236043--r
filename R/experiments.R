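#' Experiment configuration
#'
#' Bundles everything one study run needs: the phantom, grid resolution, the
#' acquisition model, the reconstruction variants to compare, and the frame
#' schedule. The default frame schedule is eleven consecutive 10-min frames
#' from time zero, over which the true sphere-to-background ratio of the
#' dual-isotope phantom sweeps from about 1:1 to beyond 15:1. The default
#' reconstruction pair mirrors clinical practice: OSEM without PSF
#' (4 iterations, 16 subsets) and with PSF (4 iterations, 21 subsets), both
#' with a 2-mm Gaussian post-filter.
#'
#' @param phantom A [phantom_spec()]; default [phantom_default()].
#' @param acquisition An [acquisition_config()].
#' @param recons List of [recon_params()] variants to compare.
#' @param n_frames,frame_duration Frame schedule (minutes).
#' @param base_seed Integer; all per-frame/replicate seeds derive from it.
#' @param spacing,margin Grid resolution and clearance, mm (see
#'   [phantom_grid()]).
#' @param supersample Rasterization anti-aliasing (see [rasterize()]).
#' @param truth `"measured"` (RC denominator from the reference VOI, as in
#'   phantom practice) or `"oracle"` (analytic truth).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_default(),
                              acquisition = acquisition_config(),
                              recons = list(
                                recon_params(4, 16, psf_modeled = FALSE,
                                             postfilter_fwhm = 2),
                                recon_params(4, 21, psf_modeled = TRUE,
                                             postfilter_fwhm = 2)),
                              n_frames = 11, frame_duration = 10,
                              base_seed = 1L, spacing = 2, margin = 18,
                              supersample = 4,
                              truth = c("measured", "oracle")) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(acquisition, "acquisition_config"),
            n_frames >= 1, frame_duration > 0, length(recons) >= 1)
  truth <- match.arg(truth)
  for (r in recons) stopifnot(inherits(r, "recon_params"))
  labels <- vapply(recons, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("recon labels must be distinct", call. = FALSE)
  names(recons) <- labels
  structure(list(phantom = phantom, acquisition = acquisition,
                 recons = recons, n_frames = as.integer(n_frames),
                 frame_duration = frame_duration,
                 base_seed = as.integer(base_seed),
                 spacing = spacing, margin = margin,
                 supersample = supersample, truth = truth),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(
    "<experiment_config> %d frames x %g min, %d recon variant(s): %s\n",
    x$n_frames, x$frame_duration, length(x$recons),
    paste(names(x$recons), collapse = ", ")))
  invisible(x)
}

#' Frame schedule with true contrast
#'
#' @param cfg An [experiment_config()].
#' @return Tibble: `frame`, `frame_start`, `frame_duration`, `true_ratio`.
#' @export
frame_schedule <- function(cfg) {
  starts <- (seq_len(cfg$n_frames) - 1) * cfg$frame_duration
  tibble::tibble(
    frame = seq_len(cfg$n_frames),
    frame_start = starts,
    frame_duration = cfg$frame_duration,
    true_ratio = vapply(starts, function(t0)
      true_ratio(cfg$phantom, t0, cfg$frame_duration), 0))
}

#' @rdname frame_schedule
#' @param ratio Target true ratio, e.g. 8.
#' @return `frame_nearest_ratio()`: the frame index whose frame-mean true
#'   ratio is closest to `ratio`.
#' @export
frame_nearest_ratio <- function(cfg, ratio) {
  sched <- frame_schedule(cfg)
  sched$frame[which.min(abs(sched$true_ratio - ratio))]
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(base, frame = 0L, replicate = 0L) {
  as.integer((as.numeric(base) * 48271 + frame * 259993 + replicate * 7919) %%
               2147483647)
}

# shared per-experiment machinery: grid, projector, calibration activity
experiment_setup <- function(cfg) {
  grid <- phantom_grid(cfg$phantom, spacing = cfg$spacing, margin = cfg$margin)
  geom <- projector_geometry(grid, n_angles = cfg$acquisition$n_angles,
                             radial_spacing = cfg$acquisition$radial_spacing)
  img1 <- rasterize(cfg$phantom, grid, 0, cfg$frame_duration,
                    supersample = cfg$supersample)
  list(grid = grid, geom = geom,
       calibration_total = sum(img1$values) * voxel_volume(grid))
}

# simulate one frame and measure every recon variant; returns RC rows
measure_frame <- function(cfg, setup, frame, recons = cfg$recons,
                          replicate = 1L, keep_results = FALSE) {
  t0 <- (frame - 1) * cfg$frame_duration
  img <- rasterize(cfg$phantom, setup$grid, t0, cfg$frame_duration,
                   supersample = cfg$supersample)
  sf <- simulate_frame(img, cfg$acquisition, setup$geom,
                       calibration_total = setup$calibration_total,
                       seed = derive_seed(cfg$base_seed, frame, replicate))
  results <- lapply(recons, function(rp) reconstruct(sf, rp))
  rows <- purrr::imap_dfr(results, function(res, label) {
    m <- measure_spheres(res$image, cfg$phantom, truth = cfg$truth)
    dplyr::mutate(m,
                  recon = label,
                  psf_modeled = res$params$psf_modeled,
                  iterations = res$params$iterations,
                  subsets = res$params$subsets,
                  postfilter_fwhm = res$params$postfilter_fwhm,
                  frame = frame,
                  true_ratio = true_ratio(cfg$phantom, t0, cfg$frame_duration),
                  replicate = replicate,
                  .before = 1)
  })
  if (keep_results) attr(rows, "recon_results") <- results
  rows
}

as_rc_table <- function(tbl) {
  class(tbl) <- unique(c("rc_table", class(tbl)))
  tbl
}

#' Contrast sweep: RC versus true sphere-to-background ratio
#'
#' Simulates the dynamic series frame by frame, reconstructs each frame with
#' every configured variant, and measures per-sphere recovery coefficients —
#' the in-silico analogue of plotting RC against the true ratio as it climbs
#' from 1:1 toward 15:1.
#'
#' @param cfg An [experiment_config()].
#' @param frames Frame indices to simulate (default: all).
#' @param .progress Print per-frame progress.
#' @return An `rc_table` tibble: one row per sphere x frame x recon variant.
#' @export
run_contrast_sweep <- function(cfg, frames = NULL, .progress = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  if (is.null(frames)) frames <- seq_len(cfg$n_frames)
  setup <- experiment_setup(cfg)
  rows <- purrr::map_dfr(frames, function(f) {
    if (.progress) message(sprintf("frame %d/%d", f, max(frames)))
    measure_frame(cfg, setup, f)
  })
  as_rc_table(rows)
}

#' Iteration sweep: convergence of RC with and without PSF
#'
#' Fixes the frame whose true ratio is nearest `ratio_target` (about 8:1 by
#' default), reconstructs it once per variant keeping every full-iteration
#' snapshot, then evaluates every (iterations, post-filter) cell by filtering
#' the stored snapshots — so the whole sweep costs two reconstructions.
#' Subset counts stay fixed (16 without PSF, 21 with, by default) while
#' iterations vary.
#'
#' @param cfg An [experiment_config()].
#' @param iterations Iteration counts to report, e.g. `1:6`.
#' @param postfilters Post-filter FWHMs in mm, e.g. `c(2, 3, 4, 6)`.
#' @param ratio_target True ratio selecting the frame.
#' @return An `rc_table` tibble over sphere x iterations x post-filter x
#'   recon variant.
#' @export
run_iteration_sweep <- function(cfg, iterations = 1:6,
                                postfilters = c(2, 3, 4, 6),
                                ratio_target = 8) {
  stopifnot(inherits(cfg, "experiment_config"))
  setup <- experiment_setup(cfg)
  frame <- frame_nearest_ratio(cfg, ratio_target)
  t0 <- (frame - 1) * cfg$frame_duration
  img <- rasterize(cfg$phantom, setup$grid, t0, cfg$frame_duration,
                   supersample = cfg$supersample)
  sf <- simulate_frame(img, cfg$acquisition, setup$geom,
                       calibration_total = setup$calibration_total,
                       seed = derive_seed(cfg$base_seed, frame))
  tr <- true_ratio(cfg$phantom, t0, cfg$frame_duration)
  rows <- purrr::imap_dfr(cfg$recons, function(rp, label) {
    deep <- recon_params(max(iterations), rp$subsets, rp$psf_modeled,
                         rp$psf_fwhm, postfilter_fwhm = 0,
                         keep_iterations = TRUE, label = label)
    res <- reconstruct(sf, deep)
    purrr::map_dfr(iterations, function(it) {
      purrr::map_dfr(postfilters, function(pf) {
        m <- measure_spheres(iteration_image(res, it, pf), cfg$phantom,
                             truth = cfg$truth)
        dplyr::mutate(m, recon = label, psf_modeled = rp$psf_modeled,
                      iterations = it, subsets = rp$subsets,
                      postfilter_fwhm = pf, frame = frame, true_ratio = tr,
                      replicate = 1L, .before = 1)
      })
    })
  })
  as_rc_table(rows)
}

#' Reproducibility: RC dispersion over noise realizations
#'
#' Repeats acquisition and reconstruction of one high-contrast frame under
#' independent Poisson noise (distinct derived seeds) and reports per-sphere
#' recovery coefficients per replicate. Summarize with
#' [summarise_reproducibility()] for the mean +/- SD comparison between
#' reconstruction variants.
#'
#' @param cfg An [experiment_config()].
#' @param n_replicates Number of noise realizations (3 matches the physical
#'   experiment; use more for power).
#' @param ratio_target True ratio selecting the frame (about 13:1 by
#'   default, the late part of the sweep).
#' @return An `rc_table` tibble with a `replicate` column.
#' @export
run_reproducibility <- function(cfg, n_replicates = 3, ratio_target = 13) {
  stopifnot(inherits(cfg, "experiment_config"), n_replicates >= 1)
  setup <- experiment_setup(cfg)
  frame <- frame_nearest_ratio(cfg, ratio_target)
  rows <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    measure_frame(cfg, setup, frame, replicate = r)
  })
  as_rc_table(rows)
}

#' @rdname run_reproducibility
#' @param table An `rc_table` with replicates.
#' @return `summarise_reproducibility()`: tibble of per recon x sphere mean
#'   and SD of each recovery metric.
#' @export
summarise_reproducibility <- function(table) {
  table |>
    dplyr::group_by(.data$recon, .data$psf_modeled, .data$sphere,
                    .data$diameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(c("rc_max", "rc_50bg", "rc_avg"),
                    list(mean = mean, sd = stats::sd)),
      .groups = "drop")
}
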