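#' Acquisition configuration
#'
#' Parameters of the emulated measurement: the scanner's effective spatial
#' resolution as an isotropic Gaussian (`system_fwhm`, default 4.5 mm, the
#' NEMA-style FWHM of the clinical systems emulated), the sampling geometry,
#' and the counting statistics. The simulator emits already-corrected
#' (mean-preserving) Poisson data: attenuation, scatter and randoms are not
#' modelled.
#'
#' @param system_fwhm Detector-response blur FWHM, mm; `>= 0`.
#' @param mode `"sinogram"` (project then count) or `"image"` (blur and count
#'   in image space, no projection — a fast path for tests).
#' @param n_angles Views over 180 degrees; default 336 (divisible by both
#'   clinical subset counts, 16 and 21).
#' @param radial_spacing Radial bin width, mm; default in-plane voxel size.
#' @param target_counts Expected total counts for a frame containing
#'   `calibration_total` activity (see below). The default, 5e8 per 10-min
#'   frame at the 1:1 start, is the magnitude of a clinical list-mode
#'   acquisition; later frames collect fewer counts as the activity decays.
#' @param seed Integer seed for the Poisson draw.
#' @param noiseless If `TRUE`, return the exact expectation (infinite-count
#'   limit).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(system_fwhm = 4.5,
                               mode = c("sinogram", "image"),
                               n_angles = 336,
                               radial_spacing = NULL,
                               target_counts = 5e8,
                               seed = 1L,
                               noiseless = FALSE) {
  mode <- match.arg(mode)
  stopifnot(system_fwhm >= 0, n_angles >= 1, target_counts > 0)
  structure(list(system_fwhm = system_fwhm, mode = mode, n_angles = n_angles,
                 radial_spacing = radial_spacing,
                 target_counts = target_counts, seed = as.integer(seed),
                 noiseless = noiseless),
            class = "acquisition_config")
}

#' Simulate measured data for one frame
#'
#' Blurs the ground-truth activity image with the system response, projects
#' it (in sinogram mode), scales the expectation so that a frame holding
#' `calibration_total` Bq of activity would total `cfg$target_counts` counts,
#' and draws independent Poisson counts. Counts therefore decay across a
#' dynamic series exactly as the phantom's activity does. The draw is
#' deterministic given `(img, cfg, seed)` and does not disturb the caller's
#' RNG state.
#'
#' @param img An [activity_image()] (ground truth).
#' @param cfg An [acquisition_config()].
#' @param geom Optional prebuilt [projector_geometry()] (rebuilt if `NULL`).
#' @param calibration_total Total activity (Bq) that maps to
#'   `target_counts`; default the activity of `img` itself, so this frame's
#'   expectation totals exactly `target_counts`. Pass the first frame's total
#'   to let later frames decay.
#' @param seed Overrides `cfg$seed`.
#' @return A [sinogram_frame()] (or, in image mode, an `image_counts`
#'   object: the blurred image plus Poisson counts on the grid).
#' @export
simulate_frame <- function(img, cfg, geom = NULL, calibration_total = NULL,
                           seed = NULL) {
  stopifnot(inherits(img, "activity_image"), inherits(cfg, "acquisition_config"))
  seed <- if (is.null(seed)) cfg$seed else as.integer(seed)
  blurred <- system_blur(img, cfg$system_fwhm)
  frame_total <- sum(img$values) * voxel_volume(img$grid)
  if (is.null(calibration_total)) calibration_total <- frame_total
  if (frame_total <= 0) stop("frame contains no activity", call. = FALSE)

  if (cfg$mode == "image") {
    lambda <- blurred$values
    scale <- cfg$target_counts * (frame_total / calibration_total) / sum(lambda)
    lambda <- lambda * scale
    counts <- if (cfg$noiseless) lambda else
      array(with_frozen_rng(seed, rpois(length(lambda), lambda)), dim(lambda))
    return(structure(list(grid = img$grid, counts = counts, scale = scale,
                          frame_start = img$frame_start,
                          frame_duration = img$frame_duration,
                          expected = cfg$noiseless),
                     class = "image_counts"))
  }

  if (is.null(geom)) {
    geom <- projector_geometry(img$grid, n_angles = cfg$n_angles,
                               radial_spacing = cfg$radial_spacing)
  }
  expect <- forward_project(blurred, geom)
  tot <- sum(expect$counts)
  if (tot <= 0) stop("degenerate frame: zero expected counts", call. = FALSE)
  scale <- cfg$target_counts * (frame_total / calibration_total) / tot
  lambda <- expect$counts * scale
  counts <- if (cfg$noiseless) lambda else
    matrix(with_frozen_rng(seed, rpois(length(lambda), lambda)),
           nrow(lambda), ncol(lambda))
  sinogram_frame(counts, geom, img$frame_start, img$frame_duration,
                 expected = cfg$noiseless, scale = scale)
}

# evaluate `expr` under a private RNG stream, restoring the caller's state
with_frozen_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
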