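#' Phantom YAML serialization
#'
#' Round-trips a [phantom_spec()] through a plain YAML document (spheres,
#' concentrations, isotopes, region geometry), so phantom definitions can be
#' versioned and shared.
#'
#' @param phantom A [phantom_spec()].
#' @param path File path to write.
#' @return `write_phantom_yaml()`: the path, invisibly;
#'   `read_phantom_yaml()`: a [phantom_spec()].
#' @export
write_phantom_yaml <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom_spec"))
  doc <- list(
    spheres = lapply(seq_len(nrow(phantom$spheres)), function(i) {
      sp <- phantom$spheres[i, ]
      list(id = sp$id, diameter = sp$diameter,
           center = c(sp$x, sp$y, sp$z))
    }),
    sphere_concentration0 = phantom$sphere_concentration0,
    sphere_isotope = list(name = phantom$sphere_isotope$name,
                          half_life = phantom$sphere_isotope$half_life),
    background = list(
      box_lo = as.numeric(phantom$background$box["lo", ]),
      box_hi = as.numeric(phantom$background$box["hi", ]),
      concentration0 = phantom$background$concentration0,
      isotope = list(name = phantom$background$isotope$name,
                     half_life = phantom$background$isotope$half_life)),
    reference = list(center = phantom$reference$center,
                     volume_ml = phantom$reference$volume_ml,
                     pad = phantom$reference$pad),
    background_voi = list(center = phantom$background_voi$center,
                          volume_ml = phantom$background_voi$volume_ml))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_phantom_yaml
#' @export
read_phantom_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  spheres <- dplyr::bind_rows(lapply(doc$spheres, function(sp) {
    tibble::tibble(id = sp$id, diameter = sp$diameter,
                   x = sp$center[1], y = sp$center[2], z = sp$center[3])
  }))
  ph <- phantom_spec(
    spheres = spheres,
    sphere_concentration0 = doc$sphere_concentration0,
    background_box = rbind(lo = doc$background$box_lo,
                           hi = doc$background$box_hi),
    background_concentration0 = doc$background$concentration0,
    reference_center = doc$reference$center,
    background_voi_center = doc$background_voi$center,
    sphere_isotope = isotope(doc$sphere_isotope$name,
                             doc$sphere_isotope$half_life),
    background_isotope = isotope(doc$background$isotope$name,
                                 doc$background$isotope$half_life),
    reference_pad = doc$reference$pad)
  ph
}

#' Activity image NIfTI I/O
#'
#' Writes an [activity_image()] as NIfTI-1 with mm voxel spacings in the
#' header, plus a JSON sidecar carrying the frame timing and the grid origin
#' (the center of the first voxel); `read_activity_nifti()` restores the
#' object from the pair. This is the interchange format for analysis-only
#' workflows on externally reconstructed volumes.
#'
#' @param img An [activity_image()].
#' @param path Path ending in `.nii` or `.nii.gz`; the sidecar gets the same
#'   stem with `.json`.
#' @return The main path, invisibly / an [activity_image()].
#' @export
write_activity_nifti <- function(img, path) {
  stopifnot(inherits(img, "activity_image"))
  nii <- RNifti::asNifti(img$values)
  RNifti::pixdim(nii) <- img$grid$spacing
  RNifti::writeNifti(nii, path, datatype = "double")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(frame_start = img$frame_start, frame_duration = img$frame_duration,
         origin = img$grid$origin, spacing = img$grid$spacing),
    sidecar, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_activity_nifti
#' @export
read_activity_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  vals <- array(as.numeric(nii), dim = dim(nii))
  grid <- voxel_grid(dim(vals), spacing = meta$spacing, origin = meta$origin)
  activity_image(grid, vals, meta$frame_start, meta$frame_duration)
}

#' Sinogram persistence
#'
#' Saves a [sinogram_frame()] as a compressed RDS array container together
#' with a human-readable JSON sidecar describing the geometry (angles,
#' radial bins and spacing, slice count, frame timing).
#'
#' @param sino A [sinogram_frame()].
#' @param path Path ending in `.rds`.
#' @return The path, invisibly / a [sinogram_frame()].
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram_frame"))
  saveRDS(sino, path, compress = "gzip")
  sidecar <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(
    list(n_angles = sino$geom$n_angles, n_rad = sino$geom$n_rad,
         radial_spacing = sino$geom$radial_spacing,
         n_slices = ncol(sino$counts),
         frame_start = sino$frame_start,
         frame_duration = sino$frame_duration,
         expected = sino$expected, total_counts = sum(sino$counts)),
    sidecar, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  sino <- readRDS(path)
  stopifnot(inherits(sino, "sinogram_frame"))
  sino
}

#' Analyze externally reconstructed volumes
#'
#' Analysis-only mode: applies the package's VOI metrics to reconstructed
#' volumes produced elsewhere, given the phantom manifest that describes the
#' sphere geometry. Each volume must share the phantom's coordinate frame.
#'
#' @param paths Character vector of NIfTI paths (with JSON sidecars as
#'   written by [write_activity_nifti()]).
#' @param phantom A [phantom_spec()] or the path to its YAML manifest.
#' @param labels Optional labels, one per volume (defaults to file stems).
#' @param truth `"measured"` or `"oracle"` (see [measure_spheres()]).
#' @return An `rc_table` tibble, one row per sphere per volume.
#' @export
analyze_volumes <- function(paths, phantom, labels = NULL,
                            truth = c("measured", "oracle")) {
  truth <- match.arg(truth)
  if (is.character(phantom)) phantom <- read_phantom_yaml(phantom)
  stopifnot(inherits(phantom, "phantom_spec"))
  if (is.null(labels)) labels <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  rows <- purrr::map2_dfr(paths, labels, function(p, lab) {
    img <- read_activity_nifti(p)
    m <- measure_spheres(img, phantom, truth = truth)
    dplyr::mutate(m, recon = lab,
                  true_ratio = true_ratio(phantom, img$frame_start,
                                          img$frame_duration),
                  .before = 1)
  })
  as_rc_table(rows)
}
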