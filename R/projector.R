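#' Slice-wise parallel-beam projector
#'
#' Builds the linear forward operator mapping a transaxial image plane
#' (grid axes 1-2) to a set of parallel-beam line integrals over `n_angles`
#' views spanning 180 degrees. The operator is voxel-driven: each voxel's
#' mass (value x in-plane voxel area, divided by the radial bin width) is
#' distributed linearly between the two radial bins bracketing the projection
#' of its center, so each view conserves total mass exactly and the adjoint
#' is the exact matrix transpose. The same 2D operator is applied
#' independently to every axial slice (axis 3).
#'
#' @param grid A [voxel_grid()]; axes 1-2 form the projection plane.
#' @param n_angles Number of equally spaced view angles over 180 degrees.
#' @param radial_spacing Radial bin width in mm; defaults to the in-plane
#'   voxel spacing.
#' @return An object of class `projector_geometry` holding the sparse system
#'   matrix and the bin layout (angles x radial bins, angle-major rows).
#' @export
projector_geometry <- function(grid, n_angles = 336, radial_spacing = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), n_angles >= 1)
  if (is.null(radial_spacing)) radial_spacing <- min(grid$spacing[1:2])
  stopifnot(radial_spacing > 0)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2)
  cx <- mean(range(xs)); cy <- mean(range(ys))
  # radial extent: cover the plane's diagonal about its center
  rmax <- sqrt(max(abs(xs - cx))^2 + max(abs(ys - cy))^2) + 2 * radial_spacing
  n_rad <- 2L * ceiling(rmax / radial_spacing) + 1L
  t0 <- -(n_rad - 1) / 2 * radial_spacing
  angles <- (seq_len(n_angles) - 1) * pi / n_angles

  vx <- rep(xs - cx, times = ny)
  vy <- rep(ys - cy, each = nx)
  nvox <- nx * ny
  wt <- prod(grid$spacing[1:2]) / radial_spacing
  ii <- jj <- xx <- vector("list", n_angles)
  for (a in seq_len(n_angles)) {
    t <- vx * cos(angles[a]) + vy * sin(angles[a])
    u <- (t - t0) / radial_spacing
    i0 <- floor(u)
    f <- u - i0
    base <- (a - 1L) * n_rad
    ii[[a]] <- base + c(i0 + 1L, i0 + 2L)
    jj[[a]] <- c(seq_len(nvox), seq_len(nvox))
    xx[[a]] <- wt * c(1 - f, f)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_angles * n_rad, nvox))
  structure(list(A = A, At = Matrix::t(A),
                 grid = grid, n_angles = n_angles, n_rad = n_rad,
                 angles = angles,
                 radial_offsets = t0 + (seq_len(n_rad) - 1) * radial_spacing,
                 radial_spacing = radial_spacing),
            class = "projector_geometry")
}

#' @export
print.projector_geometry <- function(x, ...) {
  cat(sprintf(
    "<projector_geometry> %d angles x %d radial bins (%g mm), plane %d x %d, %d slices\n",
    x$n_angles, x$n_rad, x$radial_spacing,
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Sinogram frames
#'
#' Per-axial-slice parallel-beam data for one time frame: a matrix with one
#' column per slice and one row per (angle, radial bin), angle-major. After
#' Poisson sampling the entries are integer counts; `expected = TRUE` marks
#' noiseless expectation data.
#'
#' @param counts Matrix `(n_angles * n_rad) x n_slices`, non-negative.
#' @param geom A [projector_geometry()].
#' @param frame_start,frame_duration Minutes.
#' @param expected Logical: noiseless expectation rather than counts.
#' @param scale Calibration factor from line integrals to expected counts.
#' @return An object of class `sinogram_frame`.
#' @export
sinogram_frame <- function(counts, geom, frame_start = 0, frame_duration = 10,
                           expected = FALSE, scale = 1) {
  stopifnot(inherits(geom, "projector_geometry"),
            nrow(counts) == geom$n_angles * geom$n_rad,
            ncol(counts) == geom$grid$dims[3])
  if (any(counts < 0)) stop("sinogram counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, geom = geom,
                 frame_start = frame_start, frame_duration = frame_duration,
                 expected = expected, scale = scale),
            class = "sinogram_frame")
}

#' @export
print.sinogram_frame <- function(x, ...) {
  cat(sprintf(
    "<sinogram_frame> %d angles x %d bins x %d slices, frame [%g, %g] min, total %s%.4g\n",
    x$geom$n_angles, x$geom$n_rad, ncol(x$counts),
    x$frame_start, x$frame_start + x$frame_duration,
    if (x$expected) "(expected) " else "", sum(x$counts)))
  invisible(x)
}

#' Forward and back projection
#'
#' `forward_project()` applies the line-integral operator to every axial
#' slice of an activity image; `back_project()` applies its exact adjoint to
#' sinogram data, returning a 3D array on the geometry's grid.
#'
#' @param img An [activity_image()] on the geometry's grid.
#' @param geom A [projector_geometry()].
#' @return A [sinogram_frame()] of expectation line integrals.
#' @export
forward_project <- function(img, geom) {
  stopifnot(inherits(img, "activity_image"),
            identical(img$grid$dims, geom$grid$dims))
  d <- img$grid$dims
  sino <- as.matrix(geom$A %*% matrix(img$values, d[1] * d[2], d[3]))
  sinogram_frame(sino, geom, img$frame_start, img$frame_duration,
                 expected = TRUE)
}

#' @rdname forward_project
#' @param sino A [sinogram_frame()] (or a bare matrix of matching shape).
#' @export
back_project <- function(sino, geom) {
  m <- if (inherits(sino, "sinogram_frame")) sino$counts else sino
  d <- geom$grid$dims
  array(as.matrix(geom$At %*% m), d)
}

# rows of the sinogram belonging to one interleaved angular subset
subset_rows <- function(geom, subset, n_subsets) {
  ang <- seq(subset, geom$n_angles, by = n_subsets)
  as.vector(outer(seq_len(geom$n_rad), (ang - 1L) * geom$n_rad, "+"))
}
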