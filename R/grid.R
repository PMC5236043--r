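#' Voxel grids
#'
#' A `voxel_grid` is a 3D lattice described by voxel counts `dims`, voxel
#' `spacing` in mm, and `origin` — the mm position of the *center* of the
#' first voxel (index `[1, 1, 1]`). All world coordinates in the package
#' refer to voxel centers: voxel `[i, j, k]` is centered at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param dims Integer vector of length 3: voxel counts per axis.
#' @param spacing Numeric length 1 or 3: voxel spacing in mm; positive.
#' @param origin Numeric length 3: mm position of the first voxel center.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 32), spacing = 2)
#' voxel_volume(g)
#' @export
voxel_grid <- function(dims, spacing = 2, origin = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  if (is.null(origin)) {
    # default: grid centered on the world origin
    origin <- -(dims - 1) * spacing / 2
  }
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
    x$dims[1], x$dims[2], x$dims[3],
    paste(format(x$spacing, trim = TRUE), collapse = " x "),
    paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Voxel-center coordinates along one axis
#'
#' @param grid A `voxel_grid`.
#' @param axis 1, 2 or 3.
#' @return Numeric vector of mm coordinates of voxel centers.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing[axis]
}

#' Physical extent of a grid
#'
#' Lower and upper mm bounds of the voxel *cells* (centers +/- spacing/2).
#'
#' @param grid A `voxel_grid`.
#' @return A 2 x 3 matrix with rows `lo`, `hi`.
#' @export
grid_extent <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$dims - 1 + 0.5) * grid$spacing
  rbind(lo = lo, hi = hi)
}

# nearest voxel index (length-3 integer) for a world position; clamped in-grid
nearest_voxel <- function(grid, pos) {
  idx <- round((pos - grid$origin) / grid$spacing) + 1
  pmin(pmax(as.integer(idx), 1L), grid$dims)
}

# TRUE if the world position lies inside the grid's cell extent
in_grid <- function(grid, pos) {
  ext <- grid_extent(grid)
  all(pos >= ext["lo", ] & pos <= ext["hi", ])
}
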