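#' Sphere and phantom specifications
#'
#' `sphere_spec()` describes one wall-less gel sphere: diameter (mm), center
#' (mm, world coordinates), concentration at time zero (Bq/mL). All spheres
#' of a phantom share one isotope and starting concentration, held at the
#' phantom level. `phantom_spec()` assembles the full phantom: the spheres,
#' the box-shaped background region with its own isotope, the reference
#' region (same fill as the spheres) whose central 6-mL cube VOI supplies the
#' measured "true" concentration, and the 15-mL background measurement VOI.
#'
#' @param diameter Sphere diameter, mm.
#' @param center Numeric length 3, mm.
#' @param id Optional sphere label.
#' @return `sphere_spec()`: a one-row tibble.
#' @export
sphere_spec <- function(diameter, center, id = NULL) {
  stopifnot(diameter > 0, length(center) == 3L)
  tibble::tibble(
    id = if (is.null(id)) NA_character_ else as.character(id),
    diameter = as.numeric(diameter),
    x = center[1], y = center[2], z = center[3])
}

#' @rdname sphere_spec
#' @param spheres Tibble with columns `id`, `diameter`, `x`, `y`, `z`
#'   (one row per sphere), e.g. built by binding [sphere_spec()] rows.
#' @param sphere_concentration0 Bq/mL at time zero, shared by all spheres
#'   and by the reference region.
#' @param sphere_isotope,background_isotope [isotope()] objects; defaults
#'   are the dual-isotope design (F-18 spheres in a C-11 background).
#' @param background_box 2 x 3 matrix (rows lo, hi) of the background region
#'   bounds in mm.
#' @param background_concentration0 Bq/mL of the background at time zero.
#' @param reference_center,background_voi_center Centers (mm) of the 6-mL
#'   reference VOI and the 15-mL background VOI.
#' @param reference_pad Padding (mm) of the physical reference region beyond
#'   its 6-mL measurement cube, so the VOI is unaffected by edge blur.
#' @export
phantom_spec <- function(spheres,
                         sphere_concentration0,
                         background_box,
                         background_concentration0,
                         reference_center,
                         background_voi_center,
                         sphere_isotope = isotope_f18(),
                         background_isotope = isotope_c11(),
                         reference_pad = 10) {
  stopifnot(is.data.frame(spheres),
            all(c("diameter", "x", "y", "z") %in% names(spheres)),
            sphere_concentration0 >= 0, background_concentration0 >= 0,
            inherits(sphere_isotope, "isotope"),
            inherits(background_isotope, "isotope"))
  spheres <- tibble::as_tibble(spheres)
  if (!"id" %in% names(spheres) || anyNA(spheres$id)) {
    spheres$id <- sprintf("s%02d", seq_len(nrow(spheres)))
  }
  # pairwise non-overlap
  if (nrow(spheres) > 1) {
    ctr <- as.matrix(spheres[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(ctr))
    rsum <- outer(spheres$diameter, spheres$diameter, "+") / 2
    diag(d) <- Inf
    if (any(d <= rsum)) stop("spheres overlap", call. = FALSE)
  }
  background_box <- rbind(lo = pmin(background_box[1, ], background_box[2, ]),
                          hi = pmax(background_box[1, ], background_box[2, ]))
  ph <- structure(list(
    spheres = spheres,
    sphere_concentration0 = as.numeric(sphere_concentration0),
    sphere_isotope = sphere_isotope,
    background = list(box = background_box,
                      concentration0 = as.numeric(background_concentration0),
                      isotope = background_isotope),
    reference = list(center = as.numeric(reference_center), volume_ml = 6,
                     pad = as.numeric(reference_pad)),
    background_voi = list(center = as.numeric(background_voi_center),
                          volume_ml = 15)
  ), class = "phantom_spec")
  validate_phantom(ph)
  ph
}

validate_phantom <- function(ph) {
  # measurement VOIs must clear every sphere; half-widths of the near-cubic
  # measurement blocks as realized on the default 2-mm grid
  for (voi in list(c(ph$background_voi$center, ph$background_voi$volume_ml),
                   c(ph$reference$center, ph$reference$volume_ml))) {
    half <- near_cubic_dims(round(1000 * voi[4] / 8))  # in 2-mm voxels
    lo <- voi[1:3] - half; hi <- voi[1:3] + half
    ctr <- as.matrix(ph$spheres[, c("x", "y", "z")])
    nearest <- pmin(pmax(ctr, rep(lo, each = nrow(ctr))),
                    rep(hi, each = nrow(ctr)))
    gap <- sqrt(rowSums((nearest - ctr)^2)) - ph$spheres$diameter / 2
    if (any(gap <= 0)) stop("measurement VOI intersects a sphere", call. = FALSE)
  }
  bg <- ph$background$box
  vol_ml <- prod(bg["hi", ] - bg["lo", ]) / 1000
  if (vol_ml < 250) stop("background region must be at least 250 mL", call. = FALSE)
  invisible(ph)
}

#' @export
print.phantom_spec <- function(x, ...) {
  bg <- x$background$box
  cat(sprintf(
    "<phantom_spec> %d spheres (%s mm), %s %.0f Bq/mL; background %s %.0f Bq/mL, %.0f mL\n",
    nrow(x$spheres), paste(sort(unique(x$spheres$diameter)), collapse = "/"),
    x$sphere_isotope$name, x$sphere_concentration0,
    x$background$isotope$name, x$background$concentration0,
    prod(bg["hi", ] - bg["lo", ]) / 1000))
  invisible(x)
}

#' Default dual-isotope sphere phantoms
#'
#' `phantom_default()` reproduces the physical phantom: twelve F-18 gel
#' spheres (diameters 10, 10, 6, 6, 12, 4, 10, 3, 8, 4, 4 and 6 mm) strung
#' 24 mm apart along the x axis, suspended wall-less in a C-11 background box,
#' with a padded F-18 reference region beside the background.
#' `phantom_compact()` keeps one sphere per unique diameter (3--12 mm) on a
#' shorter string; it is the economical variant used for fast experiments.
#' Both start at 1:1 sphere-to-background contrast so that differential decay
#' sweeps the true ratio upward.
#'
#' @param concentration0 Starting concentration (Bq/mL) of spheres,
#'   reference and background alike (1:1 start).
#' @param spacing_mm Center-to-center spacing along the string.
#' @param center_offset Length-3 mm shift applied to every sphere center
#'   (default 0: centers coincide with voxel centers of [phantom_grid()]).
#' @param background_isotope Background fill isotope; the default C-11 gives
#'   the growing-contrast design. Passing [isotope_f18()] yields a
#'   same-decay control phantom whose true ratio is exactly 1 in every
#'   frame.
#' @return A [phantom_spec()].
#' @export
phantom_default <- function(concentration0 = 5e4, spacing_mm = 24,
                            center_offset = c(0, 0, 0),
                            background_isotope = isotope_c11()) {
  diam <- c(10, 10, 6, 6, 12, 4, 10, 3, 8, 4, 4, 6)
  build_string_phantom(diam, concentration0, spacing_mm, center_offset,
                       background_isotope)
}

#' @rdname phantom_default
#' @export
phantom_compact <- function(concentration0 = 5e4, spacing_mm = 24,
                            center_offset = c(0, 0, 0),
                            background_isotope = isotope_c11()) {
  build_string_phantom(c(3, 4, 6, 8, 10, 12), concentration0, spacing_mm,
                       center_offset, background_isotope)
}

build_string_phantom <- function(diam, concentration0, spacing_mm,
                                 center_offset,
                                 background_isotope = isotope_c11()) {
  n <- length(diam)
  xs <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  xs <- 2 * round(xs / 2)              # keep centers on the 2-mm lattice
  spheres <- tibble::tibble(
    id = sprintf("s%02d_%dmm", seq_len(n), diam),
    diameter = diam,
    x = xs + center_offset[1], y = center_offset[2], z = center_offset[3])
  bg_halfx <- max(abs(xs)) + 18
  bg_halfx <- max(bg_halfx, ceiling((250e3 / (40 * 48) / 2)))  # >= 250 mL
  bg_halfx <- 2 * ceiling(bg_halfx / 2)
  bg_box <- rbind(lo = c(-bg_halfx, -20, -24), hi = c(bg_halfx, 20, 24))
  ref_center <- c(bg_halfx + 1 + 25, 0, 0)       # physical box abuts air gap
  ref_center[1] <- 2 * round(ref_center[1] / 2)  # VOI center on-lattice
  bgv_x <- 2 * round((xs[2] + (xs[2] - xs[1]) / 6) / 2)  # over the string, offset in z
  phantom_spec(
    spheres = spheres,
    sphere_concentration0 = concentration0,
    background_box = bg_box,
    background_concentration0 = concentration0,
    reference_center = ref_center,
    background_voi_center = c(bgv_x, 0, 16),
    background_isotope = background_isotope)
}

#' Grid fitted to a phantom
#'
#' Builds an isotropic [voxel_grid()] covering the phantom (background box,
#' spheres and padded reference region) plus `margin` mm on every side, with
#' the lattice phased so the phantom's sphere and VOI centers fall on voxel
#' centers when they are multiples of `spacing`.
#'
#' @param phantom A [phantom_spec()].
#' @param spacing Voxel size in mm (isotropic).
#' @param margin Clearance beyond the phantom, mm; at least 4 sigma of the
#'   system blur is recommended so blurred activity stays in-grid.
#' @return A [voxel_grid()].
#' @export
phantom_grid <- function(phantom, spacing = 2, margin = 18) {
  ref <- phantom$reference
  nvox <- round(1000 * ref$volume_ml / spacing^3)
  half_voi <- near_cubic_dims(nvox) * spacing / 2 + ref$pad
  lo <- pmin(phantom$background$box["lo", ], ref$center - half_voi,
             with(phantom$spheres, c(min(x - diameter / 2),
                                     min(y - diameter / 2),
                                     min(z - diameter / 2)))) - margin
  hi <- pmax(phantom$background$box["hi", ], ref$center + half_voi,
             with(phantom$spheres, c(max(x + diameter / 2),
                                     max(y + diameter / 2),
                                     max(z + diameter / 2)))) + margin
  # first voxel center: on the `spacing` lattice, at or below lo + spacing/2
  origin <- spacing * floor((lo + spacing / 2) / spacing)
  dims <- ceiling((hi - spacing / 2 - origin) / spacing) + 1
  voxel_grid(dims, spacing = spacing, origin = origin)
}

#' Activity images
#'
#' A 3D image of activity concentration (Bq/mL) on a [voxel_grid()], tagged
#' with the acquisition frame it represents.
#'
#' @param grid A [voxel_grid()].
#' @param values 3D numeric array matching `grid$dims`; non-negative.
#' @param frame_start,frame_duration Frame timing in minutes.
#' @return An object of class `activity_image`.
#' @export
activity_image <- function(grid, values, frame_start = 0, frame_duration = 10) {
  stopifnot(inherits(grid, "voxel_grid"),
            identical(dim(values), as.integer(grid$dims)))
  if (any(values < 0)) stop("activity values must be non-negative", call. = FALSE)
  if (frame_duration <= 0) stop("`frame_duration` must be positive", call. = FALSE)
  structure(list(grid = grid, values = values,
                 frame_start = as.numeric(frame_start),
                 frame_duration = as.numeric(frame_duration)),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf(
    "<activity_image> %d x %d x %d voxels, frame [%g, %g] min, total %.3g Bq\n",
    x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
    x$frame_start, x$frame_start + x$frame_duration,
    sum(x$values) * voxel_volume(x$grid) / 1000))
  invisible(x)
}

# frame-mean concentrations of each phantom compartment
phantom_frame_concentrations <- function(phantom, frame_start, frame_duration) {
  fm <- function(c0, iso) {
    if (frame_duration == 0) decayed_concentration(c0, iso, frame_start)
    else frame_mean_concentration(c0, iso, frame_start, frame_duration)
  }
  list(sphere = fm(phantom$sphere_concentration0, phantom$sphere_isotope),
       background = fm(phantom$background$concentration0,
                       phantom$background$isotope))
}

#' True sphere-to-background ratio of a frame
#'
#' Ratio of the frame-averaged sphere concentration to the frame-averaged
#' background concentration. With F-18 spheres in a C-11 background this
#' ratio grows monotonically over successive frames; being a same-time ratio
#' it is independent of any decay-correction convention. `frame_duration = 0`
#' gives the instantaneous ratio.
#'
#' @param phantom A [phantom_spec()].
#' @param frame_start,frame_duration Minutes.
#' @return Dimensionless ratio.
#' @export
true_ratio <- function(phantom, frame_start, frame_duration = 10) {
  cc <- phantom_frame_concentrations(phantom, frame_start, frame_duration)
  if (cc$background <= 0) {
    stop("background frame-mean concentration is zero: ratio undefined",
         call. = FALSE)
  }
  cc$sphere / cc$background
}

#' Rasterize a phantom into a ground-truth activity image
#'
#' Paints the frame-averaged concentration of every compartment onto the
#' grid. Sphere surfaces are anti-aliased by volume weighting: each voxel is
#' subdivided into `supersample`^3 sub-voxels whose centers are tested
#' against the sphere surface, and the voxel value mixes sphere and
#' background concentration by the resulting volume fraction. The phantom is
#' wall-less: spheres sit directly in background with no cold shell.
#' `supersample = 1` degrades to binary center-in-sphere rasterization.
#'
#' @param phantom A [phantom_spec()].
#' @param grid A [voxel_grid()] (e.g. [phantom_grid()]).
#' @param frame_start,frame_duration Frame timing, minutes.
#' @param supersample Sub-voxels per axis for surface anti-aliasing. For
#'   `supersample > 1` the fraction is sampled at sub-voxel midpoints in
#'   the plane and integrated analytically along z (sphere chord clipped to
#'   the voxel), and the in-plane sampling is automatically refined for
#'   spheres small relative to the voxel, keeping total activity within 1%
#'   of the analytic volume from `supersample = 4` up.
#' @return An [activity_image()].
#' @export
rasterize <- function(phantom, grid, frame_start = 0, frame_duration = 10,
                      supersample = 4) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(grid, "voxel_grid"),
            supersample >= 1)
  supersample <- as.integer(supersample)
  cc <- phantom_frame_concentrations(phantom, frame_start, frame_duration)

  ax <- lapply(1:3, function(a) grid_axis(grid, a))
  # background region: voxel-center membership
  inb <- lapply(1:3, function(a)
    ax[[a]] >= phantom$background$box["lo", a] &
    ax[[a]] <= phantom$background$box["hi", a])
  vals <- array(0, dim = grid$dims)
  bg_mask <- outer(outer(inb[[1]], inb[[2]], "&"), inb[[3]], "&")
  vals[bg_mask] <- cc$background

  # physical reference region: the 6-mL measurement block padded on every
  # face, so the VOI mean is untouched by edge blur
  nvox <- round(1000 * phantom$reference$volume_ml / voxel_volume(grid))
  half <- near_cubic_dims(nvox) * grid$spacing / 2 + phantom$reference$pad
  inr <- lapply(1:3, function(a)
    ax[[a]] >= phantom$reference$center[a] - half[a] &
    ax[[a]] <= phantom$reference$center[a] + half[a])
  ref_mask <- outer(outer(inr[[1]], inr[[2]], "&"), inr[[3]], "&")
  vals[ref_mask] <- cc$sphere

  # spheres: supersampled volume fractions blended over the background
  ext <- grid_extent(grid)
  for (s in seq_len(nrow(phantom$spheres))) {
    ctr <- as.numeric(phantom$spheres[s, c("x", "y", "z")])
    r <- phantom$spheres$diameter[s] / 2
    if (any(ctr - r < ext["lo", ]) || any(ctr + r > ext["hi", ]))
      stop("sphere extends outside the grid", call. = FALSE)
    ir <- lapply(1:3, function(a) which(abs(ax[[a]] - ctr[a]) <= r + grid$spacing[a]))
    # refine the in-plane sampling for spheres near the voxel size
    ss <- if (supersample > 1L) {
      max(supersample, ceiling(8 * max(grid$spacing[1:2]) / r))
    } else 1L
    off <- (seq_len(ss) - (ss + 1) / 2) / ss
    sub <- lapply(1:2, function(a) {
      centers <- ax[[a]][ir[[a]]]
      outer(centers, off * grid$spacing[a], "+") - ctr[a]  # n_vox x ss offsets
    })
    n <- vapply(ir, length, 1L)
    d2x <- sub[[1]]^2; d2y <- sub[[2]]^2
    zc <- ax[[3]][ir[[3]]] - ctr[3]
    dz <- grid$spacing[3]
    if (supersample == 1L) {
      # binary voxel-center rasterization
      d2z <- zc^2
      frac <- (outer(outer(d2x[, 1], d2y[, 1], "+"), d2z, "+") < r^2) * 1
    } else {
      # hybrid anti-aliasing: midpoint-sampled in-plane, analytic along z —
      # each (x, y) sub-column contributes its sphere chord clipped to the
      # voxel's z extent, which keeps total activity within the analytic
      # sphere volume even for spheres near the voxel size
      frac <- array(0, n)
      for (kx in seq_len(ss)) {
        for (ky in seq_len(ss)) {
          s2 <- r^2 - outer(d2x[, kx], d2y[, ky], "+")
          s <- sqrt(pmax(s2, 0))
          for (kz in seq_along(zc)) {
            ov <- pmin(s, zc[kz] + dz / 2) - pmax(-s, zc[kz] - dz / 2)
            frac[, , kz] <- frac[, , kz] + pmax(ov, 0) / dz
          }
        }
      }
      frac <- frac / ss^2
    }
    vals[ir[[1]], ir[[2]], ir[[3]]] <-
      vals[ir[[1]], ir[[2]], ir[[3]]] * (1 - frac) + cc$sphere * frac
  }
  activity_image(grid, vals, frame_start, frame_duration)
}
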