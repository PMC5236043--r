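# Shared heavyweight fixtures, built lazily once per test run.
.shared <- new.env(parent = emptyenv())

# compact 6-sphere phantom with its grid and projector
shared_compact <- function() {
  if (is.null(.shared$compact)) {
    ph <- phantom_compact()
    grid <- phantom_grid(ph)
    geom <- projector_geometry(grid)
    .shared$compact <- list(phantom = ph, grid = grid, geom = geom)
  }
  .shared$compact
}

# noiseless sinogram of the frame whose frame-mean contrast is nearest
# `ratio`, on the shared compact phantom
shared_noiseless_frame <- function(ratio) {
  key <- paste0("frame_", ratio)
  if (is.null(.shared[[key]])) {
    sc <- shared_compact()
    cfg <- experiment_config(phantom = sc$phantom,
                             acquisition = acquisition_config(noiseless = TRUE))
    f <- frame_nearest_ratio(cfg, ratio)
    t0 <- (f - 1) * cfg$frame_duration
    img <- rasterize(sc$phantom, sc$grid, t0, cfg$frame_duration)
    .shared[[key]] <- simulate_frame(img, cfg$acquisition, sc$geom)
  }
  .shared[[key]]
}

# noiseless iteration sweep over the default variant pair (used by several
# acceptance checks; two reconstructions total)
shared_iteration_sweep <- function() {
  if (is.null(.shared$sweep)) {
    sc <- shared_compact()
    cfg <- experiment_config(phantom = sc$phantom,
                             acquisition = acquisition_config(noiseless = TRUE))
    .shared$sweep <- run_iteration_sweep(cfg, iterations = 1:6,
                                         postfilters = c(2, 3, 4, 6))
  }
  .shared$sweep
}

# small toy tomographic system: a blob on a tiny grid plus its projector
toy_system <- function(dims = c(10, 10, 2), n_angles = 12, seed = 7) {
  grid <- voxel_grid(dims, spacing = 2)
  geom <- projector_geometry(grid, n_angles = n_angles)
  set.seed(seed)
  vals <- array(1, dims)
  ctr <- (dims + 1) / 2
  for (k in seq_len(dims[3])) {
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      vals[i, j, k] <- 1 + 5 * exp(-sum(((c(i, j) - ctr[1:2]) / 2)^2))
    }
  }
  img <- activity_image(grid, vals, 0, 10)
  list(grid = grid, geom = geom, img = img)
}

# independent brute-force dense 3D Gaussian convolution (non-separable path)
brute_gaussian_blur <- function(arr, spacing, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  sv <- sigma / spacing
  r <- max(1L, ceiling(6 * sv) + 1L)
  off <- (-r):r
  w1 <- exp(-off^2 / (2 * sv^2))
  w1 <- w1 / sum(w1)
  k3 <- outer(outer(w1, w1), w1)   # separable kernel, materialized densely
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- i + off; jj <- j + off; kk <- k + off
    vi <- ii >= 1 & ii <= d[1]; vj <- jj >= 1 & jj <= d[2]
    vk <- kk >= 1 & kk <= d[3]
    out[i, j, k] <- sum(arr[ii[vi], jj[vj], kk[vk]] *
                          k3[vi, vj, vk, drop = FALSE])
  }
  out
}

# independent lattice-point enumeration: voxel centers strictly inside a
# sphere of given diameter, centers on a `pitch`-spaced lattice through 0
lattice_sphere_count <- function(diameter, pitch = 2) {
  r <- diameter / 2
  reach <- ceiling(r / pitch) + 1
  off <- pitch * (-reach:reach)
  sum(outer(outer(off^2, off^2, "+"), off^2, "+") < r^2)
}
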