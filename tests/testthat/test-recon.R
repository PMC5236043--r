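test_that("sensitivity images are positive, additive over subsets, and PSF-neutral at zero width", {
  ts <- toy_system(dims = c(10, 10, 2), n_angles = 12)
  p4 <- recon_params(1, 4, psf_modeled = FALSE)
  full <- sensitivity_image(ts$geom, p4)
  expect_true(all(full > 0))
  # full angular coverage: interior voxels see nearly constant sensitivity
  interior <- full[4:7, 4:7, ]
  expect_lt(diff(range(interior)) / mean(interior), 0.01)
  # subset sensitivities partition the full one
  subs <- lapply(1:4, function(s) sensitivity_image(ts$geom, p4, s))
  expect_equal(Reduce(`+`, subs), full, tolerance = 1e-12)
  # a zero-width modelled kernel changes nothing
  p0 <- recon_params(1, 4, psf_modeled = TRUE, psf_fwhm = 0)
  expect_equal(sensitivity_image(ts$geom, p0), full, tolerance = 1e-15)
})

test_that("noiseless data at the truth is an EM fixed point", {
  ts <- toy_system(dims = c(10, 10, 2), n_angles = 12)
  for (psf in c(FALSE, TRUE)) {
    params <- recon_params(1, 1, psf_modeled = psf, psf_fwhm = 4.5,
                           postfilter_fwhm = 0)
    x <- ts$img$values
    blur <- if (psf) gaussian_blur_operator(ts$grid, 4.5) else identity
    y <- as.matrix(ts$geom$A %*% matrix(blur(x), prod(ts$grid$dims[1:2]),
                                        ts$grid$dims[3]))
    x1 <- em_update(x, y, ts$geom, params, subset = 1)
    expect_equal(x1, x, tolerance = 1e-10)
  }
})

test_that("MLEM solves an invertible two-voxel system to the direct solution", {
  g <- voxel_grid(c(2, 1, 1), spacing = 2)
  geom <- projector_geometry(g, n_angles = 2)
  x_true <- array(c(2, 5), c(2, 1, 1))
  A <- as.matrix(geom$A)
  expect_equal(qr(A)$rank, 2)
  y <- matrix(A %*% as.vector(x_true), ncol = 1)
  sino <- sinogram_frame(y, geom, expected = TRUE)
  res <- reconstruct(sino, recon_params(500, 1, psf_modeled = FALSE,
                                        postfilter_fwhm = 0))
  direct <- qr.solve(A, y)   # independent oracle: direct linear solve
  expect_equal(as.vector(res$image$values), as.vector(direct),
               tolerance = 1e-6)
  expect_equal(as.vector(direct), c(2, 5), tolerance = 1e-9)
})

test_that("each full MLEM iteration preserves the sensitivity-weighted total count", {
  ts <- toy_system(dims = c(8, 8, 2), n_angles = 8)
  cfg <- acquisition_config(n_angles = 8, target_counts = 5e4)
  sf <- simulate_frame(ts$img, cfg, ts$geom, seed = 2)
  params <- recon_params(8, 1, psf_modeled = TRUE, psf_fwhm = 4,
                         postfilter_fwhm = 0, keep_iterations = TRUE)
  res <- reconstruct(sf, params)
  sens <- sensitivity_image(ts$geom, params)
  for (it in seq_along(res$snapshots)) {
    expect_equal(sum(sens * res$snapshots[[it]]), sum(sf$counts),
                 tolerance = 1e-8)
  }
})

test_that("the MLEM likelihood trace never decreases on noisy data", {
  ts <- toy_system(dims = c(8, 8, 1), n_angles = 8)
  cfg <- acquisition_config(n_angles = 8, target_counts = 2e4)
  sf <- simulate_frame(ts$img, cfg, ts$geom, seed = 4)
  for (psf in c(FALSE, TRUE)) {
    res <- reconstruct(sf, recon_params(50, 1, psf_modeled = psf,
                                        psf_fwhm = 4, postfilter_fwhm = 0,
                                        track_loglik = TRUE))
    expect_true(all(diff(res$loglik) > -1e-7 * abs(res$loglik[1])))
    expect_gt(res$loglik[50], res$loglik[1])
  }
})

test_that("loglik handles zero counts and is stationary at the data", {
  ts <- toy_system(dims = c(6, 6, 1), n_angles = 6)
  params <- recon_params(1, 1, psf_modeled = FALSE, postfilter_fwhm = 0)
  x <- ts$img$values
  y <- as.matrix(ts$geom$A %*% matrix(x, 36, 1))
  # y = Bx is maximal over scalar rescalings of x
  ll <- vapply(c(0.8, 0.95, 1, 1.05, 1.2), function(k)
    loglik(k * x, y, ts$geom, params), 0)
  expect_equal(which.max(ll), 3L)
  expect_equal(loglik(array(0, dim(x)), 0 * y, ts$geom, params), 0)
})

test_that("reconstruction keeps zeros, non-negativity and determinism", {
  ts <- toy_system(dims = c(10, 10, 2), n_angles = 12)
  cfg <- acquisition_config(n_angles = 12, target_counts = 1e5)
  sf <- simulate_frame(ts$img, cfg, ts$geom, seed = 8)
  params <- recon_params(3, 4, psf_modeled = TRUE, psf_fwhm = 4,
                         postfilter_fwhm = 0)
  r1 <- reconstruct(sf, params)
  r2 <- reconstruct(sf, params)
  expect_identical(r1$image$values, r2$image$values)
  expect_true(all(r1$image$values >= 0))
  # zeroed initial voxels never revive under the multiplicative update
  init <- array(1, ts$grid$dims)
  init[1:3, , ] <- 0
  rz <- reconstruct(sf, params, initial = init)
  expect_true(all(rz$image$values[1:3, , ] == 0))
  expect_error(reconstruct(sf, recon_params(1, 5)), "divide")
})

test_that("a uniform object reconstructs uniformly from noiseless data", {
  g <- voxel_grid(c(28, 28, 4), spacing = 2)
  vals <- array(0, g$dims)
  vals[5:24, 5:24, ] <- 10
  img <- activity_image(g, vals)
  geom <- projector_geometry(g, n_angles = 72)
  cfg <- acquisition_config(system_fwhm = 0, n_angles = 72,
                            target_counts = 1e6, noiseless = TRUE)
  sf <- simulate_frame(img, cfg, geom)
  for (psf in c(FALSE, TRUE)) {
    res <- reconstruct(sf, recon_params(10, 6, psf_modeled = psf,
                                        psf_fwhm = 0, postfilter_fwhm = 0))
    interior <- res$image$values[12:17, 12:17, 2:3]
    expect_lt(diff(range(interior)) / mean(interior), 0.005)
  }
})

test_that("post-filtering can only lower the maximum of a hot spot", {
  g <- voxel_grid(c(21, 21, 9), spacing = 2)
  arr <- array(0.1, g$dims)
  arr[9:13, 9:13, 4:6] <- 10
  img <- activity_image(g, arr)
  m0 <- max(img$values)
  for (f in c(2, 3, 4, 6)) {
    expect_lte(max(gaussian_postfilter(img, f)$values), m0)
  }
  expect_identical(gaussian_postfilter(img, 0)$values, arr)
})

test_that("tidy and glance summarize a reconstruction", {
  ts <- toy_system(dims = c(8, 8, 1), n_angles = 8)
  cfg <- acquisition_config(n_angles = 8, target_counts = 2e4)
  sf <- simulate_frame(ts$img, cfg, ts$geom, seed = 4)
  res <- reconstruct(sf, recon_params(5, 1, psf_modeled = FALSE,
                                      postfilter_fwhm = 0,
                                      track_loglik = TRUE))
  td <- tidy(res)
  expect_equal(td$iteration, 1:5)
  expect_true(all(is.finite(td$loglik)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$total_counts, sum(sf$counts))
  expect_false(gl$psf_modeled)
})
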