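test_that("decay law matches its closed form and rejects bad input", {
  f18 <- isotope_f18()
  c11 <- isotope_c11()
  expect_equal(decayed_concentration(100, f18, 0), 100)
  expect_equal(decayed_concentration(100, c11, 20.36), 50)
  # 100 * 2^(-60/109.77), evaluated independently
  expect_equal(decayed_concentration(100, f18, 60), 68.4632919572,
               tolerance = 1e-10)
  expect_error(decayed_concentration(-1, f18, 5), "non-negative")
  expect_error(decayed_concentration(100, f18, -5), "non-negative")
  expect_error(isotope("X", 0), "positive")
})

test_that("frame-mean concentration agrees with numerical quadrature", {
  cases <- list(c(100, 0, 20.36), c(100, 35, 10), c(7, 120, 10))
  for (iso in list(isotope_f18(), isotope_c11())) {
    for (cs in cases) {
      quad <- stats::integrate(
        function(t) decayed_concentration(cs[1], iso, t),
        cs[2], cs[2] + cs[3], rel.tol = 1e-12)$value / cs[3]
      expect_equal(frame_mean_concentration(cs[1], iso, cs[2], cs[3]), quad,
                   tolerance = 1e-8)
    }
  }
  # short-frame limit approaches the instantaneous value (the genuine
  # first-order gap is dt * lambda / 2, so dt = 1e-5 min sits well inside
  # a 1e-6 relative band)
  expect_equal(frame_mean_concentration(100, isotope_c11(), 30, 1e-5),
               decayed_concentration(100, isotope_c11(), 30),
               tolerance = 1e-6)
  expect_equal(frame_mean_concentration(0, isotope_f18(), 5, 10), 0)
  expect_error(frame_mean_concentration(1, isotope_f18(), 0, 0), "positive")
})

test_that("true ratio: unit for same isotope, closed form and monotone growth for the dual-isotope design", {
  ph_same <- phantom_compact(background_isotope = isotope_f18())
  for (t0 in c(0, 30, 100)) expect_equal(true_ratio(ph_same, t0, 10), 1)

  ph <- phantom_compact()
  # instantaneous ratio at 60 min: exp(60 ln2 (1/20.36 - 1/109.77))
  expect_equal(true_ratio(ph, 60, 0), 5.27933927155, tolerance = 1e-10)
  ratios <- vapply(0:10, function(k) true_ratio(ph, 10 * k, 10), 0)
  expect_true(all(diff(ratios) > 0))
  # 1:1 -> beyond 15:1 across the default 11-frame schedule
  expect_lt(ratios[1], 1.2)
  expect_gt(ratios[11], 15)
  # a same-time ratio is invariant to any decay-correction rescaling
  expect_equal(true_ratio(ph, 40, 10),
               true_ratio(phantom_compact(concentration0 = 1), 40, 10))
})

test_that("rasterization conserves sphere activity and degrades gracefully", {
  # one sphere on a zero background: total activity vs analytic volume
  sp <- sphere_spec(10, c(0, 0, 0), id = "s")
  ph <- phantom_spec(sp, sphere_concentration0 = 1000,
                     background_box = rbind(c(-70, -20, -24), c(70, 20, 24)),
                     background_concentration0 = 0,
                     reference_center = c(100, 0, 0),
                     background_voi_center = c(-40, 0, 16),
                     background_isotope = isotope_f18())
  grid <- phantom_grid(ph, margin = 10)
  img <- rasterize(ph, grid, 0, 10, supersample = 4)
  cc <- frame_mean_concentration(1000, isotope_f18(), 0, 10)
  # integrate over a box holding only the sphere (background is cold, the
  # reference region sits far away at x = 100)
  near <- abs(grid_axis(grid, 1)) <= 16
  sphere_total <- sum(img$values[near, , ]) * voxel_volume(grid)
  expect_equal(sphere_total, cc * (4 / 3) * pi * 5^3, tolerance = 0.01)

  # equal concentrations and equal decay: background box stays uniform
  ph_eq <- phantom_compact(background_isotope = isotope_f18())
  g2 <- phantom_grid(ph_eq)
  img_eq <- rasterize(ph_eq, g2, 0, 10)
  ax <- lapply(1:3, function(a) grid_axis(g2, a))
  inb <- img_eq$values[ax[[1]] >= -70 & ax[[1]] <= 70,
                       abs(ax[[2]]) <= 20, abs(ax[[3]]) <= 24]
  expect_equal(max(inb), min(inb))

  # supersample = 1 is binary voxel-center rasterization
  img_b <- rasterize(ph, grid, 0, 10, supersample = 1)
  expect_true(all(img_b$values %in% c(0, cc)))

  # sphere partially outside the grid is a geometry error
  small <- voxel_grid(c(4, 4, 4), spacing = 2)
  expect_error(rasterize(ph, small, 0, 10), "outside")
})

test_that("phantom invariants are enforced", {
  expect_error(phantom_spec(
    dplyr::bind_rows(sphere_spec(10, c(0, 0, 0)), sphere_spec(10, c(8, 0, 0))),
    1000, rbind(c(-80, -20, -24), c(80, 20, 24)), 1000,
    c(110, 0, 0), c(-40, 0, 16)), "overlap")
  expect_error(phantom_spec(
    sphere_spec(4, c(0, 0, 0)),
    1000, rbind(c(-40, -20, -24), c(40, 20, 24)), 1000,
    c(80, 0, 0), c(-30, 0, 16)), "250 mL")
  # background VOI sitting on a sphere is rejected
  expect_error(phantom_spec(
    sphere_spec(10, c(-40, 0, 16)),
    1000, rbind(c(-80, -20, -24), c(80, 20, 24)), 1000,
    c(110, 0, 0), c(-40, 0, 16)), "intersects")
})

test_that("phantom grids put sphere and VOI centers on voxel centers", {
  ph <- phantom_default()
  grid <- phantom_grid(ph)
  on_lattice <- function(p) {
    idx <- (p - grid$origin) / grid$spacing
    max(abs(idx - round(idx)))
  }
  for (i in seq_len(nrow(ph$spheres))) {
    expect_lt(on_lattice(as.numeric(ph$spheres[i, c("x", "y", "z")])), 1e-9)
  }
  expect_lt(on_lattice(ph$reference$center), 1e-9)
  expect_lt(on_lattice(ph$background_voi$center), 1e-9)
  # twelve spheres with the standard diameter multiset
  expect_equal(sort(ph$spheres$diameter),
               sort(c(10, 10, 6, 6, 12, 4, 10, 3, 8, 4, 4, 6)))
})
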