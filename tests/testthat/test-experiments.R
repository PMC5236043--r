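test_that("the frame schedule matches the closed-form decay ratio", {
  cfg <- experiment_config(phantom = phantom_compact())
  sched <- frame_schedule(cfg)
  expect_equal(nrow(sched), 11)
  want <- vapply(sched$frame_start, function(t0) {
    fs <- frame_mean_concentration(1, isotope_f18(), t0, 10)
    fb <- frame_mean_concentration(1, isotope_c11(), t0, 10)
    fs / fb
  }, 0)
  expect_equal(sched$true_ratio, want, tolerance = 1e-9)
  expect_equal(frame_nearest_ratio(cfg, 8), 8)
  expect_equal(frame_nearest_ratio(cfg, 1), 1)
})

test_that("derived seeds are deterministic, distinct and 32-bit safe", {
  s <- outer(1:6, 1:30, function(f, r)
    mapply(function(ff, rr) rcpet:::derive_seed(123, ff, rr), f, r))
  expect_equal(anyDuplicated(as.vector(s)), 0)
  expect_true(all(abs(s) < 2^31))
  expect_identical(rcpet:::derive_seed(5, 2, 3), rcpet:::derive_seed(5, 2, 3))
})

test_that("monotonicity diagnostics flag the characteristic rank orders", {
  base <- tibble::tibble(diameter = c(3, 4, 6, 8, 10, 12), recon = "a")
  inc <- dplyr::mutate(base, rc_50bg = c(.2, .3, .5, .7, .8, .9))
  d <- monotonicity_diagnostics(inc)
  expect_true(d$is_monotone)
  expect_equal(d$argmax_diameter, 12)
  expect_equal(d$n_above_1, 0)

  # the PSF rank order: 8 > 10 > 12 > 6 > 4 > 3
  psf <- dplyr::mutate(base, rc_50bg = c(.3, .5, .9, 1.3, 1.2, 1.1))
  d2 <- monotonicity_diagnostics(psf)
  expect_false(d2$is_monotone)
  expect_equal(d2$argmax_diameter, 8)
  expect_equal(d2$n_above_1, 3)

  # ties count as monotone, argmax resolves to the largest diameter
  flat <- dplyr::mutate(base, rc_50bg = 0.7)
  d3 <- monotonicity_diagnostics(flat)
  expect_true(d3$is_monotone)
  expect_equal(d3$argmax_diameter, 12)

  # dips within tolerance do not break the flag
  jitter <- dplyr::mutate(base, rc_50bg = c(.2, .3, .5, .7, .69, .9))
  expect_true(monotonicity_diagnostics(jitter, tol = 0.02)$is_monotone)
  expect_false(monotonicity_diagnostics(jitter, tol = 0.001)$is_monotone)
})

test_that("the minimal restoring filter scans nested conditions correctly", {
  grid_tbl <- tidyr::expand_grid(
    diameter = c(3, 4, 6, 8, 10, 12),
    postfilter_fwhm = c(2, 3, 4, 6),
    iterations = 4L, recon = "psf", psf_modeled = TRUE)
  rc_of <- function(d, pf) {
    if (pf == 2) c(`3` = .3, `4` = .5, `6` = .9, `8` = 1.3, `10` = 1.2,
                   `12` = 1.1)[[as.character(d)]]
    else if (pf == 3) c(.2, .3, .6, .9, 1.0, 1.05)[match(d, c(3, 4, 6, 8, 10, 12))]
    else c(.1, .2, .4, .6, .7, .8)[match(d, c(3, 4, 6, 8, 10, 12))] * (4 / pf)
  }
  grid_tbl$rc_50bg <- mapply(rc_of, grid_tbl$diameter, grid_tbl$postfilter_fwhm)
  f_mono <- find_minimal_restoring_filter(grid_tbl, iterations = 4)
  f_unity <- find_minimal_restoring_filter(grid_tbl, iterations = 4,
                                           require_unity = TRUE)
  expect_equal(as.numeric(f_mono), 3)
  expect_equal(as.numeric(f_unity), 4)
  expect_lte(f_mono, f_unity)   # nested conditions
  pf <- attr(f_mono, "per_filter")
  expect_equal(pf$restores, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("a small contrast sweep is complete, deterministic and truth-tagged", {
  sc <- shared_compact()
  cfg <- experiment_config(
    phantom = sc$phantom,
    acquisition = acquisition_config(noiseless = TRUE),
    recons = list(recon_params(1, 21, psf_modeled = TRUE,
                               postfilter_fwhm = 2)),
    base_seed = 3)
  tbl <- run_contrast_sweep(cfg, frames = c(1, 8))
  # full factorial coverage: 6 spheres x 2 frames x 1 recon, no duplicates
  expect_equal(nrow(tbl), 12)
  expect_equal(anyDuplicated(tbl[, c("sphere", "frame", "recon")]), 0)
  expect_setequal(unique(tbl$frame), c(1, 8))
  want <- vapply(unique(tbl$frame), function(f)
    true_ratio(sc$phantom, (f - 1) * 10, 10), 0)
  expect_equal(sort(unique(tbl$true_ratio)), sort(want), tolerance = 1e-9)
  expect_s3_class(tbl, "rc_table")

  tbl2 <- run_contrast_sweep(cfg, frames = c(1, 8))
  expect_identical(tbl$rc_50bg, tbl2$rc_50bg)
})

test_that("noiseless replicates have zero dispersion and stable means", {
  sc <- shared_compact()
  cfg <- experiment_config(
    phantom = sc$phantom,
    acquisition = acquisition_config(noiseless = TRUE),
    recons = list(recon_params(1, 21, psf_modeled = TRUE,
                               postfilter_fwhm = 2)))
  rep_tbl <- run_reproducibility(cfg, n_replicates = 2, ratio_target = 8)
  s <- summarise_reproducibility(rep_tbl)
  expect_true(all(s$rc_50bg_sd == 0))
  expect_true(all(s$n == 2))
  expect_equal(nrow(s), 6)
})

test_that("reports and plots are generated from RC tables", {
  tbl <- tidyr::expand_grid(diameter = c(3, 6, 12), frame = 1:2,
                            recon = c("a", "b"), replicate = 1L)
  tbl$true_ratio <- tbl$frame * 2
  tbl$sphere <- paste0(tbl$diameter, "mm")
  tbl$rc_max <- 1; tbl$rc_50bg <- tbl$diameter / 12; tbl$rc_avg <- 0.5
  tbl <- rcpet:::as_rc_table(tbl)
  dir <- withr::local_tempdir()
  paths <- generate_report(list(sweep = tbl), dir)
  expect_true(file.exists(file.path(dir, "sweep.csv")))
  expect_true(file.exists(file.path(dir, "sweep_diagnostics.json")))
  expect_s3_class(autoplot(tbl), "ggplot")
  expect_s3_class(plot_rc_vs_diameter(tbl), "ggplot")
  long <- rc_long(tbl)
  expect_equal(nrow(long), 3 * nrow(tbl))
})
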