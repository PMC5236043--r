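#' Reconstruction parameters
#'
#' Configuration of the (OS)EM reconstruction. With `psf_modeled = TRUE` the
#' system model is `B = P G` — an image-space Gaussian resolution kernel `G`
#' of width `psf_fwhm` applied before projection `P`, and its adjoint after
#' backprojection — which is the generic stand-in for vendor PSF algorithms.
#' Defaults follow the clinical protocols emulated: 21 subsets with PSF,
#' 16 without, matched kernel (`psf_fwhm` equal to the 4.5-mm system
#' response), and a Gaussian post-filter applied once after the final
#' iteration.
#'
#' @param iterations Full iterations (each visiting every subset); `>= 1`.
#' @param subsets Number of interleaved angular subsets; must divide the
#'   geometry's `n_angles`.
#' @param psf_modeled Logical: include the resolution model in the system
#'   matrix.
#' @param psf_fwhm Width of the modelled kernel, mm (ignored when
#'   `psf_modeled = FALSE`).
#' @param postfilter_fwhm Gaussian post-filter FWHM, mm; 0 = none.
#' @param keep_iterations If `TRUE`, keep the (unfiltered) image after every
#'   full iteration.
#' @param track_loglik If `TRUE`, record the Poisson log-likelihood after
#'   every full iteration (costs one extra forward projection each).
#' @param label Optional label carried into RC tables.
#' @return An object of class `recon_params`.
#' @export
recon_params <- function(iterations = 4, subsets = 21, psf_modeled = TRUE,
                         psf_fwhm = 4.5, postfilter_fwhm = 2,
                         keep_iterations = FALSE, track_loglik = FALSE,
                         label = NULL) {
  stopifnot(iterations >= 1, subsets >= 1, psf_fwhm >= 0, postfilter_fwhm >= 0)
  if (is.null(label)) {
    label <- sprintf("%s_%dit%dss_%gmm",
                     if (psf_modeled) "psf" else "nopsf",
                     iterations, subsets, postfilter_fwhm)
  }
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets),
                 psf_modeled = isTRUE(psf_modeled),
                 psf_fwhm = psf_fwhm, postfilter_fwhm = postfilter_fwhm,
                 keep_iterations = isTRUE(keep_iterations),
                 track_loglik = isTRUE(track_loglik), label = label),
            class = "recon_params")
}

#' @export
print.recon_params <- function(x, ...) {
  cat(sprintf(
    "<recon_params> %d it x %d subsets, PSF %s, post-filter %g mm [%s]\n",
    x$iterations, x$subsets,
    if (x$psf_modeled) sprintf("on (%g mm)", x$psf_fwhm) else "off",
    x$postfilter_fwhm, x$label))
  invisible(x)
}

# image-space kernel of the system model (identity when not modeled)
model_blur <- function(geom, params) {
  if (params$psf_modeled && params$psf_fwhm > 0)
    gaussian_blur_operator(geom$grid, params$psf_fwhm)
  else identity
}

#' EM sensitivity image
#'
#' The normalization term of the EM update for one angular subset:
#' `G' P' 1` over the subset's bins (`P' 1` without PSF modelling). Strictly
#' positive over the reconstructible field of view; subset sensitivities sum
#' to the full sensitivity.
#'
#' @param geom A [projector_geometry()].
#' @param params A [recon_params()].
#' @param subset Subset index in `1:params$subsets`, or `NULL` for the full
#'   sensitivity.
#' @return 3D array on the geometry's grid.
#' @export
sensitivity_image <- function(geom, params, subset = NULL) {
  rows <- if (is.null(subset)) seq_len(nrow(geom$A)) else
    subset_rows(geom, subset, params$subsets)
  ones <- matrix(0, nrow(geom$A), 1)
  ones[rows, 1] <- 1
  plane <- as.numeric(geom$At %*% ones)
  d <- geom$grid$dims
  sens <- array(rep(plane, d[3]), d)
  model_blur(geom, params)(sens)
}

#' One EM multiplicative update
#'
#' `x <- x / s * G' P'( y / (P G x) )` restricted to one subset's bins,
#' with `s` the subset sensitivity. Non-negativity and zeros of `x` are
#' preserved; with a single subset the Poisson log-likelihood never
#' decreases. Ratio denominators are guarded by an epsilon of
#' `1e-12 * max(expectation)`.
#'
#' @param x 3D array, current image estimate (non-negative).
#' @param y Sinogram count matrix (bins x slices).
#' @param geom A [projector_geometry()].
#' @param params A [recon_params()].
#' @param subset Subset index.
#' @param sens Precomputed [sensitivity_image()] for this subset (computed
#'   if `NULL`).
#' @param blur Precomputed model blur closure (internal fast path).
#' @return Updated 3D array.
#' @export
em_update <- function(x, y, geom, params, subset = 1, sens = NULL,
                      blur = NULL) {
  d <- geom$grid$dims
  if (is.null(blur)) blur <- model_blur(geom, params)
  if (is.null(sens)) sens <- sensitivity_image(geom, params, subset)
  rows <- subset_rows(geom, subset, params$subsets)
  xb <- blur(x)
  lambda <- as.matrix(geom$A[rows, , drop = FALSE] %*%
                        matrix(xb, d[1] * d[2], d[3]))
  eps <- 1e-12 * max(lambda, 0)
  ratio <- y[rows, , drop = FALSE] / (lambda + eps)
  corr <- array(as.matrix(Matrix::t(geom$A[rows, , drop = FALSE]) %*% ratio), d)
  corr <- blur(corr)
  ok <- sens > 1e-10 * max(sens)
  out <- array(0, d)
  out[ok] <- x[ok] * corr[ok] / sens[ok]
  out
}

# deterministic spread-out subset visiting order (bit-reversal style):
# orders 0..n-1 by a fixed coprime stride near n/golden-ratio
subset_order <- function(n) {
  if (n == 1) return(1L)
  g <- round(n * 0.6180339887)
  while (g > 1 && gcd2(g, n) != 1) g <- g - 1L
  if (g < 1) g <- 1L
  as.integer(((seq_len(n) - 1) * g) %% n + 1)
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' OSEM reconstruction
#'
#' Runs `iterations x subsets` multiplicative EM updates in a fixed,
#' angularly spread-out subset order from a uniform positive initial image
#' scaled to the measured counts, then applies the Gaussian post-filter once
#' after the final iteration. Deterministic given its inputs.
#'
#' @param frames A [sinogram_frame()] (one frame).
#' @param params A [recon_params()].
#' @param initial Optional 3D array initial estimate; default uniform.
#' @return An object of class `recon_result`: the post-filtered
#'   [activity_image()], optional per-iteration unfiltered snapshots, and the
#'   log-likelihood trace if tracked.
#' @export
reconstruct <- function(frames, params, initial = NULL) {
  stopifnot(inherits(frames, "sinogram_frame"), inherits(params, "recon_params"))
  geom <- frames$geom
  if (geom$n_angles %% params$subsets != 0) {
    stop("`subsets` must divide the number of projection angles", call. = FALSE)
  }
  y <- frames$counts
  if (any(y < 0)) stop("projection data must be non-negative", call. = FALSE)
  d <- geom$grid$dims
  blur <- model_blur(geom, params)

  S <- params$subsets
  rows_s <- lapply(seq_len(S), function(s) subset_rows(geom, s, S))
  A_s <- lapply(rows_s, function(r) geom$A[r, , drop = FALSE])
  At_s <- lapply(A_s, Matrix::t)
  y_s <- lapply(rows_s, function(r) y[r, , drop = FALSE])
  # subset sensitivities: backproject subset ones, then adjoint kernel
  plane_ones <- lapply(seq_len(S), function(s) {
    ones <- rep(1, length(rows_s[[s]]))
    as.numeric(At_s[[s]] %*% ones)
  })
  sens_s <- lapply(plane_ones, function(p) blur(array(rep(p, d[3]), d)))
  sens_full <- Reduce(`+`, sens_s)
  ok_s <- lapply(sens_s, function(s) s > 1e-10 * max(sens_full))

  x <- if (is.null(initial)) {
    array(sum(y) / sum(sens_full), d)
  } else {
    stopifnot(identical(dim(initial), as.integer(d)), all(initial >= 0))
    initial
  }

  order_s <- subset_order(S)
  snapshots <- if (params$keep_iterations) vector("list", params$iterations)
  ll <- if (params$track_loglik) numeric(params$iterations)
  for (it in seq_len(params$iterations)) {
    for (s in order_s) {
      xb <- blur(x)
      lambda <- as.matrix(A_s[[s]] %*% matrix(xb, d[1] * d[2], d[3]))
      eps <- 1e-12 * max(lambda, 0)
      ratio <- y_s[[s]] / (lambda + eps)
      corr <- blur(array(as.matrix(At_s[[s]] %*% ratio), d))
      xn <- array(0, d)
      ok <- ok_s[[s]]
      xn[ok] <- x[ok] * corr[ok] / sens_s[[s]][ok]
      x <- xn
    }
    if (params$keep_iterations) snapshots[[it]] <- x
    if (params$track_loglik) ll[it] <- loglik(x, frames, geom, params)
  }

  final <- activity_image(geom$grid, pmax(x, 0),
                          frames$frame_start, frames$frame_duration)
  final <- gaussian_postfilter(final, params$postfilter_fwhm)
  structure(list(image = final, snapshots = snapshots, loglik = ll,
                 params = params, geom = geom,
                 frame_start = frames$frame_start,
                 frame_duration = frames$frame_duration,
                 total_counts = sum(y)),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> %s, frame [%g, %g] min, %.4g counts\n",
              x$params$label, x$frame_start,
              x$frame_start + x$frame_duration, x$total_counts))
  invisible(x)
}

#' Poisson log-likelihood of an image given projection data
#'
#' `sum(y * log(Bx) - Bx)` over all bins, with `0 log 0 := 0` and `B` the
#' (PSF-modelled) system matrix. With one subset the EM iteration never
#' decreases this quantity.
#'
#' @param x 3D array image estimate (non-negative).
#' @param data A [sinogram_frame()] or bare count matrix.
#' @param geom A [projector_geometry()].
#' @param params A [recon_params()].
#' @return Scalar log-likelihood (up to the data-only constant).
#' @export
loglik <- function(x, data, geom, params) {
  y <- if (inherits(data, "sinogram_frame")) data$counts else data
  d <- geom$grid$dims
  xb <- model_blur(geom, params)(x)
  lambda <- as.matrix(geom$A %*% matrix(xb, d[1] * d[2], d[3]))
  pos <- y > 0
  sum(y[pos] * log(lambda[pos])) - sum(lambda)
}

#' Extract a post-filtered image at a given iteration
#'
#' Convenience for iteration sweeps: takes the unfiltered snapshot stored by
#' `reconstruct(keep_iterations = TRUE)` and applies a post-filter, so a
#' single reconstruction yields every (iteration, post-filter) cell.
#'
#' @param result A `recon_result` with snapshots.
#' @param iteration Full-iteration index.
#' @param postfilter_fwhm Gaussian post-filter FWHM in mm.
#' @return An [activity_image()].
#' @export
iteration_image <- function(result, iteration,
                            postfilter_fwhm = result$params$postfilter_fwhm) {
  stopifnot(inherits(result, "recon_result"))
  if (is.null(result$snapshots)) {
    stop("reconstruction was run without `keep_iterations = TRUE`",
         call. = FALSE)
  }
  img <- activity_image(result$geom$grid, result$snapshots[[iteration]],
                        result$frame_start, result$frame_duration)
  gaussian_postfilter(img, postfilter_fwhm)
}
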