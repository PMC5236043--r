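#' Radioactive isotopes and decay
#'
#' An isotope is a label plus a physical half-life in minutes. The two
#' isotopes of the dual-isotope phantom are provided as constructors:
#' the spheres and reference region are filled with fluorine-18
#' (T1/2 = 109.77 min) and the background with carbon-11
#' (T1/2 = 20.36 min), so the true sphere-to-background contrast grows
#' over time purely by differential decay.
#'
#' @param name Character label.
#' @param half_life Half-life in minutes; must be positive.
#' @return An object of class `isotope`.
#' @examples
#' isotope_f18()
#' decayed_concentration(100, isotope_c11(), 20.36)
#' @export
isotope <- function(name, half_life) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life) || length(half_life) != 1L || !is.finite(half_life) ||
      half_life <= 0) {
    stop("`half_life` must be a single positive number (minutes)", call. = FALSE)
  }
  structure(list(name = name, half_life = as.numeric(half_life)),
            class = "isotope")
}

#' @rdname isotope
#' @export
isotope_f18 <- function() isotope("F-18", 109.77)

#' @rdname isotope
#' @export
isotope_c11 <- function() isotope("C-11", 20.36)

#' @export
print.isotope <- function(x, ...) {
  cat(sprintf("<isotope> %s, half-life %.2f min\n", x$name, x$half_life))
  invisible(x)
}

#' Instantaneous decayed concentration
#'
#' Exponential decay law: `c0 * 2^(-t / half_life)`.
#'
#' @param c0 Concentration at time zero (Bq/mL); non-negative.
#' @param iso An [isotope()].
#' @param t Time in minutes since time zero; non-negative.
#' @return Concentration in Bq/mL at time `t`.
#' @export
decayed_concentration <- function(c0, iso, t) {
  stopifnot(inherits(iso, "isotope"))
  if (any(c0 < 0)) stop("`c0` must be non-negative", call. = FALSE)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  c0 * 2^(-t / iso$half_life)
}

#' Frame-averaged decayed concentration
#'
#' Time-average of [decayed_concentration()] over the acquisition frame
#' `[t0, t0 + dt]`, in closed form:
#' `c0 * 2^(-t0/T) * (1 - 2^(-dt/T)) * T / (dt * ln 2)` with `T` the
#' half-life. This is the concentration an ideal detector integrating the
#' whole frame would report.
#'
#' @inheritParams decayed_concentration
#' @param t0 Frame start (minutes).
#' @param dt Frame duration (minutes); must be positive.
#' @return Mean concentration in Bq/mL over the frame.
#' @export
frame_mean_concentration <- function(c0, iso, t0, dt) {
  stopifnot(inherits(iso, "isotope"))
  if (any(c0 < 0)) stop("`c0` must be non-negative", call. = FALSE)
  if (any(t0 < 0)) stop("`t0` must be non-negative", call. = FALSE)
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  Th <- iso$half_life
  c0 * 2^(-t0 / Th) * (1 - 2^(-dt / Th)) * Th / (dt * log(2))
}
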