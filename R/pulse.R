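#' Shaped pulses as piecewise-constant control sequences
#'
#' A shaped pulse is a sequence of `N` short rectangular pulses of equal
#' duration `dt` with piecewise-constant Cartesian control amplitudes
#' `ux[k]`, `uy[k]` in Hz (rf nutation frequencies).  The polar view
#' (amplitude/phase, the form stored in spectrometer shape files) and
#' the Cartesian view used by the optimizer are interchangeable via
#' [polar_to_cartesian()] and [cartesian_to_polar()].
#'
#' @param ux,uy numeric vectors of equal length: x/y control amplitudes (Hz).
#' @param dt timestep duration in seconds.
#' @param label free-text label carried through file output.
#' @return An object of class `"shaped_pulse"`: a list with elements
#'   `ux`, `uy`, `dt`, `label`.
#' @seealso [random_pulse()], [clip_amplitude()], [gaussian_cascade()]
#' @examples
#' p <- shaped_pulse(ux = c(15000, 0), uy = c(0, 15000), dt = 5e-7)
#' pulse_amplitude(p)
#' pulse_duration(p)
#' @export
shaped_pulse <- function(ux, uy, dt, label = "shaped pulse") {
  if (length(ux) != length(uy)) stop("ux and uy must have equal length")
  if (length(ux) < 1L) stop("a pulse needs at least one step")
  if (!all(is.finite(ux), is.finite(uy))) stop("non-finite control amplitudes")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive duration in seconds")
  structure(list(ux = as.numeric(ux), uy = as.numeric(uy), dt = dt,
                 label = as.character(label)[1]),
            class = "shaped_pulse")
}

#' @rdname shaped_pulse
#' @param pulse a `shaped_pulse`.
#' @export
pulse_duration <- function(pulse) length(pulse$ux) * pulse$dt

#' @rdname shaped_pulse
#' @export
pulse_amplitude <- function(pulse) sqrt(pulse$ux^2 + pulse$uy^2)

#' @rdname shaped_pulse
#' @export
pulse_phase <- function(pulse) {
  amp <- pulse_amplitude(pulse)
  ph <- ifelse(amp == 0, 0, atan2(pulse$uy, pulse$ux) * 180 / pi)
  ph %% 360
}

#' @export
length.shaped_pulse <- function(x) length(x$ux)

#' @export
print.shaped_pulse <- function(x, ...) {
  cat("<shaped pulse>", x$label, "\n")
  cat(sprintf("  %d steps of %.3g us  (duration %.4g us)\n",
              length(x$ux), x$dt * 1e6, pulse_duration(x) * 1e6))
  cat(sprintf("  peak rf-amplitude %.4g kHz\n", max(pulse_amplitude(x)) / 1000))
  invisible(x)
}

#' @export
as.data.frame.shaped_pulse <- function(x, ...) {
  data.frame(step = seq_along(x$ux),
             t_us = (seq_along(x$ux) - 0.5) * x$dt * 1e6,
             ux = x$ux, uy = x$uy,
             amplitude = pulse_amplitude(x), phase = pulse_phase(x))
}

#' @export
plot.shaped_pulse <- function(x, ...) {
  d <- as.data.frame(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$t_us, d$amplitude / 1000, type = "s", xlab = "t [us]",
                 ylab = "amplitude [kHz]", main = x$label, ...)
  graphics::plot(d$t_us, d$phase, type = "s", xlab = "t [us]",
                 ylab = "phase [deg]", ylim = c(0, 360), ...)
  invisible(x)
}

#' Polar/Cartesian control conversion
#'
#' Converts between the amplitude/phase representation of spectrometer
#' shape files and the Cartesian controls used internally:
#' `ux = amplitude*cos(phase)`, `uy = amplitude*sin(phase)` with phases
#' in degrees.  Steps of zero amplitude carry phase 0 by convention.
#'
#' @param amplitude rf amplitudes in Hz (`>= 0`).
#' @param phase phases in degrees.
#' @return `polar_to_cartesian()`: a list with vectors `ux`, `uy`;
#'   `cartesian_to_polar()`: a list with vectors `amplitude`, `phase`.
#' @examples
#' polar_to_cartesian(15000, 90)   # ux = 0, uy = 15000
#' @export
polar_to_cartesian <- function(amplitude, phase) {
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  ph <- phase * pi / 180
  list(ux = amplitude * cos(ph), uy = amplitude * sin(ph))
}

#' @rdname polar_to_cartesian
#' @param ux,uy Cartesian controls in Hz.
#' @export
cartesian_to_polar <- function(ux, uy) {
  amp <- sqrt(ux^2 + uy^2)
  ph <- ifelse(amp == 0, 0, atan2(uy, ux) * 180 / pi) %% 360
  list(amplitude = amp, phase = ph)
}

#' Project a pulse onto the rf-amplitude constraint
#'
#' Radially rescales every step whose amplitude exceeds `u_max` down to
#' `u_max`, preserving its phase; steps within the limit are untouched.
#' This is the projection used after each gradient update so that every
#' iterate respects the hardware amplitude limit (15 kHz for the
#' flagship designs).  The operation is idempotent.
#'
#' @param pulse a [shaped_pulse].
#' @param u_max maximum rf amplitude in Hz (`> 0`).
#' @return The clipped `shaped_pulse`.
#' @export
clip_amplitude <- function(pulse, u_max) {
  stopifnot(inherits(pulse, "shaped_pulse"), u_max > 0)
  amp <- pulse_amplitude(pulse)
  # the 1e-12 relative guard makes the projection exactly idempotent:
  # a rescaled step re-enters at most 1 ulp above u_max and is left alone
  fac <- ifelse(amp > u_max * (1 + 1e-12), u_max / amp, 1)
  pulse$ux <- pulse$ux * fac
  pulse$uy <- pulse$uy * fac
  pulse
}

# evaluate f() under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards
with_seed <- function(seed, f) {
  if (is.null(seed)) return(f())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' Random starting pulse
#'
#' Draws a random shaped pulse: per-step amplitudes uniform on
#' `[0, u_max]` and phases uniform on `[0, 360)` degrees.  GRAPE-type
#' optimizations converge only to local optima, so campaigns start from
#' many such random shapes and keep the best result; the flagship
#' designs use 0.5 us steps and a 15 kHz amplitude cap.
#'
#' @param n number of steps.
#' @param dt timestep in seconds (default 0.5 us).
#' @param u_max maximum rf amplitude in Hz (default 15 kHz).
#' @param seed optional integer seed for reproducible draws; the global
#'   RNG state is left untouched.
#' @return A [shaped_pulse].
#' @examples
#' p <- random_pulse(667, seed = 1)
#' max(pulse_amplitude(p)) <= 15000
#' @export
random_pulse <- function(n, dt = 5e-7, u_max = 15000, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, function() {
    amp <- stats::runif(n, 0, u_max)
    ph <- stats::runif(n, 0, 360)
    uv <- polar_to_cartesian(amp, ph)
    shaped_pulse(uv$ux, uv$uy, dt,
                 label = sprintf("random start (n=%d%s)", n,
                                 if (is.null(seed)) "" else paste0(", seed=", seed)))
  })
}
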