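# Gaussian pulse-cascade coefficients (relative amplitude, center and
# FWHM as fractions of the pulse length), taken from the Emsley &
# Bodenhausen cascade literature.  Negative amplitudes are realized as a
# 180-degree phase jump, so cascade phases take exactly two values.
.cascade_table <- list(
  Q3 = data.frame(a = c(-4.39, 4.57, 2.60),
                  x = c(0.306, 0.545, 0.804),
                  w = c(0.180, 0.183, 0.245)),
  Q5 = data.frame(a = c(-1.48, -4.34, 7.33, -2.30, 5.66),
                  x = c(0.162, 0.307, 0.497, 0.525, 0.803),
                  w = c(0.186, 0.139, 0.143, 0.290, 0.137)),
  G4 = data.frame(a = c(0.62, 0.72, 0.91, -0.33),
                  x = c(0.177, 0.492, 0.653, 0.892),
                  w = c(0.172, 0.129, 0.119, 0.139))
)

# peak rf-amplitudes (kHz) the standard cascades need to cover the same
# 24 kHz aliphatic selective band that SURBOP pulses cover at 15 kHz
.cascade_peak_khz <- c(Q3 = 26.0, Q5 = 26.0, G4 = 22.7)

#' Gaussian pulse-cascade comparison shapes (Q3, Q5, G4)
#'
#' Samples one of the classical band-selective Gaussian pulse cascades:
#' Q3 (universal 180 rotation), Q5 (universal 90 rotation) or G4
#' (point-to-point excitation).  These are the literature baselines the
#' optimized band-selective UR pulses are compared against; they are
#' provided for qualitative comparison plots and profiling, not as
#' design outputs.  Each cascade is a sum of Gaussians with fixed
#' relative amplitudes, centers and widths; negative lobes appear as
#' 180-degree phase jumps.
#'
#' @param name one of `"Q3"`, `"Q5"`, `"G4"`.
#' @param duration pulse length in seconds.
#' @param n_steps number of sampling steps.
#' @param peak_amplitude peak rf amplitude in Hz the shape is scaled to.
#'   The default is the published amplitude each cascade needs to cover
#'   the 24 kHz aliphatic band (26.0 kHz for Q3/Q5, 22.7 kHz for G4) --
#'   roughly `sqrt(3)` times the 15 kHz of the optimized pulses.
#' @return A [shaped_pulse].
#' @examples
#' q3 <- gaussian_cascade("Q3", duration = 333.5e-6, n_steps = 667)
#' range(pulse_phase(q3))   # phases only 0 and 180
#' @export
gaussian_cascade <- function(name = c("Q3", "Q5", "G4"), duration, n_steps,
                             peak_amplitude = NULL) {
  name <- match.arg(name)
  stopifnot(duration > 0, n_steps >= 2)
  if (is.null(peak_amplitude)) peak_amplitude <- .cascade_peak_khz[[name]] * 1000
  tab <- .cascade_table[[name]]
  tau <- (seq_len(n_steps) - 0.5) / n_steps
  env <- rowSums(vapply(seq_len(nrow(tab)), function(i)
    tab$a[i] * exp(-4 * log(2) * ((tau - tab$x[i]) / tab$w[i])^2),
    numeric(length(tau))))
  env <- env / max(abs(env)) * peak_amplitude
  shaped_pulse(ux = env, uy = rep(0, n_steps), dt = duration / n_steps,
               label = sprintf("%s cascade (%.4g us)", name, duration * 1e6))
}

#' @rdname gaussian_cascade
#' @export
cascade_peak_amplitude <- function(name = c("Q3", "Q5", "G4")) {
  name <- match.arg(name)
  .cascade_peak_khz[[name]] * 1000
}
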