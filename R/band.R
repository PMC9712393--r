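#' Convert a chemical-shift bandwidth in ppm to Hz
#'
#' A bandwidth of `x` ppm at a Larmor frequency of `f` MHz spans
#' `x * f` Hz.  The flagship band: 80 ppm of aliphatic 13C at a 300 MHz
#' carbon Larmor frequency (a 1.2 GHz proton spectrometer) is 24,000 Hz,
#' i.e. a passband half-width of 12,000 Hz.
#'
#' @param ppm bandwidth in ppm.
#' @param larmor_mhz Larmor frequency of the nucleus in MHz.
#' @return Bandwidth in Hz.
#' @examples
#' ppm_to_hz(80, 300) / 2   # nu_p = 12000 Hz
#' @export
ppm_to_hz <- function(ppm, larmor_mhz) ppm * larmor_mhz

#' Band specification for band-selective pulse optimization
#'
#' Defines the offset landscape of a band-selective universal-rotation
#' optimization: a central passband `[-nu_p, nu_p]` where the pulse must
#' act as the target rotation, unconstrained transition regions, and two
#' symmetric stopbands `[-outer, -nu_s]` and `[nu_s, outer]` where no
#' net transverse-plane rotation is allowed (pure z-rotations, e.g.
#' Bloch-Siegert-type phase shifts, are free).  Rf-field inhomogeneity
#' is represented by an ensemble of multiplicative B1 scales applied to
#' the control amplitudes.
#'
#' The defaults are the flagship aliphatic-13C design at 1.2 GHz:
#' `nu_p` = 12 kHz (80 ppm at 300 MHz carbon Larmor frequency), a 6 kHz
#' transition (`nu_s` = 18 kHz), stopbands out to 60 kHz (140 ppm each),
#' 31 equally spaced passband offsets, 31 offsets per stopband (62
#' total), and B1 scales {0.95, 0.975, 1, 1.025, 1.05}.
#'
#' @param nu_p passband half-width in Hz.
#' @param nu_s inner stopband edge in Hz (`> nu_p`).
#' @param outer outer stopband edge in Hz (`> nu_s`).
#' @param n_pass number of equally spaced passband offsets.
#' @param n_stop number of equally spaced offsets per stopband.
#' @param b1_scales dimensionless rf-amplitude scales of the ensemble.
#' @return An object of class `"band_spec"` with elements `nu_p`,
#'   `nu_s`, `outer`, `passband_offsets`, `stopband_offsets`,
#'   `b1_scales`.
#' @examples
#' b <- band_spec()
#' length(b$passband_offsets)   # 31
#' length(b$stopband_offsets)   # 62
#' @export
band_spec <- function(nu_p = 12000, nu_s = 18000, outer = 60000,
                      n_pass = 31, n_stop = 31,
                      b1_scales = c(0.95, 0.975, 1, 1.025, 1.05)) {
  if (!(0 < nu_p && nu_p < nu_s && nu_s < outer))
    stop("band edges must satisfy 0 < nu_p < nu_s < outer")
  if (n_pass < 1 || n_stop < 1) stop("need at least one offset per region")
  if (any(b1_scales <= 0)) stop("b1_scales must be positive")
  pass <- if (n_pass == 1) 0 else seq(-nu_p, nu_p, length.out = n_pass)
  stop_right <- seq(nu_s, outer, length.out = n_stop)
  structure(list(nu_p = nu_p, nu_s = nu_s, outer = outer,
                 passband_offsets = pass,
                 stopband_offsets = c(-rev(stop_right), stop_right),
                 b1_scales = as.numeric(b1_scales)),
            class = "band_spec")
}

#' @rdname band_spec
#' @param larmor_mhz Larmor frequency in MHz used to convert ppm widths.
#' @param pass_ppm,transition_ppm,stop_ppm passband width, transition
#'   width and per-stopband width in ppm.
#' @param ... further arguments passed to [band_spec()].
#' @export
band_spec_ppm <- function(pass_ppm = 80, transition_ppm = 20, stop_ppm = 140,
                          larmor_mhz = 300, ...) {
  nu_p <- ppm_to_hz(pass_ppm, larmor_mhz) / 2
  nu_s <- nu_p + ppm_to_hz(transition_ppm, larmor_mhz)
  band_spec(nu_p = nu_p, nu_s = nu_s,
            outer = nu_s + ppm_to_hz(stop_ppm, larmor_mhz), ...)
}

#' @export
print.band_spec <- function(x, ...) {
  cat("<band spec>\n")
  cat(sprintf("  passband: +/- %.4g kHz (%d offsets)\n",
              x$nu_p / 1000, length(x$passband_offsets)))
  cat(sprintf("  stopbands: +/- [%.4g, %.4g] kHz (%d offsets)\n",
              x$nu_s / 1000, x$outer / 1000, length(x$stopband_offsets)))
  cat("  B1 scales:", paste(x$b1_scales, collapse = ", "), "\n")
  invisible(x)
}

# flatten a band spec into parallel vectors over all (offset, B1) pairs:
# offsets, b1 scale, and region flag (0 = passband, 1 = stopband)
band_ensemble <- function(band) {
  offs <- c(band$passband_offsets, band$stopband_offsets)
  reg <- rep(c(0L, 1L),
             c(length(band$passband_offsets), length(band$stopband_offsets)))
  list(off = rep(offs, times = length(band$b1_scales)),
       b1 = rep(band$b1_scales, each = length(offs)),
       region = rep(reg, times = length(band$b1_scales)),
       n_pass = length(band$passband_offsets),
       n_stop = length(band$stopband_offsets),
       n_b1 = length(band$b1_scales))
}
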