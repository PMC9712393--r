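#' Read and write spectrometer shape files
#'
#' Shaped pulses are interchanged as amplitude/phase tables: per step a
#' relative amplitude in percent of the calibration peak (0--100) and a
#' phase in degrees.  Two dialects are supported:
#' \describe{
#'   \item{`"jcamp"`}{the JCAMP-DX-style Bruker shape dialect:
#'     `##`-prefixed header records, an `##NPOINTS=` count, and
#'     `##XYPOINTS= (XY..XY)` followed by one `amplitude, phase` pair
#'     per line, terminated by `##END=`.}
#'   \item{`"text"`}{plain two-column whitespace-separated text
#'     (amplitude percent, phase degrees); lines starting with `#` are
#'     ignored.}
#' }
#' Reading requires the calibration `peak_amplitude` in Hz (what 100%
#' corresponds to) and the pulse timing (`dt` or total `duration`),
#' which plain shape files do not carry.
#'
#' @param path file path.
#' @param peak_amplitude rf amplitude in Hz that 100% maps to.
#' @param dt timestep in seconds (alternatively give `duration`).
#' @param duration total pulse length in seconds.
#' @return `read_shape()`: a [shaped_pulse]. `write_shape()`: `path`,
#'   invisibly.
#' @examples
#' p <- random_pulse(16, seed = 2)
#' f <- tempfile(fileext = ".shp")
#' write_shape(p, f, peak_amplitude = 15000)
#' q <- read_shape(f, peak_amplitude = 15000, dt = p$dt)
#' max(abs(q$ux - p$ux))
#' @export
read_shape <- function(path, peak_amplitude, dt = NULL, duration = NULL) {
  if (!file.exists(path)) stop("no such shape file: ", path)
  stopifnot(peak_amplitude > 0)
  lines <- readLines(path, warn = FALSE)
  jcamp <- any(grepl("^##", lines))
  if (jcamp) {
    rec <- parse_jcamp_points(lines, path)
  } else {
    rec <- parse_text_points(lines, path)
  }
  bad <- which(rec$amplitude < 0 | rec$amplitude > 100)
  if (length(bad))
    stop(sprintf("%s: amplitude out of [0, 100]%% at data line %d (%.6g)",
                 path, bad[1], rec$amplitude[bad[1]]))
  n <- length(rec$amplitude)
  if (is.null(dt)) {
    if (is.null(duration)) stop("supply dt or duration to time the shape")
    dt <- duration / n
  }
  uv <- polar_to_cartesian(rec$amplitude / 100 * peak_amplitude, rec$phase)
  shaped_pulse(uv$ux, uv$uy, dt, label = rec$title %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_jcamp_points <- function(lines, path) {
  np_line <- grep("^##NPOINTS=", lines)
  xy_line <- grep("^##XYPOINTS=", lines)
  if (length(xy_line) != 1L)
    stop(path, ": expected exactly one ##XYPOINTS= record")
  end_line <- grep("^##END=", lines)
  end_line <- if (length(end_line)) min(end_line[end_line > xy_line]) else length(lines) + 1L
  body <- lines[seq(xy_line + 1L, end_line - 1L)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  ok <- lengths(parts) == 2L
  if (any(!ok))
    stop(sprintf("%s: malformed XY point at line %d: '%s'", path,
                 xy_line + which(!ok)[1], body[which(!ok)[1]]))
  vals <- vapply(parts, function(p) suppressWarnings(as.numeric(p)), numeric(2))
  if (any(!is.finite(vals)))
    stop(path, ": non-numeric XY point near line ",
         xy_line + which(colSums(!is.finite(vals)) > 0)[1])
  if (length(np_line)) {
    np <- as.integer(sub("^##NPOINTS=\\s*", "", lines[np_line[1]]))
    if (is.finite(np) && np != ncol(vals))
      stop(sprintf("%s: ##NPOINTS= %d but %d XY points found (lines %d-%d)",
                   path, np, ncol(vals), xy_line + 1L, end_line - 1L))
  }
  title_line <- grep("^##TITLE=", lines)
  title <- if (length(title_line))
    trimws(sub("^##TITLE=", "", lines[title_line[1]])) else NULL
  list(amplitude = vals[1, ], phase = vals[2, ], title = title)
}

parse_text_points <- function(lines, path) {
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  body <- lines[keep]
  if (!length(body)) stop(path, ": no data lines found")
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  ok <- lengths(parts) == 2L
  if (any(!ok))
    stop(sprintf("%s: expected two columns at line %d: '%s'", path,
                 which(keep)[which(!ok)[1]], body[which(!ok)[1]]))
  vals <- vapply(parts, function(p) suppressWarnings(as.numeric(p)), numeric(2))
  if (any(!is.finite(vals)))
    stop(path, ": non-numeric value near line ",
         which(keep)[which(colSums(!is.finite(vals)) > 0)[1]])
  list(amplitude = vals[1, ], phase = vals[2, ], title = NULL)
}

#' @rdname read_shape
#' @param pulse a [shaped_pulse] to write.
#' @param format `"jcamp"` (Bruker-style, default) or `"text"`.
#' @param title title record for the JCAMP header.
#' @export
write_shape <- function(pulse, path, peak_amplitude = NULL,
                        format = c("jcamp", "text"), title = pulse$label) {
  stopifnot(inherits(pulse, "shaped_pulse"))
  format <- match.arg(format)
  amp <- pulse_amplitude(pulse)
  if (is.null(peak_amplitude)) peak_amplitude <- max(amp)
  if (peak_amplitude <= 0) stop("peak_amplitude must be positive")
  if (max(amp) > peak_amplitude * (1 + 1e-9))
    stop("pulse amplitudes exceed the calibration peak_amplitude")
  pct <- pmin(100, amp / peak_amplitude * 100)
  ph <- pulse_phase(pulse)
  pts <- sprintf("%.6e, %.6e", pct, ph)
  if (format == "text") {
    writeLines(sub(",", "", pts), path)
    return(invisible(path))
  }
  hdr <- c(
    sprintf("##TITLE= %s", title),
    "##JCAMP-DX= 5.00 $$ Bruker JCAMP library",
    "##DATA TYPE= Shape Data",
    "##ORIGIN= surbop R package",
    sprintf("##MINX= %.6e", min(pct)),
    sprintf("##MAXX= %.6e", max(pct)),
    sprintf("##MINY= %.6e", min(ph)),
    sprintf("##MAXY= %.6e", max(ph)),
    "##$SHAPE_EXMODE= Universal",
    sprintf("##$SHAPE_LENGTH= %.6e", pulse_duration(pulse) * 1e6),
    sprintf("##$SHAPE_AMPLITUDE= %.6e", peak_amplitude),
    sprintf("##NPOINTS= %d", length(pulse)),
    "##XYPOINTS= (XY..XY)")
  writeLines(c(hdr, pts, "##END="), path)
  invisible(path)
}

#' Convert a shape file between dialects
#'
#' @param infile,outfile input and output paths.
#' @param out_format output dialect (`"jcamp"` or `"text"`).
#' @param peak_amplitude calibration amplitude in Hz (defaults to 100%
#'   = 15 kHz; the relative amplitudes are format-invariant, so the
#'   value only needs to be consistent between read and write).
#' @param dt timestep assigned while the shape is in memory (irrelevant
#'   to the written relative amplitudes).
#' @return `outfile`, invisibly.
#' @export
convert_shape <- function(infile, outfile, out_format = c("jcamp", "text"),
                          peak_amplitude = 15000, dt = 5e-7) {
  p <- read_shape(infile, peak_amplitude = peak_amplitude, dt = dt)
  write_shape(p, outfile, peak_amplitude = peak_amplitude,
              format = match.arg(out_format))
}
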