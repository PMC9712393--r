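#' Rotation quaternions for spin-1/2 propagation
#'
#' A shaped pulse acting on a non-interacting spin-1/2 isochromat is a
#' sequence of rotations, each fully described by a unit quaternion
#' `(A, B, C, D)` with `D = cos(theta/2)` and `(A, B, C)` the rotation
#' axis scaled by `sin(theta/2)`.  Quaternions double-cover physical
#' rotations: `q` and `-q` act identically on magnetization.
#'
#' The rotation convention used throughout the package is right-handed
#' and active: a 90 degree rotation about +x maps +z magnetization to
#' -y.  Offsets and control amplitudes are in Hz; the angle of a step of
#' duration `dt` seconds is `2*pi*dt*sqrt(ux^2 + uy^2 + off^2)` radians.
#'
#' `quat()` builds a quaternion from its four components and checks unit
#' norm; `quat_identity()` is the null rotation `(0, 0, 0, 1)`.
#'
#' @param A,B,C,D quaternion components (axis * sin(theta/2), cos(theta/2)).
#' @return A numeric vector of length 4 with class `"quat"`.
#' @examples
#' quat_identity()
#' ur_target(90, phase = 0)   # 90 degrees about +x: (1/sqrt(2), 0, 0, 1/sqrt(2))
#' @export
quat <- function(A, B, C, D) {
  q <- c(A, B, C, D)
  if (length(q) != 4L || !all(is.finite(q)))
    stop("a quaternion needs four finite components")
  nrm <- sqrt(sum(q^2))
  if (abs(nrm - 1) > 1e-9)
    stop("quaternion is not unit-norm (|q| = ", format(nrm), ")")
  structure(as.numeric(q), class = "quat")
}

#' @rdname quat
#' @export
quat_identity <- function() structure(c(0, 0, 0, 1), class = "quat")

#' @export
print.quat <- function(x, digits = 6, ...) {
  cat("<rotation quaternion>  (A, B, C, D) =",
      paste(format(unclass(x), digits = digits), collapse = ", "), "\n")
  ang <- 2 * atan2(sqrt(sum(x[1:3]^2)), x[4]) * 180 / pi
  cat("  rotation angle:", format(ang, digits = digits), "deg\n")
  invisible(x)
}

#' Single-step rotation quaternion of a piecewise-constant control
#'
#' Computes the propagator quaternion of one timestep of a shaped pulse:
#' an rf field with Cartesian control amplitudes `ux`, `uy` (Hz) applied
#' for `dt` seconds to a spin at resonance offset `off` (Hz).  The
#' rotation angle is `theta = 2*pi*dt*sqrt(ux^2 + uy^2 + off^2)` about
#' the unit axis `(ux, uy, off)/sqrt(ux^2 + uy^2 + off^2)`; the zero-field
#' step (`theta = 0`) is the identity rotation.
#'
#' All arguments are vectorized (recycled to a common length); with
#' vector input a matrix with one quaternion per row is returned.
#'
#' @param ux,uy x/y control amplitudes in Hz (nutation frequencies).
#' @param off resonance offset in Hz.
#' @param dt timestep duration in seconds (`> 0`).
#' @return A `"quat"` for scalar input, otherwise an `n x 4` matrix with
#'   columns A, B, C, D.
#' @examples
#' # a hard 180x: 2*pi*dt*ux == pi
#' quat_step(ux = 25000, uy = 0, off = 0, dt = 1 / (2 * 25000))
#' @export
quat_step <- function(ux, uy, off, dt) {
  n <- max(length(ux), length(uy), length(off))
  if (!all(is.finite(ux), is.finite(uy), is.finite(off), is.finite(dt)))
    stop("non-finite control amplitude, offset or timestep")
  if (any(dt <= 0)) stop("timestep dt must be positive")
  ux <- rep_len(ux, n); uy <- rep_len(uy, n); off <- rep_len(off, n)
  theta <- 2 * pi * dt * sqrt(ux^2 + uy^2 + off^2)
  # f = sin(theta/2)/theta, series-expanded near theta = 0 so the
  # zero-angle step smoothly becomes the identity
  f <- ifelse(theta < 1e-8, 0.5 - theta^2 / 48, sin(theta / 2) / theta)
  a <- 2 * pi * dt
  out <- cbind(A = a * ux * f, B = a * uy * f, C = a * off * f,
               D = cos(theta / 2))
  if (n == 1L) structure(as.numeric(out), class = "quat") else out
}

#' Quaternion composition and the 4x4 composition matrix
#'
#' `quat_matrix()` returns the 4x4 matrix `R(q2)` such that the
#' cumulative rotation "first q1, then q2" is the matrix-vector product
#' `R(q2) %*% q1` (the Hamilton product `q2 * q1` written as a linear map
#' in its right factor).  `quat_compose(q2, q1)` applies it directly.
#'
#' @param q2,q1 unit quaternions (`"quat"` or plain length-4 numeric).
#' @return `quat_matrix()`: a 4x4 numeric matrix; `quat_compose()`: the
#'   composed unit quaternion.
#' @examples
#' q90 <- ur_target(90)
#' quat_compose(q90, q90)  # two 90x in a row: 180x = (1, 0, 0, 0)
#' @export
quat_matrix <- function(q2) {
  q2 <- as.numeric(q2)
  stopifnot(length(q2) == 4L)
  A <- q2[1]; B <- q2[2]; C <- q2[3]; D <- q2[4]
  matrix(c( D, -C,  B,  A,
            C,  D, -A,  B,
           -B,  A,  D,  C,
           -A, -B, -C,  D), nrow = 4, byrow = TRUE)
}

#' @rdname quat_matrix
#' @export
quat_compose <- function(q2, q1) {
  x <- drop(quat_matrix(q2) %*% as.numeric(q1))
  structure(x, class = "quat")
}

#' Conjugate (inverse rotation) of a unit quaternion
#' @param q a unit quaternion.
#' @return The quaternion of the inverse rotation (axis part negated).
#' @export
quat_conj <- function(q) {
  q <- as.numeric(q)
  structure(c(-q[1:3], q[4]), class = "quat")
}

#' Propagate a shaped pulse on one isochromat
#'
#' Computes the cumulative propagators `X_k = R_k R_{k-1} ... R_1 U_0`
#' of a shaped pulse for a single isochromat, starting from the identity
#' `U_0 = (0, 0, 0, 1)`.  All intermediate propagators are retained;
#' they are the forward states paired with the backpropagated costates
#' when gradients are assembled.
#'
#' B1 inhomogeneity is modeled multiplicatively: `b1_scale` scales the
#' control amplitudes `ux`, `uy` only, never the offset.
#'
#' @param pulse a [shaped_pulse].
#' @param off resonance offset in Hz.
#' @param b1_scale dimensionless rf-amplitude scaling factor (`> 0`).
#' @return An `(N + 1) x 4` matrix; row `k + 1` is `X_k` (row 1 is `U_0`).
#' @examples
#' p <- shaped_pulse(ux = rep(25000, 10), uy = rep(0, 10), dt = 2e-6)
#' tail(quat_propagate(p, off = 0), 1)  # total flip pi: (1,0,0,0)
#' @export
quat_propagate <- function(pulse, off, b1_scale = 1) {
  stopifnot(inherits(pulse, "shaped_pulse"))
  if (b1_scale <= 0) stop("b1_scale must be positive")
  n <- length(pulse$ux)
  if (n == 0L) stop("cannot propagate an empty pulse")
  steps <- quat_step(b1_scale * pulse$ux, b1_scale * pulse$uy, off, pulse$dt)
  if (n == 1L) steps <- matrix(steps, nrow = 1)
  X <- matrix(0, n + 1L, 4L, dimnames = list(NULL, c("A", "B", "C", "D")))
  X[1L, 4L] <- 1
  x <- c(0, 0, 0, 1)
  for (k in seq_len(n)) {
    q <- steps[k, ]
    x <- c(q[4] * x[1] - q[3] * x[2] + q[2] * x[3] + q[1] * x[4],
           q[3] * x[1] + q[4] * x[2] - q[1] * x[3] + q[2] * x[4],
          -q[2] * x[1] + q[1] * x[2] + q[4] * x[3] + q[3] * x[4],
          -q[1] * x[1] - q[2] * x[2] - q[3] * x[3] + q[4] * x[4])
    X[k + 1L, ] <- x
  }
  X
}

#' Rotate a magnetization vector by a quaternion
#'
#' Applies the physical rotation encoded by `q` to a 3-vector via the
#' Euler-Rodrigues map.  The map is quadratic in `q`, so `q` and `-q`
#' give identical results (quaternion double cover), and it preserves
#' the vector norm exactly.
#'
#' @param q a unit quaternion (or an `n x 4` matrix of them).
#' @param M magnetization 3-vector (dimensionless, `|M| <= 1`).
#' @return The rotated 3-vector (or `n x 3` matrix).
#' @examples
#' quat_rotate(ur_target(180), c(0, 0, 1))  # inversion: (0, 0, -1)
#' @export
quat_rotate <- function(q, M) {
  M <- as.numeric(M)
  stopifnot(length(M) == 3L)
  if (sqrt(sum(M^2)) > 1 + 1e-9) stop("|M| must be <= 1")
  qm <- if (is.matrix(q)) q else matrix(as.numeric(q), nrow = 1)
  w <- qm[, 1:3, drop = FALSE]
  d <- qm[, 4]
  # v' = v + 2 d (w x v) + 2 w x (w x v)
  cx <- cbind(w[, 2] * M[3] - w[, 3] * M[2],
              w[, 3] * M[1] - w[, 1] * M[3],
              w[, 1] * M[2] - w[, 2] * M[1])
  cwx <- cbind(w[, 2] * cx[, 3] - w[, 3] * cx[, 2],
               w[, 3] * cx[, 1] - w[, 1] * cx[, 3],
               w[, 1] * cx[, 2] - w[, 2] * cx[, 1])
  out <- matrix(M, nrow(qm), 3L, byrow = TRUE) + 2 * d * cx + 2 * cwx
  colnames(out) <- c("Mx", "My", "Mz")
  if (nrow(out) == 1L) drop(out) else out
}

#' Target quaternion of a universal rotation
#'
#' Builds the target propagator of a universal rotation by `angle`
#' degrees about an axis in the transverse plane at azimuthal `phase`
#' degrees from +x (0 = x, 90 = y).
#'
#' @param angle rotation angle in degrees (90 and 180 are the flagship
#'   targets).
#' @param phase rf phase of the rotation axis in degrees.
#' @return A unit `"quat"`.
#' @examples
#' ur_target(180)            # (1, 0, 0, 0)
#' ur_target(90, phase = 90) # 90 degrees about +y
#' @export
ur_target <- function(angle, phase = 0) {
  th <- angle * pi / 180
  ph <- phase * pi / 180
  quat(sin(th / 2) * cos(ph), sin(th / 2) * sin(ph), 0, cos(th / 2))
}
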