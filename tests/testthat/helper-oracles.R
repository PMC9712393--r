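# Independent oracles for propagation checks.  These never call the
# package's propagators: SU(2) works in 2x2 complex matrices, the Bloch
# oracle integrates the magnetization ODE numerically.

# SU(2) step propagator U = cos(th/2) I - i sin(th/2) n.sigma for a
# piecewise-constant field (ux, uy, off) in Hz over dt seconds
su2_step <- function(ux, uy, off, dt) {
  r <- sqrt(ux^2 + uy^2 + off^2)
  th <- 2 * pi * dt * r
  if (r == 0) return(diag(2) + 0i)
  n <- c(ux, uy, off) / r
  sx <- matrix(c(0, 1, 1, 0), 2)
  sy <- matrix(c(0, 1i, -1i, 0), 2)
  sz <- matrix(c(1, 0, 0, -1), 2)
  cos(th / 2) * diag(2) - 1i * sin(th / 2) * (n[1] * sx + n[2] * sy + n[3] * sz)
}

# Cayley-Klein decomposition U = D I - i (A sx + B sy + C sz)
su2_to_quat <- function(U) {
  c(A = -Im(U[2, 1]), B = Re(U[2, 1]), C = -Im(U[1, 1]), D = Re(U[1, 1]))
}

# full-pulse propagator by left-multiplied 2x2 matrix products
su2_propagate <- function(pulse, off, b1_scale = 1) {
  U <- diag(2) + 0i
  for (k in seq_along(pulse$ux))
    U <- su2_step(b1_scale * pulse$ux[k], b1_scale * pulse$uy[k], off,
                  pulse$dt) %*% U
  su2_to_quat(U)
}

# Bloch equations without relaxation: dM/dt = 2*pi*(ux, uy, off) x M,
# integrated step by step with a stiff high-accuracy solver
bloch_propagate <- function(pulse, off, M0, b1_scale = 1) {
  M <- as.numeric(M0)
  for (k in seq_along(pulse$ux)) {
    om <- 2 * pi * c(b1_scale * pulse$ux[k], b1_scale * pulse$uy[k], off)
    sol <- deSolve::ode(
      y = M, times = c(0, pulse$dt),
      func = function(t, y, p) {
        list(c(p[2] * y[3] - p[3] * y[2],
               p[3] * y[1] - p[1] * y[3],
               p[1] * y[2] - p[2] * y[1]))
      },
      parms = om, rtol = 1e-10, atol = 1e-12)
    M <- as.numeric(sol[2, 2:4])
  }
  M
}

# closed-form free-evolution propagator (zero-amplitude pulse):
# a pure z-rotation by 2*pi*off*T
free_evolution_quat <- function(off, duration) {
  th <- 2 * pi * off * duration
  c(0, 0, sin(th / 2), cos(th / 2))
}

# a hard rectangular x-pulse of given flip angle (degrees)
hard_pulse <- function(flip_deg, n = 10, amplitude = 25000) {
  dt <- (flip_deg / 360) / amplitude / n
  shaped_pulse(rep(amplitude, n), rep(0, n), dt)
}

# small band spec used where full default grids would be wasteful
tiny_band <- function() band_spec(n_pass = 5, n_stop = 4,
                                  b1_scales = c(0.95, 1, 1.05))
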