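test_that("terminal costs match their closed forms", {
  UF <- ur_target(180)
  expect_equal(passband_cost(UF, UF), 0)
  expect_equal(passband_cost(-as.numeric(UF), UF), 4)  # double-cover penalty
  expect_equal(passband_cost(quat_identity(), UF), 2)
  # z-rotations are free in the stopband
  th <- 1.234
  expect_equal(stopband_cost(c(0, 0, sin(th / 2), cos(th / 2))), 0)
  expect_equal(stopband_cost(ur_target(180)), 1)
  expect_equal(stopband_cost(ur_target(90)), 0.5)
})

test_that("terminal costates follow the adjoint seeding rules", {
  UF <- ur_target(180)
  expect_equal(terminal_costate(UF, UF, "passband"), rep(0, 4))
  expect_equal(terminal_costate(c(0, 0, 0.6, 0.8), region = "stopband"),
               rep(0, 4))
  expect_equal(terminal_costate(quat_identity(), UF, "passband", w_sel = 1),
               c(-2, 0, 0, 2))
  expect_equal(terminal_costate(c(0.3, -0.4, 0.5, 0.1), region = "stopband",
                                w_0 = 2),
               c(1.2, -1.6, 0, 0))
})

test_that("backpropagation transports the costate consistently", {
  # identity steps leave the costate unchanged
  id_steps <- matrix(rep(c(0, 0, 0, 1), each = 6), 6)
  P <- backpropagate(c(1, 2, 3, 4), id_steps)
  expect_true(all(P == rep(c(1, 2, 3, 4), each = 6)))
  # single step: P_{N-1} = P_N R_N
  p <- random_pulse(2, seed = 21)
  st <- surbop:::pulse_steps(p, off = 5000)
  P2 <- backpropagate(c(1, 0, 0, 0), st)
  expect_equal(P2[1, ], drop(c(1, 0, 0, 0) %*% quat_matrix(st[2, ])),
               tolerance = 1e-12)
  # pairing invariance: <P_k|X_k> constant when P_N = X_N
  p <- random_pulse(30, seed = 22)
  X <- quat_propagate(p, off = -7000)
  st <- surbop:::pulse_steps(p, off = -7000)
  P <- backpropagate(X[31, ], st)
  pairing <- rowSums(P * X[2:31, ])
  expect_equal(pairing, rep(1, 30), tolerance = 1e-10)
  expect_error(backpropagate(c(1, 0, 0), st), "length")
})

test_that("the total cost matches a free-evolution closed form", {
  band <- band_spec()
  n <- length(band$passband_offsets)
  nb <- length(band$b1_scales)
  pz <- shaped_pulse(rep(0, 50), rep(0, 50), 5e-7)
  UF <- ur_target(180)
  # zero pulse: every isochromat freely precesses; passband term only
  phi <- surbop_cost(pz, band, UF, w_sel = 2, w_0 = 0)
  expected <- 0
  for (off in band$passband_offsets) {
    X <- free_evolution_quat(off, pulse_duration(pz))
    expected <- expected + nb * sum((X - as.numeric(UF))^2)
  }
  expected <- 2 * expected / (2 * n * nb)
  expect_equal(phi, expected, tolerance = 1e-12)
  expect_gte(surbop_cost(random_pulse(20, seed = 1), band, UF), 0)
  expect_error(surbop_cost(pz, band, UF, w_sel = 0, w_0 = 0), "weights")
})

test_that("analytic gradients match central finite differences", {
  band <- band_spec()
  fd_grad <- function(p, UF, w_sel, w_0, h) {
    g <- matrix(0, length(p), 2)
    for (k in seq_along(p$ux)) for (j in 1:2) {
      comp <- c("ux", "uy")[j]
      up <- p; up[[comp]][k] <- up[[comp]][k] + h
      um <- p; um[[comp]][k] <- um[[comp]][k] - h
      g[k, j] <- (surbop_cost(up, band, UF, w_sel, w_0) -
                    surbop_cost(um, band, UF, w_sel, w_0)) / (2 * h)
    }
    g
  }
  set.seed(31)
  for (i in 1:6) {
    n <- sample(5:30, 1)
    p <- random_pulse(n, seed = 300 + i)
    UF <- ur_target(sample(c(90, 180), 1), phase = runif(1, 0, 360))
    w <- runif(2, 0.2, 3)
    g <- surbop_gradient(p, band, UF, w[1], w[2])
    # h = 0.5 Hz keeps FD round-off well below the comparison tolerance;
    # exact step derivatives should agree to ~1e-6 relative
    fd <- fd_grad(p, UF, w[1], w[2], h = 0.5)
    scale <- max(abs(fd))
    expect_lt(max(abs(cbind(g$gx, g$gy) - fd)) / scale, 1e-6)
  }
})

test_that("gradient is zero at an exact minimum and linear in the weights", {
  # single on-resonance passband point, no stopband weight: a hard 180x
  # start is an exact zero of the cost, so the gradient must vanish
  band1 <- band_spec(n_pass = 1, n_stop = 1, b1_scales = 1)
  p180 <- hard_pulse(180, n = 10, amplitude = 15000)
  g <- surbop_gradient(p180, band1, ur_target(180), w_sel = 1, w_0 = 0)
  expect_equal(g$cost, 0, tolerance = 1e-20)
  expect_lt(max(abs(c(g$gx, g$gy))), 1e-10)
  # doubling w_sel with w_0 = 0 doubles the gradient exactly
  p <- random_pulse(15, seed = 41)
  g1 <- surbop_gradient(p, band_spec(), ur_target(90), w_sel = 1, w_0 = 0)
  g2 <- surbop_gradient(p, band_spec(), ur_target(90), w_sel = 2, w_0 = 0)
  expect_equal(g2$gx, 2 * g1$gx, tolerance = 1e-12)
  expect_equal(g2$gy, 2 * g1$gy, tolerance = 1e-12)
  expect_equal(g2$cost, 2 * g1$cost, tolerance = 1e-12)
})

test_that("stopband cost is invariant under phase and time reversal", {
  band <- band_spec()
  p <- random_pulse(25, seed = 51)
  stop_cost <- function(p) surbop_cost(p, band, ur_target(180),
                                       w_sel = 0, w_0 = 1)
  base <- stop_cost(p)
  # phase reversal (uy -> -uy) mirrors offsets; symmetric grids see no change
  expect_equal(stop_cost(shaped_pulse(p$ux, -p$uy, p$dt)), base,
               tolerance = 1e-12)
  # time reversal
  expect_equal(stop_cost(shaped_pulse(rev(p$ux), rev(p$uy), p$dt)), base,
               tolerance = 1e-12)
})
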