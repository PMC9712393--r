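test_that("step quaternions reproduce the hard-pulse closed forms", {
  # 180x: 2*pi*dt*ux = pi
  q180 <- quat_step(ux = 20000, uy = 0, off = 0, dt = 1 / (2 * 20000))
  expect_equal(as.numeric(q180), c(1, 0, 0, 0), tolerance = 1e-12)
  # 90x
  q90 <- quat_step(ux = 20000, uy = 0, off = 0, dt = 1 / (4 * 20000))
  expect_equal(as.numeric(q90), c(1, 0, 0, 1) / sqrt(2), tolerance = 1e-12)
  # free evolution is a pure z-rotation
  off <- 12345
  dt <- 3e-6
  th <- 2 * pi * dt * off
  expect_equal(as.numeric(quat_step(0, 0, off, dt)),
               c(0, 0, sin(th / 2), cos(th / 2)), tolerance = 1e-12)
  # zero field: identity, no 0/0
  expect_equal(as.numeric(quat_step(0, 0, 0, dt)), c(0, 0, 0, 1))
  expect_error(quat_step(Inf, 0, 0, dt), "non-finite")
  expect_error(quat_step(1, 0, 0, -1e-6), "positive")
})

test_that("composition matrix matches direct quaternion arithmetic", {
  expect_equal(quat_matrix(quat_identity()), diag(4))
  # two 90x rotations compose to 180x
  q90 <- ur_target(90)
  expect_equal(as.numeric(quat_compose(q90, q90)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  # norm preservation and agreement with the SU(2) product on random pairs
  set.seed(42)
  for (i in 1:20) {
    v1 <- rnorm(4); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- rnorm(4); v2 <- v2 / sqrt(sum(v2^2))
    x <- quat_compose(v2, v1)
    expect_equal(sum(unclass(x)^2), 1, tolerance = 1e-12)
    U <- function(q) matrix(c(q[4] - 1i * q[3], q[2] - 1i * q[1],
                              -q[2] - 1i * q[1], q[4] + 1i * q[3]), 2)
    expect_equal(as.numeric(x), as.numeric(su2_to_quat(U(v2) %*% U(v1))),
                 tolerance = 1e-12)
  }
})

test_that("pulse propagation agrees with the SU(2) matrix-product oracle", {
  set.seed(1)
  for (i in 1:5) {
    p <- random_pulse(50, seed = 100 + i)
    off <- runif(1, -60000, 60000)
    b1 <- runif(1, 0.8, 1.2)
    X <- quat_propagate(p, off, b1)
    expect_equal(max(abs(rowSums(X^2) - 1)), 0, tolerance = 1e-12)
    expect_equal(as.numeric(X[nrow(X), ]),
                 as.numeric(su2_propagate(p, off, b1)), tolerance = 1e-10)
  }
  # trivial cases
  pz <- shaped_pulse(rep(0, 8), rep(0, 8), 1e-6)
  expect_true(all(quat_propagate(pz, 0) == rep(c(0, 0, 0, 1), each = 9)))
  p180 <- hard_pulse(180, n = 20)
  expect_equal(as.numeric(quat_propagate(p180, 0)[21, ]), c(1, 0, 0, 0),
               tolerance = 1e-10)
  expect_error(quat_propagate(p180, 0, b1_scale = 0), "positive")
})

test_that("the C++ ensemble propagator matches the R single-isochromat path", {
  p <- random_pulse(40, seed = 9)
  offs <- c(-50000, -3000, 0, 8000, 60000)
  b1s <- c(0.8, 0.95, 1, 1.05, 1.2)
  Xc <- surbop:::cpp_propagate_final(p$ux, p$uy, p$dt, offs, b1s)
  for (i in seq_along(offs)) {
    Xr <- quat_propagate(p, offs[i], b1s[i])
    expect_equal(as.numeric(Xc[i, ]), as.numeric(Xr[nrow(Xr), ]),
                 tolerance = 1e-12)
  }
})

test_that("magnetization rotation follows the Bloch equations", {
  skip_if_not_installed("deSolve")
  set.seed(2)
  for (i in 1:3) {
    p <- random_pulse(10, seed = 200 + i)
    off <- runif(1, -30000, 30000)
    X <- quat_propagate(p, off)
    M <- quat_rotate(X[nrow(X), ], c(0, 0, 1))
    expect_equal(as.numeric(M), bloch_propagate(p, off, c(0, 0, 1)),
                 tolerance = 1e-6)
  }
})

test_that("rotation convention and double cover hold", {
  # right-handed active: 90x maps +z -> -y; flip beta: z -> (0,-sin b,cos b)
  for (beta in c(30, 90, 135, 180)) {
    q <- ur_target(beta)
    expect_equal(as.numeric(quat_rotate(q, c(0, 0, 1))),
                 c(0, -sin(beta * pi / 180), cos(beta * pi / 180)),
                 tolerance = 1e-12)
  }
  expect_equal(quat_rotate(quat_identity(), c(0.3, -0.2, 0.5)),
               c(0.3, -0.2, 0.5), ignore_attr = TRUE)
  set.seed(3)
  v <- rnorm(4); v <- v / sqrt(sum(v^2))
  M <- c(0.6, 0, 0.8)
  expect_identical(quat_rotate(v, M), quat_rotate(-v, M))
  expect_equal(sum(quat_rotate(v, M)^2), 1, tolerance = 1e-12)
})
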