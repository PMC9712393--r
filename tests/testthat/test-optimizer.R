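test_that("a single control update moves against the gradient and clips", {
  p <- random_pulse(20, seed = 61)
  g0 <- list(gx = rep(0, 20), gy = rep(0, 20))
  expect_equal(update_controls(p, g0, eps = 1e6)$ux, p$ux)
  g <- surbop_gradient(p, band_spec(), ur_target(180))
  expect_equal(update_controls(p, g, eps = 0)$uy, p$uy)
  up <- update_controls(p, g, eps = 1e8, u_max = 15000)
  expect_lte(max(pulse_amplitude(up)), 15000 * (1 + 1e-12))
  expect_error(update_controls(p, list(gx = 1, gy = 1), 1))
})

test_that("optimization returns immediately from an exact zero-cost start", {
  band1 <- band_spec(n_pass = 1, n_stop = 1, b1_scales = 1)
  p180 <- hard_pulse(180, n = 10, amplitude = 15000)
  fit <- surbop(180, band1, start = p180, w_sel = 1, w_0 = 0)
  expect_true(fit$converged)
  expect_lte(fit$iterations, 1L)          # at most one (vain) line search
  expect_true(all(fit$cost_trace < 1e-30))
  expect_equal(coef(fit)[, "ux"], p180$ux)
})

test_that("line-searched descent is monotone, constrained and deterministic", {
  band <- band_spec()
  ctrl <- surbop_control(max_iter = 40)
  fit <- surbop(90, band, seed = 3, n_steps = 40, control = ctrl)
  expect_true(all(diff(fit$cost_trace) <= 0))
  expect_lte(max(pulse_amplitude(fit$pulse)), 15000 * (1 + 1e-12))
  expect_lt(fit$cost_trace[length(fit$cost_trace)], fit$cost_trace[1])
  expect_length(fit$grad_norm, fit$iterations)
  fit2 <- surbop(90, band, seed = 3, n_steps = 40, control = ctrl)
  expect_identical(fit$cost_trace, fit2$cost_trace)
  expect_identical(coef(fit), coef(fit2))
  # conjugate-gradient option runs and is monotone too
  fitcg <- surbop(90, band, seed = 3, n_steps = 40,
                  control = surbop_control(max_iter = 25, method = "cg"))
  expect_true(all(diff(fitcg$cost_trace) <= 0))
})

test_that("optimizing both targets strongly improves passband UR fidelity", {
  # 100 us reduced-scale designs; the passband quaternion error of the
  # optimized pulse must fall >= 10x below the random-start baseline
  band <- band_spec()
  for (tg in c(90, 180)) {
    start <- random_pulse(200, seed = 11)
    fit <- surbop(tg, band, start = start,
                  control = surbop_control(max_iter = 300))
    r0 <- mean(passband_cost(
      surbop:::cpp_propagate_final(start$ux, start$uy, start$dt,
                                   band$passband_offsets,
                                   rep(1, 31)), ur_target(tg)))
    r1 <- mean(subset(residuals(fit), region == "passband")$cost)
    expect_gt(r0 / r1, 10)
  }
})

test_that("multi-start returns the best of its reproducible runs", {
  band <- band_spec(n_pass = 7, n_stop = 5)
  ctrl <- surbop_control(max_iter = 15)
  one <- surbop(180, band, seed = 5, n_steps = 25, control = ctrl)
  best1 <- surbop_multistart(180, band, n_starts = 1, seeds = 5,
                             n_steps = 25, control = ctrl)
  expect_identical(coef(best1), coef(one))
  best <- surbop_multistart(180, band, n_starts = 4, n_steps = 25,
                            control = ctrl)
  runs <- attr(best, "runs")
  expect_identical(nrow(runs), 4L)
  expect_true(!is.unsorted(runs$final_cost))
  expect_lte(runs$final_cost[1], stats::median(runs$final_cost))
  best_again <- surbop_multistart(180, band, n_starts = 4, n_steps = 25,
                                  control = ctrl)
  expect_identical(attr(best_again, "runs"), runs)
})

test_that("fit methods expose controls, residuals and predictions", {
  fit <- surbop(180, band_spec(n_pass = 5, n_stop = 3), seed = 6,
                n_steps = 30, control = surbop_control(max_iter = 10))
  cf <- coef(fit)
  expect_identical(dim(cf), c(30L, 2L))
  r <- residuals(fit)
  expect_setequal(unique(r$region), c("passband", "stopband"))
  expect_true(all(r$cost >= 0))
  m <- predict(fit, offsets = c(-1000, 0, 1000), b1_scales = 1)
  expect_s3_class(m, "response_map")
  expect_identical(nrow(m), 3L)
  expect_output(print(fit), "universal-rotation")
  expect_output(print(summary(fit)), "ripple")
})
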