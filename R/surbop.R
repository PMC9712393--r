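#' Optimizer settings for [surbop()]
#'
#' @param step_mode `"linesearch"` (backtracking with an Armijo-type
#'   acceptance on the amplitude-clipped candidate; default) or
#'   `"fixed"` (constant step size, the literal printed update rule).
#' @param epsilon0 initial step size in Hz per unit gradient.  The
#'   default `NULL` picks it automatically so the first trial update
#'   moves the largest control by 5% of `u_max`.
#' @param max_iter maximum number of iterations.
#' @param tol relative cost-change threshold; convergence is declared
#'   when the relative decrease stays below `tol` for `patience`
#'   consecutive iterations.
#' @param patience consecutive small-change iterations required.
#' @param u_max rf-amplitude cap in Hz enforced after every update.
#' @param method `"steepest"` (default, the printed algorithm) or
#'   `"cg"` (Polak-Ribiere conjugate gradient with restarts).
#' @param verbose print per-iteration progress every `verbose` iterations
#'   (0 = silent).
#' @return A list of class `"surbop_control"`.
#' @export
surbop_control <- function(step_mode = c("linesearch", "fixed"),
                           epsilon0 = NULL, max_iter = 5000, tol = 1e-8,
                           patience = 10, u_max = 15000,
                           method = c("steepest", "cg"), verbose = 0) {
  step_mode <- match.arg(step_mode)
  method <- match.arg(method)
  if (!is.null(epsilon0) && epsilon0 <= 0) stop("epsilon0 must be positive")
  if (tol <= 0) stop("tol must be positive")
  stopifnot(max_iter >= 1, u_max > 0)
  structure(list(step_mode = step_mode, epsilon0 = epsilon0,
                 max_iter = max_iter, tol = tol, patience = patience,
                 u_max = u_max, method = method, verbose = verbose),
            class = "surbop_control")
}

#' Design a band-selective universal-rotation pulse by quaternion GRAPE
#'
#' Fits the controls of a shaped pulse so that its propagator matches a
#' target rotation (e.g. 90 or 180 degrees about x) across the passband
#' while producing no net transverse rotation in the stopbands, robust
#' over an ensemble of B1 scales.  The algorithm is projected gradient
#' descent on the quaternion cost of [surbop_cost()]: forward
#' propagation of every isochromat, costate backpropagation, analytic
#' averaged gradients, a control update along the descent direction,
#' and radial clipping to the rf-amplitude limit, iterated to
#' convergence.  The update direction is the negative gradient (the
#' quaternion difference cost is minimized); with line search active
#' the cost trace is non-increasing by construction.
#'
#' @param target target rotation: a quaternion from [ur_target()], or a
#'   rotation angle in degrees (about +x).
#' @param band a [band_spec()] describing passband, stopbands and the
#'   B1 ensemble.
#' @param start starting [shaped_pulse]; default a [random_pulse()] of
#'   `n_steps` steps drawn with `seed`.
#' @param w_sel,w_0 passband/stopband cost weights.
#' @param control optimizer settings from [surbop_control()].
#' @param n_steps,dt geometry of the default random start (667 steps of
#'   0.5 us: a 333.5 us pulse).
#' @param seed integer seed for the default random start.
#' @return An object of class `"surbop"`: a list with elements
#'   `pulse` (the optimized [shaped_pulse]), `start`, `target`, `band`,
#'   `weights`, `cost_trace`, `grad_norm`, `converged`, `iterations`,
#'   `seed`, `control`.  Supports `print()`, `summary()`, `coef()`
#'   (the `N x 2` control matrix), `residuals()` (per-isochromat
#'   terminal costs), `predict()` (response maps on new offset/B1
#'   grids) and `plot()`.
#' @examples
#' \donttest{
#' fit <- surbop(180, band_spec(), seed = 1,
#'               control = surbop_control(max_iter = 50))
#' summary(fit)
#' }
#' @export
surbop <- function(target, band = band_spec(), start = NULL,
                   w_sel = 1, w_0 = 1, control = surbop_control(),
                   n_steps = 667, dt = 5e-7, seed = NULL) {
  if (is.numeric(target) && length(target) == 1L) target <- ur_target(target)
  UF <- as.numeric(target)
  stopifnot(inherits(band, "band_spec"), inherits(control, "surbop_control"))
  if (is.null(start))
    start <- random_pulse(n_steps, dt, control$u_max, seed = seed)
  stopifnot(inherits(start, "shaped_pulse"))
  pulse <- clip_amplitude(start, control$u_max)

  g <- surbop_gradient(pulse, band, UF, w_sel, w_0)
  cost <- g$cost
  cost_trace <- numeric(control$max_iter + 1L)
  grad_norm <- numeric(control$max_iter)
  cost_trace[1L] <- cost
  eps <- control$epsilon0
  gmax <- max(abs(c(g$gx, g$gy)))
  if (is.null(eps)) eps <- if (gmax > 0) 0.05 * control$u_max / gmax else 1
  dx <- -g$gx; dy <- -g$gy          # descent direction
  converged <- cost == 0
  small <- 0L
  iter <- 0L

  # candidate after a step of size e along (dx, dy), projected onto the
  # amplitude constraint
  cand_at <- function(e) clip_amplitude(
    shaped_pulse(pulse$ux + e * dx, pulse$uy + e * dy, pulse$dt, pulse$label),
    control$u_max)

  # simple line minimization along the current direction: expand the
  # step while the (projected) cost keeps dropping, otherwise contract
  # until the first decrease; returns NULL when no decrease exists
  line_min <- function(e0) {
    c1 <- surbop_cost(cand_at(e0), band, UF, w_sel, w_0)
    if (c1 < cost) {
      be <- e0; bc <- c1
      for (h in 1:60) {   # bounded: huge steps saturate at the clip sphere
        c2 <- surbop_cost(cand_at(2 * be), band, UF, w_sel, w_0)
        if (is.finite(c2) && c2 < bc) { be <- 2 * be; bc <- c2 } else break
      }
      return(list(eps = be, cost = bc))
    }
    e <- e0
    for (h in 1:50) {
      e <- e / 2
      ch <- surbop_cost(cand_at(e), band, UF, w_sel, w_0)
      if (ch < cost) return(list(eps = e, cost = ch))
    }
    NULL
  }

  while (!converged && iter < control$max_iter) {
    iter <- iter + 1L
    gn2 <- sum(g$gx^2 + g$gy^2)
    grad_norm[iter] <- sqrt(gn2)
    if (gn2 == 0) { converged <- TRUE; iter <- iter - 1L; break }

    if (control$step_mode == "fixed") {
      cand <- cand_at(eps)
      new_cost <- surbop_cost(cand, band, UF, w_sel, w_0)
    } else {
      ls <- line_min(eps)
      if (is.null(ls) && control$method == "cg") {
        # conjugate direction exhausted: restart from steepest descent
        dx <- -g$gx; dy <- -g$gy
        ls <- line_min(eps)
      }
      if (is.null(ls)) {
        # no decrease at any step size: stationary under the projection
        cost_trace[iter + 1L] <- cost
        converged <- TRUE
        break
      }
      eps <- ls$eps
      cand <- cand_at(eps)
      new_cost <- ls$cost
    }

    rel <- if (cost > 0) (cost - new_cost) / cost else 0
    gx_old <- g$gx; gy_old <- g$gy
    pulse <- cand
    cost <- new_cost
    cost_trace[iter + 1L] <- cost
    g <- surbop_gradient(pulse, band, UF, w_sel, w_0)

    if (control$method == "cg") {
      beta <- sum(g$gx * (g$gx - gx_old) + g$gy * (g$gy - gy_old)) /
        sum(gx_old^2 + gy_old^2)
      beta <- max(0, beta)            # Polak-Ribiere+ restart
      dx <- -g$gx + beta * dx
      dy <- -g$gy + beta * dy
      if (sum(dx * g$gx + dy * g$gy) >= 0) { dx <- -g$gx; dy <- -g$gy }
    } else {
      dx <- -g$gx; dy <- -g$gy
    }

    small <- if (abs(rel) < control$tol) small + 1L else 0L
    if (small >= control$patience) converged <- TRUE
    if (control$verbose > 0 && iter %% control$verbose == 0)
      message(sprintf("iter %5d  cost %.6e  |grad| %.3e  eps %.3e",
                      iter, cost, grad_norm[iter], eps))
  }

  structure(list(pulse = pulse, start = start, target = quat(UF[1], UF[2], UF[3], UF[4]),
                 band = band, weights = c(w_sel = w_sel, w_0 = w_0),
                 cost_trace = cost_trace[seq_len(iter + 1L)],
                 grad_norm = grad_norm[seq_len(iter)],
                 converged = converged, iterations = iter, seed = seed,
                 control = control),
            class = "surbop")
}

#' Single control update along the descent direction
#'
#' One explicit GRAPE update: moves the controls against the gradient by
#' step size `eps` and projects the result onto the rf-amplitude
#' constraint.  [surbop()] applies this update with an automatically
#' line-searched `eps`; the standalone form exists for step-by-step
#' experimentation.  (The printed update rule adds `+eps * grad`; since
#' the quaternion difference cost is minimized, the descent direction is
#' the negative gradient.)
#'
#' @param pulse a [shaped_pulse].
#' @param gradient a list with `gx`, `gy` as returned by
#'   [surbop_gradient()].
#' @param eps step size (Hz per unit gradient).
#' @param u_max rf-amplitude cap applied after the move.
#' @return The updated, clipped [shaped_pulse].
#' @export
update_controls <- function(pulse, gradient, eps, u_max = 15000) {
  stopifnot(inherits(pulse, "shaped_pulse"),
            length(gradient$gx) == length(pulse$ux),
            length(gradient$gy) == length(pulse$uy))
  clip_amplitude(shaped_pulse(pulse$ux - eps * gradient$gx,
                              pulse$uy - eps * gradient$gy,
                              pulse$dt, pulse$label),
                 u_max)
}

#' Multi-start optimization
#'
#' GRAPE converges only to local optima, so the published design
#' campaigns run many optimizations from random starting shapes and
#' keep the best.  `surbop_multistart()` runs [surbop()] from
#' `n_starts` seeded random starts and returns the lowest-cost fit,
#' with a ranked summary of all runs attached as attribute `"runs"`.
#'
#' @inheritParams surbop
#' @param n_starts number of random starts.
#' @param seeds integer seeds, one per start (default `seq_len(n_starts)`).
#' @param ... passed on to [surbop()].
#' @return The best `"surbop"` fit; `attr(, "runs")` is a data.frame
#'   with one row per start (seed, final cost, iterations, converged),
#'   ranked by final cost.
#' @export
surbop_multistart <- function(target, band = band_spec(), n_starts = 8,
                              seeds = seq_len(n_starts), ...) {
  stopifnot(n_starts >= 1, length(seeds) == n_starts)
  fits <- lapply(seeds, function(s) surbop(target, band, seed = s, ...))
  final <- vapply(fits, function(f) f$cost_trace[length(f$cost_trace)],
                  numeric(1))
  ord <- order(final)
  runs <- data.frame(seed = seeds[ord], final_cost = final[ord],
                     iterations = vapply(fits, `[[`, 0L, "iterations")[ord],
                     converged = vapply(fits, `[[`, TRUE, "converged")[ord])
  best <- fits[[ord[1L]]]
  attr(best, "runs") <- runs
  best
}

#' @export
print.surbop <- function(x, ...) {
  cat("Band-selective universal-rotation pulse (quaternion GRAPE)\n")
  print(x$target)
  print(x$pulse)
  n <- length(x$cost_trace)
  cat(sprintf("  cost: %.4e -> %.4e in %d iterations (%s)\n",
              x$cost_trace[1], x$cost_trace[n], x$iterations,
              if (x$converged) "converged" else "iteration limit"))
  invisible(x)
}

#' @export
coef.surbop <- function(object, ...) {
  cbind(ux = object$pulse$ux, uy = object$pulse$uy)
}

#' Per-isochromat terminal costs of a fitted pulse
#'
#' Returns the terminal cost of every (offset, B1) pair of the fitted
#' band: [passband_cost()] in the passband, [stopband_cost()] in the
#' stopbands.  Large residuals localize where in the band the pulse
#' still deviates from the target behaviour.
#'
#' @param object a `"surbop"` fit.
#' @param ... unused.
#' @return A data.frame with columns `offset`, `b1`, `region`, `cost`.
#' @export
residuals.surbop <- function(object, ...) {
  e <- band_ensemble(object$band)
  X <- cpp_propagate_final(object$pulse$ux, object$pulse$uy,
                           object$pulse$dt, e$off, e$b1)
  cost <- ifelse(e$region == 0L,
                 passband_cost(X, object$target),
                 stopband_cost(X))
  data.frame(offset = e$off, b1 = e$b1,
             region = ifelse(e$region == 0L, "passband", "stopband"),
             cost = cost)
}

#' @export
summary.surbop <- function(object, ...) {
  r <- residuals(object)
  m <- pulse_metrics(object$pulse, object$band,
                     target = object$target)
  out <- list(fit = object, residual_summary = stats::aggregate(
    cost ~ region, data = r, FUN = function(z) c(mean = mean(z), max = max(z))),
    metrics = m)
  class(out) <- "summary.surbop"
  out
}

#' @export
print.summary.surbop <- function(x, ...) {
  print(x$fit)
  cat("\nTerminal cost by region:\n")
  print(x$residual_summary)
  cat("\nSimulated performance (optimized offset/B1 region):\n")
  print(x$metrics)
  invisible(x)
}

#' Simulated response of a fitted pulse on new offset/B1 grids
#'
#' @param object a `"surbop"` fit.
#' @param offsets offsets in Hz (default the Fig.-3-style 141-point grid).
#' @param b1_scales B1 scales (default 51 points on `[0.8, 1.2]`).
#' @param initial_state starting magnetization 3-vector.
#' @param ... unused.
#' @return A [response_map()].
#' @export
predict.surbop <- function(object, offsets = NULL, b1_scales = NULL,
                           initial_state = c(0, 0, 1), ...) {
  grid <- profile_grid(offsets = offsets, b1_scales = b1_scales,
                       initial_state = initial_state)
  response_map(object$pulse, grid)
}

#' @export
plot.surbop <- function(x, type = c("pulse", "cost"), ...) {
  type <- match.arg(type)
  if (type == "pulse") {
    plot(x$pulse, ...)
  } else {
    graphics::plot(seq_along(x$cost_trace) - 1L, x$cost_trace, type = "l",
                   log = "y", xlab = "iteration", ylab = "cost",
                   main = "GRAPE cost trace", ...)
  }
  invisible(x)
}
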