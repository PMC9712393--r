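---
title: "Designing band-selective universal-rotation pulses with quaternion GRAPE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing band-selective universal-rotation pulses with quaternion GRAPE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design problem

Protein triple-resonance NMR at the highest fields (1.2 GHz proton
frequency) needs pulses that treat the ¹³C spectrum selectively: the
aliphatic band (roughly 80 ppm, i.e. 24 kHz at a 300 MHz carbon Larmor
frequency) must experience a clean 90° or 180° rotation while the
aromatic and carbonyl bands must be left untouched.  Classical
band-selective shapes (the Gaussian cascades Q5/Q3/G4) cover this
bandwidth only when scaled to ~26 kHz peak rf-amplitude — beyond the
specification of common cryoprobes.  `surbop` implements an
optimal-control route to *universal-rotation* (UR) pulses that meet the
same selectivity within a 15 kHz amplitude budget: a UR pulse realizes
a defined rotation axis and angle for every initial magnetization
state, so it can replace a hard pulse anywhere in a sequence, in
contrast to point-to-point pulses that only map one state to another.

## Spin model and propagation

A shaped pulse is a sequence of `N` piecewise-constant steps of
duration `dt` with Cartesian controls `ux[k]`, `uy[k]` (Hz).  For a
non-interacting spin-1/2 isochromat at offset `off`, step `k` is a
rotation by

    theta = 2*pi*dt*sqrt(ux^2 + uy^2 + off^2)

about the unit axis `(ux, uy, off)/|.|`, represented as the unit
quaternion `(A, B, C, D) = (n*sin(theta/2), cos(theta/2))`.  Cumulative
propagators are built by quaternion composition, `X_k = R_k X_{k-1}`
with `R_k` the 4×4 composition matrix (`quat_matrix()`); the identity
is `(0, 0, 0, 1)`.  The degenerate zero-field step returns the identity
directly — the `sin(theta/2)/theta` factor is series-expanded near
zero, so no division by the rotation angle ever occurs.

Two conventions had to be fixed because they are genuinely open:

* **Rotation sense.**  Rotations are right-handed and active: a 90°
  rotation about +x maps +z to −y.  The mirrored convention is equally
  valid and corresponds to phase-reflected pulse shapes; every test in
  the package is consistent with the one chosen here, which is stated
  in `?quat`.
* **Units.**  Controls and offsets are plain Hz (nutation frequencies);
  all 2π factors live inside the step-quaternion construction.

B1 inhomogeneity is modeled multiplicatively: a B1 scale multiplies
`ux` and `uy` only, never the offset.

## Cost function

The band is described by `band_spec()`: a passband `[-nu_p, nu_p]`
(default ±12 kHz, sampled at 31 equally spaced offsets), two symmetric
stopbands `±[nu_s, outer]` (default ±[18, 60] kHz, 31 offsets each) and
a B1 ensemble (default 0.95, 0.975, 1, 1.025, 1.05).  Two symmetric
stopbands make the design tolerant of time or phase reversal of the
shape.  Each passband isochromat is scored by the squared quaternion
difference to the target rotation `UF`,

    Phi_sel,i = |X_N,i - UF|^2 ,

each stopband isochromat by its transverse-rotation content

    Phi_0,j = A^2 + B^2 ,

which leaves z-rotations (Bloch–Siegert-type phase shifts) free.  Note
that the passband cost penalizes `-UF` maximally although it is the
same physical rotation: pinning one lobe of the quaternion double cover
keeps the rotation's overall phase consistent across the band, which
is what makes the offset profile of the final pulse well defined.

The global cost implemented here is

    Phi = (1/n_B1) * [ w_sel/(2n) * sum_i Phi_sel,i
                     + w_0/(2m)  * sum_j Phi_0,j ] .

The `1/(2n)`, `1/(2m)` and B1-ensemble averaging mirrors the averaging
used in the adjoint gradient assembly, so the reported cost and its
gradient are *exactly* consistent — the analytic gradient is verified
against central finite differences in the test suite, which is the
defining contract for the generator matrices that appear in the
gradient expression (they are realized as the exact closed-form
derivatives of the step quaternion with respect to each control).
`w_sel` and `w_0` remain free weights (defaults 1 and 1) and are the
main knobs for trading passband fidelity against stopband suppression.

Gradients are computed by costate backpropagation: the terminal costate
is `2*w_sel*(X_N − UF)` in the passband and `2*w_0*(A, B, 0, 0)` in the
stopbands; it is transported backwards through the step rotations and
paired with the stored forward propagators.  Cost and gradient for the
full ensemble (93 offsets × 5 B1 scales by default) are evaluated in
compiled code; everything else is plain R.

## Optimizer

`surbop()` performs projected gradient descent:

1. forward-propagate all isochromats, 2. backpropagate costates,
3. assemble averaged gradients, 4. move the controls along the descent
direction, 5. radially clip every step to the amplitude limit
(`u_max`, default 15 kHz), 6. iterate.

The printed update rule in the GRAPE literature adds `+eps*grad`; since
the quaternion-difference `Phi` is a cost to be *minimized*, the package
moves against the gradient.  The step size is chosen per iteration by a
simple line minimization: starting from the previous accepted step, the
step is doubled while the cost of the clipped candidate keeps dropping,
or halved until the first decrease.  Because acceptance is evaluated on
the *clipped* candidate, the cost trace is non-increasing with the
constraint active, and every iterate satisfies the amplitude limit
exactly.  A fixed-step mode reproduces the literal update rule, and a
Polak–Ribière conjugate-gradient direction (with automatic restart to
steepest descent) is available; steepest descent is the default for
fidelity to the printed algorithm.  Convergence is declared when the
relative cost change stays below `tol` (default 1e-8) for 10
consecutive iterations, when no step size yields any decrease
(stationarity under the projection), or at `max_iter`.

GRAPE only finds local optima, so results depend on the random start.
`random_pulse()` draws per-step amplitudes uniformly on `[0, u_max]`
and phases uniformly on `[0°, 360°)` — uniform *polar* sampling, which
is the natural reading of "random amplitudes and phases" — at 0.5 µs
steps.  `surbop_multistart()` ranks several seeded runs and returns the
best.  The published design campaigns ran thousands of starts with
systematically varied weights and pulse lengths; this package makes no
claim to reproduce the exact published shapes, which are one particular
pair of local optima.

One geometric detail: the published pulse length 333.3 µs is not an
integer multiple of the 0.5 µs timestep, so the flagship default here
is `N = 667` steps = 333.5 µs; the duration is fully configurable, and
shapes loaded from files keep their own timing.

## Response simulation and metrics

`response_map()` propagates an arbitrary initial state over an
offset × B1 grid (default 141 offsets spanning 130 kHz × 51 B1 scales
on [0.8, 1.2], from equilibrium z-magnetization) using the exact
quaternion propagator — no relaxation, non-interacting spins — and
`offset_profile()` produces 1-D profiles with a global zero-order phase
chosen so the central offset is purely absorptive, matching how
experimental offset profiles are processed.

`pulse_metrics()` reduces a design to three numbers over the optimized
offset/B1 region of a `band_spec`:

* **passband ripple** `100*(I_max − I_min)/I_max` in percent.  "Peak
  intensity" is not uniquely defined in the field; the convention here
  is the absorptive transverse component of initially-longitudinal
  magnetization after global phasing for (near-)90° targets, and the
  inverted longitudinal component `−Mz` for (near-)180° targets.
* **maximum phase deviation** of the transverse signal across the
  passband (for 180° targets measured on refocused transverse
  magnetization), in degrees.
* **stopband leakage**, the largest `sqrt(A² + B²)` of the net
  propagator over the stopband offsets and the band's B1 scales.

## What the tests do and do not show

All test inputs are synthetic — random starting shapes with fixed
seeds, closed-form rotations, and ideal hard pulses; there is no
measured data in the package.  Propagation is verified against two
independent oracles (an SU(2) complex-matrix product and direct
numerical integration of the Bloch equations), gradients against
central finite differences, and the optimizer on reduced problem sizes
chosen so the whole suite runs in minutes: 100–200-step pulses
(50–100 µs) for convergence properties and one 667-step (333.5 µs)
single-seed run for the full-scale design.  A practical finite-
difference note: with a step of 1e-3 Hz on an order-one cost, central
differences carry ~1e-13 absolute round-off, so gradient components
that are essentially zero can only be compared in the vector norm at
that step; per-component agreement is verified at a larger step where
round-off is negligible.

Two honest limitations of the reduced-scale checks deserve emphasis:

* **Short pulses hit a physical wall, not an algorithmic one.**  At
  50 µs (N = 100) both targets converge to genuine local plateaus
  (~11% of the starting cost for 180°, ~42% for 90°, identical for
  steepest descent and conjugate gradients across seeds).  The residual
  passband cost grows quadratically with offset — an uncompensated
  linear phase roll equivalent to free evolution over roughly half the
  pulse length.  Refocusing that roll over a ±12 kHz band through a
  6 kHz transition needs on the order of the published 333 µs; the
  full-scale run reaches ~0.4% of its starting cost with the same
  machinery.
* **A single default-weight run does not match a tuned campaign.**
  With `w_sel = w_0 = 1`, one 1000-iteration full-scale run from a
  fixed seed brings the stopband leakage below 0.05 at every stopband
  grid offset for the 90° target (this is verified in the test suite);
  equivalent single runs for the 180° target stay well above that
  level, because near-constant-amplitude refocusing solutions bleed
  more into the stopbands.  Reaching the published stopband quality for
  refocusing pulses requires the weight tuning and multi-start
  selection the original campaign used.

The comparison of simulated passband ripple against the published
values (2.80% for the 180° and 1.53% for the 90° design) additionally
depends on the authors' published shape files, which are distributed
from their institute's site and are not bundled with the package; the
corresponding test states this requirement explicitly.

Relaxation, coupled-spin evolution, amplifier droop and other
spectrometer artifacts are out of scope throughout — performance on
real hardware is expected to be slightly below simulation, as the
original experimental profiles show.
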