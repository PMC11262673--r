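---
title: "Monitored tomographic reconstruction: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitored tomographic reconstruction: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtrecon)
```

## The problem

A computed-tomography scan acquires projections one angle at a time. In a
*monitored* protocol the instrument reconstructs in real time from the
projections acquired so far, a quality signal is evaluated after each
reconstruction cycle (a *decision point*), and acquisition stops early once
the signal stabilises. Whether this is worth doing on a given instrument
depends on three quantitative questions this package models:

1. how scan time and dose accumulate per projection, and how the
   *acquisition order* changes that (`projection_costs()`,
   `acquisition_totals()`, `acquisition_curves()`);
2. whether a reconstruction cycle fits into the acquisition at all, i.e.
   how many partial reconstructions per scan a given GPU and algorithm can
   deliver (`recon_time()`, `recons_per_acquisition()`);
3. what image quality a partial reconstruction has at each stopping point,
   which depends strongly on the acquisition order (`fbp_reconstruct()`,
   `fbp_update()`, `convergence_report()`).

`mtr_simulate()` ties the three together in a discrete-event simulation of
the asynchronous acquire/reconstruct loop with a pluggable stopping rule.

## Acquisition orders

Angles live on a half-open grid: `angle_grid(a_min, a_max, n_proj)` places
angle `j` at `a_min + j/n_proj * (a_max - a_min)`; the upper limit is never
generated because on a full circle it repeats the first angle. Three orders
are provided:

* **consecutive** — `order(i) = i`; total travel over a full circle is one
  rotation (~360 deg) regardless of the projection count, but a partial
  data set is an angular wedge, which reconstructs with severe
  limited-angle artifacts;
* **random** — a seeded uniform permutation; partial data are always well
  spread, but the expected travel per step is 90 deg for a stage that can
  reverse (shortest arc) and 180 deg for one-way rotation, which slows
  most instruments by roughly an order of magnitude;
* **logarithmic** — a prescan rotation of `n_prescan` equidistant angles,
  then midpoint-refinement rotations that double the angular sampling each
  time. After every completed rotation the acquired set is equidistant, so
  classical filtered back projection stays artifact-free, while total
  travel is only `360 * (1 + log2(n_proj / n_prescan))` degrees.

Two conventions were genuinely open and are fixed as follows. Within a
logarithmic refinement rotation the new angles are visited in ascending
angle (a single sweep); any intra-rotation ordering preserves the
equidistance property, and a monotone sweep is what a rotation stage would
do. Travel metrics default to bidirectional (shortest-arc) movement, with
`rotation = "unidirectional"` for gantry-style one-way systems; for the
consecutive and logarithmic orders the two coincide on a full-circle grid.
`n_proj / n_prescan` must be a power of two — other ratios cannot keep the
set equidistant at every rotation boundary and are rejected rather than
approximated.

## The time/dose model

Per acquired projection `i` the model charges

* exposure `t_exp = t_frame + c_det` (useful frame time plus readout
  overhead),
* movement `t_move = c_move + dist_i * time_per_rotation / 360`, where
  `dist_i` is the angular travel to reach the projection (the first
  projection's initial positioning is charged zero travel, so all
  `n_proj` movement overheads are counted),
* gating `t_gate = gate * c_gate_move`.

Quasi-stationary instruments (step-and-shoot stages) pay the *sum* of the
three per projection; continuously rotating systems (medical gantry, cargo
portal) expose while moving and pay the per-projection *maximum* of
exposure+gating and movement. Dose is accounted in object-exposition
seconds: exposure always contributes, movement contributes only when the
beam is not gated, and gating itself may cost a fixed dose overhead per
projection (`c_gate_dose`). A consequence the tests assert: with gating
active the total dose is identical for every acquisition order, because
the order only enters through movement.

One printed-notation ambiguity had to be resolved: the source model writes
the movement dose with a bare gate indicator, which taken literally would
make gating *add* movement dose, contradicting the stated purpose of
gating and the published dose curves. The package implements
`d_move = (1 - gate) * t_move`.

The five instrument presets (micro, nano, medical, cargo, EBCT) carry the
published parameter sets verbatim; zero entries are literal zeros
(unavailable and presumed negligible). Two caveats are worth knowing:

* the published nano CT total (4.9e4 s) is inconsistent with the published
  nano per-projection parameters, which evaluate to ~1.45e5 s; the preset
  ships the printed parameters and the total is simply what the model
  gives;
* the published ~10x slowdown of random order on the micro preset
  evaluates to ~7.7x under the model as printed (1024 s of exposure plus
  ~90.2 deg of travel per step at 6 deg/s against 1135 s consecutive);
  the package reports the computed ratio.

Rotation speed is derived as `360 / time_per_rotation` even when the angle
range is smaller than a full circle (cargo, 256 deg), and a
`time_per_rotation` of zero (EBCT beam steering) means angle changes cost
only the constant `c_move`.

## The GPU reconstruction-cost model

A reconstruction (or incremental update) is decomposed into host-to-device
load, device memory traffic, projection preprocessing, and the kernel term
`it_count * vol_size * n_a * p_voxel / s_rec`, with
`proj_size = n_x * n_z * n_a` and `vol_size = n_x^2 * n_z`. Choices made
where the source is silent:

* pixels are 4 bytes (single precision) — the source mixes pixel counts
  with byte rates without stating a width;
* the host-to-device load is a one-time per-experiment cost, excluded from
  per-cycle times by default (`include_load = FALSE`); the published cycle
  times are only reproducible under this reading;
* SIRT is charged `iteration_ops_multiplier = 3` backprojection-equivalent
  passes per iteration (forward, back, update); the literal one-pass
  reading underestimates the published SIRT cells by about 3x;
* `recons_per_acquisition()` floors the quotient, and a result below one
  raises the infeasibility flag — real-time reconstruction is impossible
  on that combination;
* a memory-fit check warns when volume plus projections exceed device RAM
  (the model itself assumes residency, as its source does).

The model's calibration anchor — a 1000x1000-detector, 500-projection
batch FBP on the current-generation preset GPU — evaluates to ~3.5 s
against a 4 s measurement, within the model's order-of-magnitude remit.
The published medical CT cycle cells are ~1.7x smaller than the model
evaluates from the same tables; they are treated as a documented
discrepancy, not a calibration target.

## Partial FBP and the incremental update

The 2D parallel-beam core renders a deterministic ellipse head phantom
(values in [0, 1], edges antialiased by subpixel averaging), forward
projects by ray sampling with bilinear interpolation (0.5-pixel steps,
lengths in pixel units), ramp filters with the band-limited discrete
kernel (`h(0) = 1/4`, `h(odd k) = -1/(pi^2 k^2)`, FFT convolution with
zero padding to the next power of two at least twice the detector length;
optional Hann apodization), and backprojects with linear detector
interpolation, pixel centres at `(index - (n-1)/2)` and the origin at the
grid centre.

The accumulator of a partial reconstruction stores the *average* of the
filtered backprojections. Batch reconstruction from `n` projections and
the recurrence

v[n+1] = (n * v[n] + backproject(p~[n+1])) / (n + 1)

are algebraically identical, which the tests assert to 1e-6 relative
max-difference; the incremental form costs one filter+backprojection per
update whatever `n` is, which is the O(1)-per-cycle property the
monitored protocol relies on. The read-out image applies the global scale
`pi` (the quadrature weight of an equidistant full-circle angle set with
unit detector spacing); keeping the scale at read-out makes the
incremental invariant scale-free. Partial, non-equidistant subsets
inherit the same scale, which is exactly what produces the wedge and
streak artifacts the protocol comparison is about.

Primary geometry is parallel-beam, which admits an independent
inverse-radon oracle (the test suite cross-checks full-data FBP against
scikit-image's `iradon` on a shared sinogram, on an odd-sized grid so both
implementations use the same rotation centre, agreeing to ~1% relative
RMSE). Fan-beam geometry is not implemented; the order-quality phenomena
are geometry-independent, with one caveat: in parallel geometry a
consecutive half-turn (180 deg) is already a complete data set, so
"equidistant beats a consecutive wedge" holds for true wedges
(n < n_proj/2) and the comparison is made there. With the full projection
set all orders reconstruct the same image to floating-point accuracy, and
full-data fidelity on the 512-grid study condition is ~8% relative RMSE
inside the reconstruction circle (asserted < 10%).

SIRT uses the standard row/column-sum normalisation with relaxation 0.9
(the source does not specify its SIRT variant); the residual is recorded
per iteration, and warm starts from any partial reconstruction are
supported.

## The monitored-run simulator

`mtr_simulate()` runs in simulated time: acquisition events occur at the
cumulative times of the time/dose model and are never blocked by
reconstruction; a single worker consumes the whole FIFO queue each cycle,
with cycle duration from a pluggable cost model (fixed overhead plus
per-new-projection cost by default — validation experience shows the fixed
part dominates). After each cycle the quality function is evaluated and
the stopping rule sees the history; `n_rec` counts cycles completed
before acquisition ends and is the protocol's decision-scale resolution.
Consequences asserted by the tests: with an instant cycle `n_rec = n_proj`
(one decision per projection, the theoretical-study limit); a cycle longer
than the whole acquisition gives `n_rec = 0` and the infeasibility flag;
and with a never-firing rule the realised time and dose equal the
standard-protocol totals exactly — monitoring is free on the acquisition
path. A fixed 3 s cycle on the micro preset yields ~377 cycles per
512-projection run, the same regime as the ~385 measured on the reference
validation stand.

The default `stop_on_plateau(epsilon, patience)` rule stops once the
relative change of the quality signal between successive decision points
stays below `epsilon` for `patience` points, and never before three
decision points exist (baseline, first difference, first comparable
difference). Quality assessment is deliberately task-specific, so the
quality signal is an argument, not a fixture of the engine; zero cycle
cost is allowed (the instant-reconstruction limit), negative cost is an
error.

## Problem sizes and what the synthetic experiments do not show

The package's study conditions are those of the published configurations:
512 projections on a 360-degree grid with a 512x512 image for the
protocol-scale quality comparison, `n_prescan = 4` for the logarithmic
validation case, and the printed instrument/GPU parameter sets. Unit
tests run the same physics on 64- and 128-sized grids purely to keep the
suite fast; the convergence bounds they assert are stated at those sizes
(the last-update relative change scales as 1/n: ~4% at n = 128, ~1.4% at
n = 512).

The synthetic phantom experiments emulate geometry and sampling, not
physics: no noise, no beam hardening, no scatter, no detector blur, and
an inverse-crime pairing of forward and backprojector discretisations.
Passing tests therefore demonstrate the ordering/convergence/accounting
properties of the protocol machinery, not clinical image quality. The
time/dose model is empirical and per-projection; it does not model
spectrum, mAs-based dosimetry, or helical trajectories (helical scans are
represented by the equivalent circular geometry, as in its source). The
measured hardware numbers of the reference validation stand (1.3e3 s,
385/440 reconstructions) are wall-clock measurements of a specific rig;
the simulator reproduces their qualitative regime — queue growth once
acquisition outpaces cycles, logarithmic order trading ~40% extra
acquisition time for artifact-free checkpoints — but only the *modeled*
totals (1135 s consecutive, 1555 s logarithmic) are numeric targets.
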