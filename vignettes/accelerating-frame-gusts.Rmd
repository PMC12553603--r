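---
title: "Methods: accelerating-frame simulation of transverse gust response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerating-frame simulation of transverse gust response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gustfall)
```

## The model

`gustfall` simulates a rigid body falling (or hovering) in an incompressible
fluid while the far-field fluid undergoes a prescribed horizontal
acceleration — a uniform, irrotational transverse gust. The package's frame
convention is x vertical upward (streamwise in a vertically blowing tunnel),
y horizontal along the gust, z completing the right-handed triad; planar
demonstrations live in the x–y plane with rotation about z, positive angles
being clockwise for a viewer of that plane.

Two mathematically equivalent formulations are implemented and checked
against each other:

**Tunnel frame** (non-inertial, translating with the gust velocity `u_G(t)`,
zero angular velocity). The ambient flow is the steady inflow; the gust never
touches the fluid state and enters the body equations only as

* a linear term `m⁻¹ F + (1 − ρ_f/ρ_b)(g − u̇_G)`, where `F` is the
  quasi-steady aerodynamic force and the second term combines gravity,
  buoyancy, the fictitious force and the gust-buoyancy force; and
* a torque `e r̂_w × [−ρ_f V (g − u̇_G)]` about the centre of gravity, because
  every buoyancy-type force acts at the centre of buoyancy (offset `e r̂`
  from the centre of gravity, rotated to world axes), while gravity and the
  fictitious force act at the centre of gravity and contribute no couple.

**Inertial frame.** The ambient fluid moves at `inflow + u_G(t)`; the
accelerating fluid carries a uniform pressure gradient whose resultant on the
displaced volume is `+ρ_f V u̇_G` at the centre of buoyancy. The torque
expression is identical in the two frames, which is why the orientation
dynamics agree without any mapping.

A trajectory computed in the inertial frame, after subtracting the gust
displacement and velocity, must coincide with the tunnel-frame trajectory up
to integration error. `run_frame_pair()` /
`equivalence_deviation()` operationalise this as a testable contract, and the
test suite exercises it over a closures × gusts × buoyancy matrix.

Two consequences of the formulation are used as strong oracles:

* **Neutral buoyancy.** With `ρ_f = ρ_b` the factor `(1 − ρ_f/ρ_b)` is
  exactly zero in floating point, and for a homogeneous body (`e = 0`) every
  gust term vanishes identically, so a gusted and an ungusted run are
  bitwise identical provided both are integrated with the same restart
  points (the `breakpoints` argument exists for exactly this comparison).
  Note the qualifier: a *neutrally buoyant but bottom-heavy* body
  (`e > 0`) still feels the gust-buoyancy couple `e r̂ × ρ_f V u̇_G`, because
  the pressure-gradient force acts at the centre of buoyancy while the
  inertia acts at the centre of mass. The null statement concerns the net
  force, and the package keeps the couple.
* **Effective gravity.** For a horizontal gust the body behaves as if gravity
  were `g − u̇_G`, with magnitude `sqrt(g² + u̇_G²)` and tilt
  `atan(u̇_G/g)`. (The tilt is an arctangent on dimensional grounds, although
  it is sometimes written as a bare tangent.)

## Aerodynamic closures

The fluid loads `F`, `T_o` that a flow solver or experiment would supply are
represented by quasi-steady closures acting at the centre of gravity:

* `linear_drag_closure(c, c_ω)`: `F = −c u_rel`, `T_o = −c_ω ω`. Its analytic
  solutions (terminal velocity `m g*/c`, relaxation time `m/c`, post-step
  decay `−(1 − ρ_f/ρ_b) v₁ e^{−t/τ}`) serve as integration oracles, and its
  isotropy makes the vertical response to a horizontal gust exactly zero — a
  useful negative control.
* `quadratic_drag_closure(C_D, A, c_ω)`: `F = −½ ρ_f C_D A |u_rel| u_rel`.
  The `|u_rel|` coupling converts horizontal slip into extra vertical drag,
  which is the mechanism behind the transient altitude gain of a drag-borne
  diaspore in a gust.

Closures are deliberately *not* where buoyancy lives: the decomposition into
fluid loads versus gravity/buoyancy terms mirrors the governing equations and
keeps the closure interface the extension point for CFD- or data-driven
forces. No added-mass or history (Basset) forces are included; for the
millimetre-scale, low-speed regime targeted here they are subdominant, but
this is a stated limitation, not a claim.

`terminal_velocity()` solves the vertical force balance by bracketed root
finding on [1e-6, 1e3] m/s (Brent, tolerance 1e-14 absolute) and matches the
closed forms of both built-in closures to better than 1e-9 relative;
`calibrate_closure_to_terminal_velocity()` inverts the same balance in closed
form, mirroring the experimental procedure of matching the tunnel airflow to
a specimen's measured terminal velocity.

## Numerical choices

* **Integrator.** Dormand–Prince Runge–Kutta 4(5) (`deSolve::ode`,
  `method = "ode45"`), relative tolerance 1e-8 and absolute tolerance 1e-10
  by default. Orientation is a unit quaternion (one code path for planar and
  spatial cases, no gimbal singularities), renormalised at every derivative
  evaluation and on output.
* **Discontinuities are structural, not numerical.** Step gusts carry their
  velocity jump as an explicit impulse record; the integrator stops at the
  impulse time, applies the exact velocity jump
  (`−(1 − ρ_f/ρ_b) Δv` in the tunnel frame, `+(ρ_f/ρ_b) Δv` in the inertial
  frame) and the matching angular impulse, and restarts. Ramp corners —
  where the forcing has a kink — are likewise restart points. Within a
  segment the right-hand side is smooth, so the scheme keeps its design
  order; at a segment end that sits exactly on a discontinuity, stage
  evaluations use the profile's left limit (profiles are otherwise
  right-continuous). Restart times that nearly coincide with an output time
  are snapped onto it so the time grid never contains ulp-separated
  duplicates.
* **Step-size cap.** The internal step is capped at the output spacing. The
  embedded error estimator controls only the step endpoint; without the cap,
  dense-output samples inside an over-long step taken right after a forcing
  onset can carry interpolation error well above the integration tolerance.
* **States at an impulse time are right-continuous** (post-jump), matching
  the step-profile convention.
* **Degenerate inputs** fail loudly: neutral buoyancy in
  `gravitational_velocity()` (the scaling is undefined there), non-SPD
  inertia tensors, zero-length directions, single-frame field statistics,
  coincident tip/centroid points in the stem angle, windows selecting no
  grid points.

All internal computation is dimensional (SI); dimensionless groups (`Ga`,
`Re`, `ρ`, gust ratio) are derived for reporting. This avoids the `u_g`
singularity at neutral buoyancy while keeping the non-dimensional view
available, and integrating dimensionally then rescaling is equivalent to
integrating the non-dimensional equations.

## Flow statistics and tracking conventions

`turbulence_intensity()` implements the pointwise RMS fluctuation normalised
by the **local** time-mean speed (not a window mean), with time means over
frames; zero-mean-speed points are masked and counted rather than divided
by. `flow_uniformity()` normalises the time-averaged speed map by its
spatial mean over the analysis window, whose default mirrors a 40 mm × 80 mm
central region. Frame shifting subtracts the spatially uniform tunnel
velocity from the horizontal component only — by construction it cannot
change any spatial gradient.

The de-noising filter is a **centred** ten-point moving average with
shrinking windows at the series ends, so series length and event timestamps
are preserved. (Whether the original procedure centred or trailed its filter
is not documented; centring avoids a five-sample lag on the gust-onset and
stop times. An even window still carries an intrinsic half-sample shift,
which the tests account for.) Derivatives are second-order-accurate central
differences with second-order one-sided stencils at the ends; the phrase
"second-order time derivative" in descriptions of such pipelines is read
here as a second-order-*accurate* first derivative, since the quantity it
produces is a velocity. The stem angle is the angle of the tip-to-centroid
axis from vertical, positive clockwise (a top leaning towards +y is
positive).

Pressure reconstruction restores the vertical hydrostatic term
`−g (x − x_out)` and, in the accelerating frame, the horizontal
gust-hydrostatic term `−u̇_G y′`. The horizontal term is written here with
the gust *acceleration*, which dimensional consistency requires even though
it occasionally appears typeset with the velocity symbol. Both terms are
linear in the coordinates: they shift the pressure gradient uniformly and
contribute nothing to the pressure Laplacian.

## The synthetic-data generators

The fixtures emulate the facility's demonstration conditions:

* camera at 750 frames/s, 0.0805 mm/pixel, ~1 px RMS centroid noise;
* tunnel plateau at exactly −2 û_t = −0.76 m/s (the printed value, −0.8 m/s,
  is this number at one decimal), braking from 0.1 s to a stop at 0.27 s;
* the braking pulse is `a(t) = a_peak sin^p(π (t − t₀)/Δt)` with `p` solved
  numerically (by bracketed root finding on the pulse integral) so that a
  pulse peaking at 11 m/s² integrates exactly to 0.76 m/s over 0.17 s — the
  stated peak is honoured without pretending the deceleration was constant;
* low-turbulence vertical flow: independent Gaussian fluctuations on both
  velocity components scaled so the expected intensity matches the
  prescription (default 0.8%), on a 2 mm grid over the analysis window.

The virtual diaspore couples a quadratic closure calibrated to
û_t = 0.38 m/s (the one measured property of the reference specimen) to a
bottom-heavy body. Its remaining properties are plausible order-of-magnitude
choices, flagged `non_paper_default` in its metadata and chosen once: mass
0.6 mg and mean density 60 kg/m³ (a 10 mm³ effective displaced volume —
deliberately an *effective* value, since the displaced volume of a porous
pappus is not well defined), centre-of-buoyancy offset e = 3 mm along the
stem, transverse moment of inertia 1.5e-11 kg m² (mass concentrated near the
seed), and rotational damping 1.2e-10 N m s, about 0.8 of critical for the
buoyancy-pendulum mode, so the body rights itself within a couple of
seconds. With these choices the demonstration scenario shows the qualitative
phenomenology the method was built to expose — clockwise rotation during the
braking pulse, buoyancy-driven righting afterwards, and a millimetre-scale
permanent altitude gain — but the *magnitudes* of those responses are
functions of the stand-in parameters and should not be read as predictions
for a real specimen.

What the generators do **not** emulate: PIV cross-correlation artefacts and
window stitching, shear in the gust (the method is exactly shear-free),
wake instabilities and unsteady aerodynamics of the pappus, added-mass
effects, and three-dimensional tumbling of the real diaspore. Passing tests
therefore demonstrate the correctness of the frame mechanics, the statistics
and the pipelines, not the fidelity of any particular aerodynamic closure to
a real dandelion.

## Problem sizes

The test and acceptance runs use: 5 s frame-equivalence integrations at 50 ms
output spacing over an 18-case matrix; a 4 s demonstration at the 750 Hz
camera rate; 2000-frame turbulence fixtures on a 21 × 41 grid; and 0.4 s
tracks at 750 frames/s. These sizes resolve every timescale in the problem
(the slowest being the ~1.3 s righting period) while keeping a full run in
the tens of seconds.

## Known limitations

* Quasi-steady, orientation-independent drag closures; no lift, added mass,
  or history forces. The closure interface is the intended extension point.
* The flow field itself is never solved; the method's premise (the gust does
  not change the tunnel-frame flow) enters as a contract, verified
  experimentally elsewhere, not recomputed here.
* Single-camera, single-window field analysis; no stitching.
* Step gusts are idealisations: a physical tunnel realises a finite-duration
  pulse, which is why the demonstration uses the smooth braking profile.
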