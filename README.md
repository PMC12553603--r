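# gustfall

Simulation and analysis tools for studying how **untethered free-falling
bodies** — plant diaspores such as the dandelion's pappus-borne seed, spores,
or seed-inspired microrobots — respond to **uniform, irrotational transverse
gusts**.

## The idea

A transverse gust for a falling body is a horizontal acceleration of the
surrounding air. If the whole volume of fluid around the body is accelerated
uniformly (for example by translating a vertically blowing wind tunnel
horizontally), the flow field observed in the frame moving with the fluid is
*unchanged*: the acceleration only adds a uniform horizontal pressure
gradient, exactly as gravity adds the vertical hydrostatic pressure. In that
non-inertial "tunnel frame" the gust acts on a rigid body only through

* a **reduced gust force** `-m (1 - ρ_f/ρ_b) u̇_G` at the centre of gravity
  (the body's inertia minus the inertia of the displaced fluid), and
* a **buoyancy couple**: all buoyancy-type forces, `-ρ_f V (g - u̇_G)`, act at
  the centre of buoyancy, offset by `e r̂` from the centre of gravity.

Equivalently, the gust temporarily replaces gravity by the **effective
gravity** `g - u̇_G`, of magnitude `(g² + u̇_G²)^{1/2}` for a horizontal gust,
tilted by `atan(u̇_G/g)` away from the gust direction. At neutral buoyancy
(`ρ_f = ρ_b`) the reduced gust force vanishes for any gust: the body simply
rides along with the fluid.

The package implements this accelerating-frame method end to end:

* **scales** — reduced gravity `g* = (1 - ρ_f/ρ_b) g`, gravitational velocity
  `u_g = (m g*/ρ_f l²)^{1/2}`, Galilei number `Ga = u_g l/ν`, Reynolds number
  `Re = u_t l/ν`, density ratio `ρ = ρ_f/ρ_b`;
* **gusts** — step (Wagner-type), ramp, sine and tabulated gust profiles with
  exact impulse handling for velocity jumps, plus the effective-gravity
  construction;
* **bodies & closures** — body specifications (mass, inertia,
  centre-of-buoyancy offset) with pluggable quasi-steady aerodynamic closures
  (linear and quadratic drag), terminal-velocity solving and calibration;
* **dynamics** — adaptive Runge–Kutta 4(5) integration of the rigid-body
  equations in either the tunnel frame or the inertial frame, with a
  verifiable frame-equivalence check;
* **flow analysis** — flow uniformity, turbulence-intensity maps
  (RMS fluctuation over local mean speed), frame shifting `u' = u - u_G` of
  measured velocity fields, and hydrostatic/gust-hydrostatic pressure
  reconstruction;
* **tracking** — marker-track kinematics: pixel-to-metre conversion, ten-point
  centred moving-average de-noising, second-order differentiation, tunnel
  gust-profile extraction and the positive-clockwise stem-angle convention;
* **fixtures** — seeded synthetic data (fields, tracks, a calibrated virtual
  diaspore and a full demonstration scenario) so every pipeline is testable
  without external data.

## Worked example

The reference virtual diaspore hovers in a 0.38 m/s upward airstream (its
calibrated terminal velocity) and experiences a Wagner-type stop gust: the
tunnel translates at −0.76 m/s (twice the terminal velocity, a gust ratio
of 2) and brakes to rest between 0.1 s and 0.27 s with a peak deceleration of
11 m/s².

```r
library(gustfall)
dia <- virtual_diaspore()
scale_set(dia$body, dia$medium, u_t = dia$u_t)
#> <scale_set>
#>   g_star  9.61315
#>   u_g     0.156339
#>   Ga      145.916
#>   rho     0.0200667
#>   m_nd    0.18161
#>   Re      354.667

effective_gravity(c(-9.81, 0, 0), c(0, 11, 0))
#> <effective_gravity> |g_eff| 14.74 m/s^2, tilt 0.8425 rad

sc <- demo_scenario()
sc$gust_ratio                          # 2
max(sc$theta$theta)                    # 0.156 rad (~8.9 deg, clockwise)
1000 * tail(sc$height_change$dx, 1)    # 3.15 mm altitude gain
```

During the braking pulse the gust-buoyancy couple rotates the diaspore
clockwise (positive stem angle); once the pulse ends the ordinary buoyancy
couple rights it back upright, and the transient horizontal slip through the
air increases the relative airspeed, boosting vertical drag: the diaspore
settles about 3 mm *higher* than it started. Replacing the quadratic drag law
with an isotropic linear one removes the speed coupling and the altitude gain
vanishes identically — the discriminating mechanism for the observed height
increase.

## Command line

A thin CLI over the same functions lives in `inst/cli/gustfall.R`:

```sh
Rscript inst/cli/gustfall.R make-fixtures --out-dir fixtures --seed 1
Rscript inst/cli/gustfall.R simulate     --config fixtures/demo_config.yaml --out-dir out
Rscript inst/cli/gustfall.R equivalence  --config fixtures/demo_config.yaml --out-dir out
Rscript inst/cli/gustfall.R characterise --field fixtures/field_series.csv  --out-dir out
Rscript inst/cli/gustfall.R kinematics   --track fixtures/tunnel_track.csv  --out-dir out
```

Configurations are YAML with unit-suffixed keys (`mass_kg`, `onset_s`, ...);
every run writes a metadata sidecar that reproduces it.

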