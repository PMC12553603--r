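#' Synthetic velocity-field series
#'
#' Generates a gridded velocity-field time series emulating PIV of a
#' well-conditioned vertical tunnel: a spatially uniform upward mean flow plus
#' independent Gaussian fluctuations on both components, scaled so that the
#' expected turbulence intensity (RMS fluctuation over local mean speed)
#' equals `intensity`. The generator is a pure function of its arguments and
#' the seed; identical calls are identical.
#'
#' @param mean_speed Mean streamwise speed (m s^-1), positive.
#' @param intensity Prescribed turbulence intensity (dimensionless), >= 0.
#' @param x,y Grid coordinates (m). Defaults emulate a 2 mm grid on an
#'   80 mm wide by 40 mm high analysis window.
#' @param n_frames Number of frames, >= 2.
#' @param frame_rate Acquisition rate (s^-1).
#' @param seed RNG seed.
#' @return A [field_series()].
#' @export
synth_field_series <- function(mean_speed = 0.38, intensity = 0.008,
                               x = seq(-0.02, 0.02, by = 0.002),
                               y = seq(-0.04, 0.04, by = 0.002),
                               n_frames = 2000, frame_rate = 1000, seed = 1) {
  check_positive(mean_speed, "mean_speed")
  check_nonnegative(intensity, "intensity")
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  nx <- length(x); ny <- length(y)
  sigma <- intensity * mean_speed
  with_seed(seed, {
    u <- mean_speed + array(stats::rnorm(nx * ny * n_frames, sd = sigma),
                            c(nx, ny, n_frames))
    v <- array(stats::rnorm(nx * ny * n_frames, sd = sigma), c(nx, ny, n_frames))
    if (sigma == 0) {
      u <- array(mean_speed, c(nx, ny, n_frames))
      v <- array(0, c(nx, ny, n_frames))
    }
    field_series(x, y, u, v, times = (seq_len(n_frames) - 1) / frame_rate)
  })
}

#' Synthetic tunnel marker track
#'
#' Integrates a gust (tunnel translation) profile to displacement, samples it
#' at the camera frame rate, converts to pixels at the stated resolution and
#' adds seeded Gaussian pixel noise — a virtual version of tracking a marker
#' mounted on the rear of the tunnel.
#'
#' @param profile A [gust_profiles] object: the tunnel velocity history.
#' @param duration Track duration (s), positive.
#' @param frame_rate Camera frame rate (s^-1), default 750.
#' @param resolution_mm_px Image resolution (mm per pixel), default 0.0805.
#' @param noise_px RMS pixel noise, >= 0.
#' @param seed RNG seed.
#' @param x0_px,y0_px Marker position at `t = 0` (px).
#' @return A [track_series()].
#' @export
synth_tunnel_track <- function(profile, duration, frame_rate = 750,
                               resolution_mm_px = 0.0805, noise_px = 1,
                               seed = 1, x0_px = 500, y0_px = 500) {
  stopifnot(inherits(profile, "gust_profile"))
  check_positive(duration, "duration")
  check_nonnegative(noise_px, "noise_px")
  t <- seq(0, duration, by = 1 / frame_rate)
  disp_m <- gust_disp_scalar(profile, t)
  disp_px <- disp_m / (resolution_mm_px * 1e-3)
  with_seed(seed, {
    n <- length(t)
    x_px <- rep(x0_px, n) + if (noise_px > 0) stats::rnorm(n, sd = noise_px) else 0
    y_px <- y0_px + disp_px + if (noise_px > 0) stats::rnorm(n, sd = noise_px) else 0
    track_series(x_px, y_px, frame_rate, resolution_mm_px)
  })
}

#' Demonstration stop-gust profile
#'
#' The Wagner-type gust realised by translating the tunnel at a constant
#' plateau speed and braking it smoothly to a stop. The plateau is
#' `-2 u_t = -0.76` m/s for the reference diaspore (gust ratio 2); braking
#' starts at `t_start` and ends at `t_stop`. The deceleration pulse is
#' `a(t) = a_peak * sin^p(pi (t - t_start) / (t_stop - t_start))`, with the
#' exponent `p` solved numerically so that a pulse peaking at `peak_decel`
#' integrates exactly to the plateau speed: the stated peak deceleration and
#' the stop time are then both honoured without assuming a constant
#' deceleration. Returned as a finely tabulated profile.
#'
#' @param u_plateau Plateau (pre-gust) tunnel velocity (m s^-1), non-zero.
#' @param t_start Braking onset (s).
#' @param t_stop Stop time (s), > `t_start`.
#' @param peak_decel Peak deceleration magnitude (m s^-2); must exceed the
#'   mean deceleration `|u_plateau| / (t_stop - t_start)`.
#' @param t_end Last tabulated time (s), >= `t_stop`.
#' @param dt Tabulation step (s).
#' @return A [gust_tabulated()] profile along +y.
#' @export
demo_gust_profile <- function(u_plateau = -0.76, t_start = 0.1, t_stop = 0.27,
                              peak_decel = 11, t_end = 0.6, dt = 1e-4) {
  stopifnot(is.finite(u_plateau), u_plateau != 0, t_stop > t_start, t_end >= t_stop)
  check_positive(peak_decel, "peak_decel")
  dur <- t_stop - t_start
  # Fraction of a unit-peak sin^p pulse: c(p) = integral_0^1 sin^p(pi s) ds,
  # monotonically decreasing in p; solve c(p) = |u_plateau| / (peak * dur).
  target <- abs(u_plateau) / (peak_decel * dur)
  if (target >= 1 || target <= 0) {
    stop("'peak_decel' must exceed the mean deceleration |u_plateau|/(t_stop - t_start)",
         call. = FALSE)
  }
  cfun <- function(p) stats::integrate(function(s) sin(pi * s)^p, 0, 1,
                                       rel.tol = 1e-10)$value - target
  p <- stats::uniroot(cfun, c(1e-3, 60), tol = 1e-12)$root
  t <- seq(0, t_end, by = dt)
  s <- pmin(pmax((t - t_start) / dur, 0), 1)
  a <- -sign(u_plateau) * peak_decel * sin(pi * s)^p
  a[t >= t_stop] <- 0
  # Rescale away the O(dt^2) quadrature residual so the tabulated velocity
  # stops exactly at t_stop; the peak changes by the same negligible factor.
  pulse <- cumtrapz1(t, a)
  a <- a * (-u_plateau / pulse[length(pulse)])
  v <- u_plateau + cumtrapz1(t, a)
  v[t >= t_stop] <- 0
  gust_tabulated(t, v, direction = c(0, 1, 0))
}

#' Reference virtual diaspore
#'
#' A dandelion-like test body with a quadratic drag closure calibrated so its
#' terminal velocity is exactly 0.38 m/s in standard air, suspended at hover
#' by an upward inflow at the terminal velocity. The body is bottom-heavy
#' (centre of gravity at the seed, centre of buoyancy at the pappus centre:
#' `r_hat = +x`, `e = 3` mm) so buoyancy provides an upright-righting couple,
#' with rotational damping at about 0.8 of critical. Only the terminal
#' velocity is a measured property of the reference specimen; the mass
#' (0.6 mg), mean density (60 kg/m^3 over a 10 mm^3 displaced volume),
#' inertia and damping are plausible order-of-magnitude stand-ins, flagged
#' `non_paper_default` in the returned metadata.
#'
#' @param u_t Terminal velocity to calibrate to (m s^-1), default 0.38.
#' @return List with `body` ([body_spec()]), `medium` ([fluid_medium()]),
#'   `closure` (calibrated [aero_closures]), `inflow` (hover inflow vector,
#'   m s^-1), `u_t` and `metadata` (provenance flags).
#' @export
virtual_diaspore <- function(u_t = 0.38) {
  check_positive(u_t, "u_t")
  medium <- fluid_medium(density = 1.204, viscosity = 1.5e-5)
  body <- body_spec(mass = 6e-7, density = 60, length = 0.014,
                    inertia = c(2e-12, 1.5e-11, 1.5e-11),
                    e = 0.003, r_hat = c(1, 0, 0))
  closure <- calibrate_closure_to_terminal_velocity(
    u_t, body, medium, family = "quadratic", c_omega = 1.2e-10)
  list(body = body, medium = medium, closure = closure,
       inflow = c(u_t, 0, 0), u_t = u_t,
       metadata = list(
         u_t_source = "measured_reference",
         mass_kg = "non_paper_default",
         density_kg_m3 = "non_paper_default",
         inertia_kgm2 = "non_paper_default",
         eccentricity_m = "non_paper_default",
         rotational_damping_Nms = "non_paper_default"))
}

#' Demonstration gust-encounter scenario
#'
#' The full virtual experiment: the reference diaspore hovering in the tunnel
#' frame, subjected to the stop-gust of [demo_gust_profile()] (plateau
#' `-2 u_t`, braking from 0.1 s to a stop at 0.27 s with an 11 m/s^2 peak).
#' Integrated in the tunnel frame; returns the trajectory together with the
#' stem-angle history (positive clockwise) and the height change, the
#' quantities observed in the physical demonstration: an initial clockwise
#' rotation during the braking pulse, buoyancy-driven righting afterwards,
#' and a transient altitude gain that settles at or above the initial height.
#'
#' @param t_end Simulated duration (s), default 4.
#' @param dt Output sampling step (s), default 1/750 (the camera rate).
#' @param rtol,atol Integrator tolerances.
#' @return List with `trajectory`, `theta` (data frame `t`, `theta` in rad),
#'   `height_change` (data frame `t`, `dx` in m), `gust`, `gust_ratio` and
#'   the `diaspore` configuration.
#' @export
demo_scenario <- function(t_end = 4, dt = 1 / 750, rtol = 1e-8, atol = 1e-10) {
  dia <- virtual_diaspore()
  gust <- demo_gust_profile(u_plateau = -2 * dia$u_t)
  times <- seq(0, t_end, by = dt)
  traj <- simulate_trajectory(dia$body, dia$medium, dia$closure, gust,
                              frame = "tunnel", inflow = dia$inflow,
                              state0 = body_state(), times = times,
                              rtol = rtol, atol = atol)
  theta <- data.frame(t = traj$t, theta = trajectory_angle_z(traj))
  list(trajectory = traj,
       theta = theta,
       height_change = data.frame(t = traj$t, dx = traj$x - traj$x[1L]),
       gust = gust,
       gust_ratio = gust_ratio(2 * dia$u_t, dia$u_t),
       diaspore = dia)
}
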