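#' Gust profiles
#'
#' A gust profile is the time history of the far-field horizontal flow velocity
#' `u_G(t)` (equivalently, of the tunnel translation velocity in the
#' accelerating-tunnel realisation). Four kinds are supported:
#'
#' * `gust_step()` — Wagner-type step: velocity jumps by `amplitude` at `t0`
#'   (right-continuous). Its acceleration is zero everywhere, with the jump
#'   recorded as an explicit velocity impulse (see [gust_impulses()]) that
#'   integrators apply exactly.
#' * `gust_ramp()` — linear change by `dv` over `duration` starting at `t0`.
#' * `gust_sine()` — `amplitude * sin(omega * t + phase)`.
#' * `gust_tabulated()` — samples on a strictly increasing time grid; velocity
#'   is linearly interpolated (constant beyond the ends) and acceleration is
#'   computed by centred second-order finite differences on the grid.
#' * `gust_none()` — identically zero (the quiescent control).
#'
#' The gust direction defaults to +y, horizontal and orthogonal to the vertical
#' flight axis x. Non-horizontal directions are allowed but warned about, since
#' a "transverse" gust is horizontal by convention for a falling body.
#'
#' @param amplitude,v1 Step/sine amplitude (m s^-1).
#' @param t0 Onset time (s).
#' @param duration Ramp duration (s), positive.
#' @param dv Ramp velocity change (m s^-1).
#' @param omega Sine angular frequency (s^-1).
#' @param phase Sine phase (rad).
#' @param time,velocity Tabulated samples; `time` strictly increasing.
#' @param direction Gust direction unit vector; normalised internally.
#' @return An object of class `gust_profile`.
#' @name gust_profiles
NULL

new_gust <- function(kind, direction, ...) {
  direction <- unitize(direction, "direction")
  if (abs(direction[1L]) > 1e-9) {
    warning("gust direction has a vertical (x) component; transverse gusts are horizontal by convention")
  }
  structure(list(kind = kind, direction = direction, ...),
            class = c(paste0("gust_", kind), "gust_profile"))
}

#' @rdname gust_profiles
#' @export
gust_none <- function() {
  structure(list(kind = "none", direction = c(0, 1, 0)),
            class = c("gust_none", "gust_profile"))
}

#' @rdname gust_profiles
#' @export
gust_step <- function(v1, t0 = 0, direction = c(0, 1, 0)) {
  stopifnot(is.finite(v1), is.finite(t0))
  new_gust("step", direction, v1 = v1, t0 = t0)
}

#' @rdname gust_profiles
#' @export
gust_ramp <- function(t0, duration, dv, direction = c(0, 1, 0)) {
  stopifnot(is.finite(t0), is.finite(dv))
  check_positive(duration, "duration")
  new_gust("ramp", direction, t0 = t0, duration = duration, dv = dv)
}

#' @rdname gust_profiles
#' @export
gust_sine <- function(amplitude, omega, phase = 0, direction = c(0, 1, 0)) {
  stopifnot(is.finite(amplitude), is.finite(omega), is.finite(phase))
  new_gust("sine", direction, amplitude = amplitude, omega = omega, phase = phase)
}

#' @rdname gust_profiles
#' @export
gust_tabulated <- function(time, velocity, direction = c(0, 1, 0)) {
  time <- as.numeric(time); velocity <- as.numeric(velocity)
  if (length(time) < 2L || length(time) != length(velocity)) {
    stop("tabulated profile needs >= 2 (time, velocity) samples of equal length",
         call. = FALSE)
  }
  if (any(diff(time) <= 0)) stop("tabulated time grid must be strictly increasing", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(velocity))) {
    stop("tabulated samples must be finite", call. = FALSE)
  }
  # Centred second-order differences on the (possibly non-uniform) grid,
  # second-order one-sided at the ends.
  accel <- fd_derivative(time, velocity)
  new_gust("tabulated", direction, time = time, velocity = velocity, accel = accel)
}

#' @export
print.gust_profile <- function(x, ...) {
  cat(sprintf("<gust_profile> kind '%s', direction (%.3g, %.3g, %.3g)\n",
              x$kind, x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

gust_speed <- function(profile, t) {
  UseMethod("gust_speed")
}

# Left-continuous evaluation: used while integrating up to (and including) a
# discontinuity of the profile, where Runge-Kutta stages land exactly on the
# breakpoint but must still see the pre-jump values (a step's jump itself is
# applied as an impulse). Only steps (velocity) and ramps (acceleration) are
# two-sided.
gust_speed_left <- function(profile, t) {
  if (inherits(profile, "gust_step")) {
    ifelse(t > profile$t0, profile$v1, 0)
  } else {
    gust_speed(profile, t)
  }
}

gust_accel_left <- function(profile, t) {
  if (inherits(profile, "gust_ramp")) {
    inside <- t > profile$t0 & t <= profile$t0 + profile$duration
    ifelse(inside, profile$dv / profile$duration, 0)
  } else {
    gust_accel_scalar(profile, t)
  }
}

# Times at which the profile's right-hand-side contribution is non-smooth
# (integration restarts there so the Runge-Kutta scheme only ever sees a
# smooth problem). Step jumps are handled separately as impulses.
gust_breakpoints <- function(profile) {
  if (inherits(profile, "gust_ramp")) {
    c(profile$t0, profile$t0 + profile$duration)
  } else {
    numeric(0)
  }
}

#' @export
gust_speed.gust_none <- function(profile, t) rep(0, length(t))

#' @export
gust_speed.gust_step <- function(profile, t) {
  ifelse(t >= profile$t0, profile$v1, 0)
}

#' @export
gust_speed.gust_ramp <- function(profile, t) {
  s <- pmin(pmax((t - profile$t0) / profile$duration, 0), 1)
  profile$dv * s
}

#' @export
gust_speed.gust_sine <- function(profile, t) {
  profile$amplitude * sin(profile$omega * t + profile$phase)
}

#' @export
gust_speed.gust_tabulated <- function(profile, t) {
  stats::approx(profile$time, profile$velocity, xout = t, rule = 2)$y
}

gust_accel_scalar <- function(profile, t) {
  UseMethod("gust_accel_scalar")
}

#' @export
gust_accel_scalar.gust_none <- function(profile, t) rep(0, length(t))

#' @export
gust_accel_scalar.gust_step <- function(profile, t) rep(0, length(t))

#' @export
gust_accel_scalar.gust_ramp <- function(profile, t) {
  inside <- t >= profile$t0 & t < profile$t0 + profile$duration
  ifelse(inside, profile$dv / profile$duration, 0)
}

#' @export
gust_accel_scalar.gust_sine <- function(profile, t) {
  profile$amplitude * profile$omega * cos(profile$omega * t + profile$phase)
}

#' @export
gust_accel_scalar.gust_tabulated <- function(profile, t) {
  stats::approx(profile$time, profile$accel, xout = t, rule = 2)$y
}

gust_disp_scalar <- function(profile, t) {
  UseMethod("gust_disp_scalar")
}

#' @export
gust_disp_scalar.gust_none <- function(profile, t) rep(0, length(t))

#' @export
gust_disp_scalar.gust_step <- function(profile, t) {
  profile$v1 * pmax(0, t - profile$t0)
}

#' @export
gust_disp_scalar.gust_ramp <- function(profile, t) {
  t0 <- profile$t0; dt <- profile$duration; dv <- profile$dv
  s <- t - t0
  ifelse(t <= t0, 0,
         ifelse(t < t0 + dt, dv * s^2 / (2 * dt), dv * (s - dt / 2)))
}

#' @export
gust_disp_scalar.gust_sine <- function(profile, t) {
  A <- profile$amplitude; w <- profile$omega; ph <- profile$phase
  (A / w) * (cos(ph) - cos(w * t + ph))
}

#' @export
gust_disp_scalar.gust_tabulated <- function(profile, t) {
  tt <- profile$time; vv <- profile$velocity
  cum <- cumtrapz1(tt, vv)
  anti <- function(x) {
    # Antiderivative of the piecewise-linear velocity, constant extrapolation
    # beyond the grid ends.
    sapply(x, function(xi) {
      if (xi <= tt[1L]) return(vv[1L] * (xi - tt[1L]))
      n <- length(tt)
      if (xi >= tt[n]) return(cum[n] + vv[n] * (xi - tt[n]))
      i <- findInterval(xi, tt)
      h <- xi - tt[i]
      # midpoint rule is exact for the linearly interpolated velocity
      vmid <- vv[i] + (vv[i + 1L] - vv[i]) * (h / 2) / (tt[i + 1L] - tt[i])
      cum[i] + h * vmid
    })
  }
  anti(t) - anti(0)
}

#' Evaluate a gust profile
#'
#' `gust_velocity()` returns the far-field velocity vector(s) `u_G(t)`;
#' `gust_acceleration()` the acceleration vector(s) `du_G/dt` (zero for step
#' profiles, whose jumps live in [gust_impulses()]); `gust_displacement()` the
#' integral of velocity from time 0 to `t` (used to map inertial-frame
#' trajectories into the tunnel frame). All are total functions of finite `t`.
#'
#' @param profile A [gust_profiles] object.
#' @param t Time(s) (s), finite.
#' @return For scalar `t`, a numeric length-3 vector; for vector `t`, an
#'   `length(t)` x 3 matrix.
#' @export
gust_velocity <- function(profile, t) {
  stopifnot(inherits(profile, "gust_profile"), all(is.finite(t)))
  s <- gust_speed(profile, t)
  if (length(t) == 1L) s * profile$direction else outer(s, profile$direction)
}

#' @rdname gust_velocity
#' @export
gust_acceleration <- function(profile, t) {
  stopifnot(inherits(profile, "gust_profile"), all(is.finite(t)))
  a <- gust_accel_scalar(profile, t)
  if (length(t) == 1L) a * profile$direction else outer(a, profile$direction)
}

#' @rdname gust_velocity
#' @export
gust_displacement <- function(profile, t) {
  stopifnot(inherits(profile, "gust_profile"), all(is.finite(t)))
  d <- gust_disp_scalar(profile, t)
  if (length(t) == 1L) d * profile$direction else outer(d, profile$direction)
}

#' Velocity impulses of a gust profile
#'
#' Step gusts change the far-field velocity discontinuously. Rather than
#' approximating the corresponding infinite acceleration, the jump is carried
#' as an explicit impulse record `(time, dv)` that [simulate_trajectory()]
#' applies analytically: the integration restarts at the impulse time and the
#' matching velocity jumps (frame and gust-buoyancy impulse) are applied in
#' closed form. This preserves the exact cancellation of the gust response at
#' neutral buoyancy.
#'
#' @param profile A [gust_profiles] object.
#' @return A data frame with columns `time` and `dv` (signed speed jump along
#'   the profile direction); zero rows for impulse-free profiles.
#' @export
gust_impulses <- function(profile) {
  stopifnot(inherits(profile, "gust_profile"))
  if (inherits(profile, "gust_step")) {
    data.frame(time = profile$t0, dv = profile$v1)
  } else {
    data.frame(time = numeric(0), dv = numeric(0))
  }
}

#' Reduced gust acceleration
#'
#' The gust acceleration net of its specific buoyancy,
#' `(1 - rho_f/rho_b) * a_G` (componentwise for vectors). This is the body
#' force per unit mass felt in the tunnel frame; it vanishes identically at
#' neutral buoyancy, which is why a gust has no effect on a neutrally buoyant
#' body regardless of the gust strength.
#'
#' @param a_G Gust acceleration, scalar or length-3 vector (m s^-2).
#' @param rho_f Fluid density (kg m^-3), positive.
#' @param rho_b Body mean density (kg m^-3), positive.
#' @return Reduced gust acceleration, same shape as `a_G`.
#' @export
reduced_gust_acceleration <- function(a_G, rho_f, rho_b) {
  check_positive(rho_f, "rho_f")
  check_positive(rho_b, "rho_b")
  stopifnot(is.numeric(a_G), all(is.finite(a_G)))
  (1 - rho_f / rho_b) * a_G
}

#' Effective gravity under a gust
#'
#' In the tunnel frame a gust acts as a temporary modification of gravity: the
#' effective gravitational acceleration is the vector difference `g - du_G/dt`.
#' For a horizontal gust acceleration orthogonal to `g` its magnitude is
#' `sqrt(g^2 + a_G^2)` and its direction tilts by `atan(a_G / g)` away from the
#' gust direction.
#'
#' @param g_vec Gravity vector (m s^-2), non-zero.
#' @param a_G_vec Gust acceleration vector (m s^-2).
#' @return An object of class `effective_gravity`: list with `vector`,
#'   `magnitude` and `tilt` (rad, angle from `g_vec`).
#' @examples
#' effective_gravity(c(-9.81, 0, 0), c(0, 11, 0))
#' @export
effective_gravity <- function(g_vec, a_G_vec = c(0, 0, 0)) {
  g_vec <- as_vec3(g_vec, "g_vec")
  a_G_vec <- as_vec3(a_G_vec, "a_G_vec")
  if (norm3(g_vec) <= 0) stop("'g_vec' must have positive magnitude", call. = FALSE)
  v <- g_vec - a_G_vec
  tilt <- atan2(norm3(cross3(g_vec, v)), sum(g_vec * v))
  structure(list(vector = v, magnitude = norm3(v), tilt = tilt),
            class = "effective_gravity")
}

#' @export
print.effective_gravity <- function(x, ...) {
  cat(sprintf("<effective_gravity> |g_eff| %.4g m/s^2, tilt %.4g rad\n",
              x$magnitude, x$tilt))
  invisible(x)
}

#' Gust ratio
#'
#' The ratio of the maximum gust velocity to the flyer's characteristic speed
#' (terminal velocity for a falling body). Ratios of order one or larger mark
#' large-amplitude gusts outside the reach of linearised gust models.
#'
#' @param u_gust_max Maximum gust speed (m s^-1); sign is ignored.
#' @param u_flyer Flyer speed (m s^-1), positive.
#' @return Dimensionless gust ratio.
#' @examples
#' gust_ratio(0.8, 0.38)
#' @export
gust_ratio <- function(u_gust_max, u_flyer) {
  stopifnot(is.numeric(u_gust_max), length(u_gust_max) == 1L, is.finite(u_gust_max))
  if (!is.numeric(u_flyer) || length(u_flyer) != 1L || !is.finite(u_flyer) || u_flyer <= 0) {
    stop("'u_flyer' must be a single positive finite number", call. = FALSE)
  }
  abs(u_gust_max) / u_flyer
}
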