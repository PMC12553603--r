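#' Body state
#'
#' Instantaneous rigid-body state: position and velocity of the centre of
#' gravity, orientation as a unit quaternion (body to frame), and body-frame
#' angular velocity. States are interpreted in the frame the trajectory is
#' integrated in (inertial Earth frame or non-inertial tunnel frame).
#'
#' @param position Position (m), length 3.
#' @param velocity Velocity (m s^-1), length 3.
#' @param quaternion Orientation unit quaternion `c(qw, qx, qy, qz)`;
#'   normalised internally.
#' @param omega Body-frame angular velocity (rad s^-1), length 3.
#' @return An object of class `body_state`.
#' @export
body_state <- function(position = c(0, 0, 0), velocity = c(0, 0, 0),
                       quaternion = c(1, 0, 0, 0), omega = c(0, 0, 0)) {
  position <- as_vec3(position, "position")
  velocity <- as_vec3(velocity, "velocity")
  omega <- as_vec3(omega, "omega")
  quaternion <- as.numeric(quaternion)
  if (length(quaternion) != 4L || any(!is.finite(quaternion))) {
    stop("'quaternion' must be a finite numeric vector of length 4", call. = FALSE)
  }
  quaternion <- quat_normalize(quaternion)
  structure(list(position = position, velocity = velocity,
                 quaternion = quaternion, omega = omega),
            class = "body_state")
}

state_to_y <- function(state) {
  c(state$position, state$velocity, state$quaternion, state$omega)
}

y_to_state <- function(y) {
  body_state(position = y[1:3], velocity = y[4:6],
             quaternion = y[7:10], omega = y[11:13])
}

#' Map kinematics from a moving frame to the inertial frame
#'
#' General transformation between a translating and rotating frame and an
#' inertial frame: `u = u_G + u' + omega_G x x'` and
#' `a = a_G + a' + 2 omega_G x u' + alpha_G x x' + omega_G x (omega_G x x')`
#' (Coriolis, Euler and centripetal terms). For a purely translating tunnel
#' frame (`omega_G = 0`) these reduce to `u = u_G + u'` and `a = a_G + a'`.
#'
#' @param x_p,u_p,a_p Position, velocity and acceleration in the moving frame.
#' @param u_G,a_G Frame translation velocity and acceleration.
#' @param omega_G,alpha_G Frame angular velocity and acceleration.
#' @return List with `velocity` and `acceleration` in the inertial frame.
#' @export
transform_kinematics <- function(x_p, u_p, a_p,
                                 u_G = c(0, 0, 0), omega_G = c(0, 0, 0),
                                 a_G = c(0, 0, 0), alpha_G = c(0, 0, 0)) {
  x_p <- as_vec3(x_p, "x_p"); u_p <- as_vec3(u_p, "u_p"); a_p <- as_vec3(a_p, "a_p")
  u_G <- as_vec3(u_G, "u_G"); omega_G <- as_vec3(omega_G, "omega_G")
  a_G <- as_vec3(a_G, "a_G"); alpha_G <- as_vec3(alpha_G, "alpha_G")
  list(
    velocity = u_G + u_p + cross3(omega_G, x_p),
    acceleration = a_G + a_p + 2 * cross3(omega_G, u_p) +
      cross3(alpha_G, x_p) + cross3(omega_G, cross3(omega_G, x_p))
  )
}

# Shared right-hand side. `frame` is "tunnel" or "inertial".
#
# Tunnel frame (translating with the gust, zero angular velocity): the ambient
# flow is the steady inflow; the gust enters only as the reduced body force
# -(1 - rho_f/rho_b) a_G per unit mass and through the buoyancy-type torque.
# Inertial frame: the ambient fluid itself moves at inflow + u_G(t) and the
# accelerating fluid carries a uniform pressure gradient whose resultant on
# the displaced volume is +rho_f V a_G at the centre of buoyancy.
#
# In both frames all buoyancy-type forces, -rho_f V (g - a_G), act at the
# centre of buoyancy (offset e r_hat from the centre of gravity), while
# gravity and the fictitious force act at the centre of gravity: only the
# buoyancy-type resultant produces a torque about the centre of gravity.
# `t_left_limit`: time at or beyond which the gust profile is evaluated by its
# left limit. Profiles are right-continuous, so inside a segment (a, b) the
# plain evaluation is correct; Runge-Kutta stages landing exactly on a
# breakpoint b must instead see the pre-break values.
rhs_core <- function(t, y, body, medium, closure, gust, inflow, frame,
                     t_left_limit = Inf) {
  u <- y[4:6]
  q <- quat_normalize(y[7:10])
  w <- y[11:13]
  k <- medium$density / body$density
  g_vec <- medium$gravity
  use_left <- t >= t_left_limit
  a_G <- if (use_left) gust_accel_left(gust, t) * gust$direction
         else gust_acceleration(gust, t)

  if (frame == "tunnel") {
    u_rel <- u - inflow
    a_buoy_grav <- (1 - k) * (g_vec - a_G)
  } else {
    u_G <- if (use_left) gust_speed_left(gust, t) * gust$direction
           else gust_velocity(gust, t)
    u_rel <- u - inflow - u_G
    a_buoy_grav <- (1 - k) * g_vec + k * a_G
  }

  loads <- closure$evaluate(u_rel, q, w, medium, body)
  a_lin <- loads$force / body$mass + a_buoy_grav

  tau_b <- loads$torque
  if (body$e > 0) {
    R <- quat_rotmat(q)
    r_w <- as.numeric(R %*% body$r_hat)
    tau_w <- cross3(body$e * r_w, -medium$density * body$volume * (g_vec - a_G))
    tau_b <- tau_b + as.numeric(crossprod(R, tau_w))
  }
  w_dot <- as.numeric(body$inertia_inv %*% (tau_b - cross3(w, as.numeric(body$inertia %*% w))))

  list(lin = a_lin, ang = w_dot, q = q, u = u, w = w)
}

#' Frame-specific accelerations (right-hand sides)
#'
#' Evaluate the linear and angular accelerations of the rigid-body equations
#' at a given state, either in the non-inertial tunnel frame
#' (`rhs_tunnel_frame()`: gust as a reduced body force
#' `-(1 - rho_f/rho_b) du_G/dt` plus a gust-buoyancy torque) or in the inertial
#' Earth frame (`rhs_inertial_frame()`: moving ambient fluid plus the
#' pressure-gradient force `+rho_f V du_G/dt` at the centre of buoyancy). With
#' no gust the two coincide. All buoyancy-type forces act at the centre of
#' buoyancy in the instantaneous effective gravity `g - du_G/dt`.
#'
#' @param state A [body_state()].
#' @param t Time (s).
#' @param body A [body_spec()].
#' @param medium A [fluid_medium()].
#' @param closure An [aero_closures] object.
#' @param gust A [gust_profiles] object.
#' @param inflow Tunnel inflow velocity vector (m s^-1); a scalar is taken as
#'   the upward (+x) component.
#' @return List with `linear` (m s^-2) and `angular` (rad s^-2, body frame)
#'   accelerations.
#' @export
rhs_tunnel_frame <- function(state, t, body, medium, closure, gust = gust_none(),
                             inflow = c(0, 0, 0)) {
  inflow <- as_vec3(inflow, "inflow")
  r <- rhs_core(t, state_to_y(state), body, medium, closure, gust, inflow, "tunnel")
  list(linear = r$lin, angular = r$ang)
}

#' @rdname rhs_tunnel_frame
#' @export
rhs_inertial_frame <- function(state, t, body, medium, closure, gust = gust_none(),
                               inflow = c(0, 0, 0)) {
  inflow <- as_vec3(inflow, "inflow")
  r <- rhs_core(t, state_to_y(state), body, medium, closure, gust, inflow, "inertial")
  list(linear = r$lin, angular = r$ang)
}

# Velocity and angular-velocity jumps produced by a gust velocity impulse dv
# (vector). The impulsive ambient pressure field delivers the linear impulse
# rho_f V dv at the centre of buoyancy, so the body's inertial velocity jumps
# by (rho_f/rho_b) dv; in the tunnel frame the frame itself jumps by dv, so
# the relative velocity jumps by -(1 - rho_f/rho_b) dv. The matching angular
# impulse about the centre of gravity is e r_w x (rho_f V dv).
impulse_jump <- function(y, dv_vec, body, medium, frame) {
  k <- medium$density / body$density
  if (frame == "tunnel") {
    y[4:6] <- y[4:6] - (1 - k) * dv_vec
  } else {
    y[4:6] <- y[4:6] + k * dv_vec
  }
  if (body$e > 0) {
    q <- quat_normalize(y[7:10])
    R <- quat_rotmat(q)
    r_w <- as.numeric(R %*% body$r_hat)
    L_w <- cross3(body$e * r_w, medium$density * body$volume * dv_vec)
    y[11:13] <- y[11:13] + as.numeric(body$inertia_inv %*% crossprod(R, L_w))
  }
  y
}

#' Integrate a rigid-body trajectory
#'
#' Integrates the equations of motion with an adaptive Dormand-Prince
#' Runge-Kutta 4(5) scheme (deSolve), in either the tunnel or the inertial
#' frame. Step-gust velocity jumps are applied analytically: the integration
#' restarts at each impulse time and the exact velocity/angular-velocity jumps
#' are added, so the neutral-buoyancy cancellation holds to the last bit. The
#' orientation quaternion is renormalised at every evaluation and on output.
#'
#' @inheritParams rhs_tunnel_frame
#' @param frame `"tunnel"` or `"inertial"`.
#' @param state0 Initial [body_state()] (in `frame`).
#' @param times Strictly increasing output times (s).
#' @param rtol,atol Relative/absolute integration tolerances (defaults 1e-8
#'   and 1e-10).
#' @param breakpoints Extra times at which to restart the integrator (used to
#'   give a control run the same segmentation as an impulse-carrying run).
#' @return An object of class `trajectory`: a data frame with columns `t`,
#'   `x`, `y`, `z`, `u`, `v`, `w`, `qw`, `qx`, `qy`, `qz`, `wx`, `wy`, `wz`
#'   and attributes recording the frame and configuration.
#' @examples
#' air <- fluid_medium()
#' b <- body_spec(1e-6, 600, 0.01, inertia = diag(1e-11, 3))
#' cl <- calibrate_closure_to_terminal_velocity(0.38, b, air, "linear")
#' tr <- simulate_trajectory(b, air, cl, times = seq(0, 1, 0.01))
#' @export
simulate_trajectory <- function(body, medium, closure, gust = gust_none(),
                                frame = c("tunnel", "inertial"),
                                inflow = c(0, 0, 0),
                                state0 = body_state(),
                                times = seq(0, 5, by = 0.01),
                                rtol = 1e-8, atol = 1e-10,
                                breakpoints = numeric(0)) {
  frame <- match.arg(frame)
  stopifnot(inherits(body, "body_spec"), inherits(medium, "fluid_medium"),
            inherits(closure, "aero_closure"), inherits(gust, "gust_profile"),
            inherits(state0, "body_state"))
  inflow <- as_vec3(inflow, "inflow")
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing with length >= 2", call. = FALSE)
  }

  # Snap restart times onto output times they all but coincide with, so the
  # time grid never contains near-duplicate entries (which would drive the
  # step-size cap towards zero).
  snap_to_times <- function(v) {
    vapply(v, function(vi) {
      j <- which.min(abs(times - vi))
      if (abs(times[j] - vi) < 1e-9 * (1 + abs(vi))) times[j] else vi
    }, numeric(1))
  }
  imp <- gust_impulses(gust)
  t0 <- times[1L]; t1 <- times[length(times)]
  imp$time <- snap_to_times(imp$time)
  imp <- imp[imp$time > t0 & imp$time < t1, , drop = FALSE]
  brk <- snap_to_times(c(imp$time, gust_breakpoints(gust), breakpoints))
  brk <- sort(unique(brk[brk > t0 & brk < t1]))
  bounds <- c(t0, brk, t1)

  y <- state_to_y(state0)
  rows <- matrix(NA_real_, nrow = length(times), ncol = 13L)
  for (i in seq_len(length(bounds) - 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    t_left <- if (b %in% brk) b else Inf
    deriv <- function(t, y, parms) {
      r <- rhs_core(t, y, body, medium, closure, gust, inflow, frame,
                    t_left_limit = t_left)
      list(c(r$u, r$lin, quat_deriv(r$q, r$w), r$ang))
    }
    sel <- times >= a & times <= b
    seg_times <- sort(unique(c(a, times[sel], b)))
    # Cap the internal step at the output spacing: the embedded error
    # estimator only controls the endpoint of a step, and dense output inside
    # an over-long step (e.g. straight after a forcing onset) would otherwise
    # dominate the sampled error.
    sol <- deSolve::ode(y = y, times = seg_times, func = deriv, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol,
                        hmax = min(diff(seg_times)), maxsteps = 1e5)
    if (attr(sol, "istate")[1L] < 0) {
      stop(sprintf("integration failed in [%g, %g] (possible stiffness); last state: %s",
                   a, b, paste(signif(y, 6), collapse = ", ")), call. = FALSE)
    }
    m <- unname(sol[, -1L, drop = FALSE])
    keep <- match(times[sel], seg_times)
    rows[which(sel), ] <- m[keep, , drop = FALSE]
    y <- m[nrow(m), ]
    y[7:10] <- quat_normalize(y[7:10])
    if (b %in% imp$time) {
      dv <- imp$dv[match(b, imp$time)]
      y <- impulse_jump(y, dv * gust$direction, body, medium, frame)
      # The state at an impulse time is right-continuous (post-jump).
      at_b <- which(times == b)
      if (length(at_b)) rows[at_b, ] <- y
    }
  }
  qn <- sqrt(rowSums(rows[, 7:10, drop = FALSE]^2))
  rows[, 7:10] <- rows[, 7:10] / qn

  out <- as.data.frame(rows)
  names(out) <- c("x", "y", "z", "u", "v", "w",
                  "qw", "qx", "qy", "qz", "wx", "wy", "wz")
  out <- cbind(t = times, out)
  structure(out,
            class = c("trajectory", "data.frame"),
            frame = frame, body = body, medium = medium, closure = closure,
            gust = gust, inflow = inflow, rtol = rtol, atol = atol)
}

#' Per-sample force and torque breakdown of a trajectory
#'
#' Re-evaluates the dynamical terms at every saved state: closure force,
#' gravity-plus-buoyancy specific force, gust body force and the buoyancy
#' torque, in the trajectory's frame. Useful as a diagnostic of which term
#' drives each phase of a gust response.
#'
#' @param traj A [simulate_trajectory()] result.
#' @return Data frame with one row per sample: closure force components
#'   (`F_*`, N), gravity/buoyancy acceleration (`ab_*`, m s^-2), gust
#'   acceleration (`aG_*`, m s^-2) and body-frame torque (`tau_*`, N m).
#' @export
trajectory_forces <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  body <- attr(traj, "body"); medium <- attr(traj, "medium")
  closure <- attr(traj, "closure"); gust <- attr(traj, "gust")
  inflow <- attr(traj, "inflow"); frame <- attr(traj, "frame")
  n <- nrow(traj)
  out <- matrix(NA_real_, n, 12L)
  for (i in seq_len(n)) {
    y <- as.numeric(traj[i, 2:14])
    t <- traj$t[i]
    r <- rhs_core(t, y, body, medium, closure, gust, inflow, frame)
    loads <- closure$evaluate(
      if (frame == "tunnel") y[4:6] - inflow else y[4:6] - inflow - gust_velocity(gust, t),
      r$q, y[11:13], medium, body)
    k <- medium$density / body$density
    ab <- (1 - k) * medium$gravity
    aG <- if (frame == "tunnel") -(1 - k) * gust_acceleration(gust, t)
          else k * gust_acceleration(gust, t)
    tau_b <- loads$torque
    if (body$e > 0) {
      R <- quat_rotmat(r$q)
      r_w <- as.numeric(R %*% body$r_hat)
      tau_w <- cross3(body$e * r_w,
                      -medium$density * body$volume * (medium$gravity - gust_acceleration(gust, t)))
      tau_b <- tau_b + as.numeric(crossprod(R, tau_w))
    }
    out[i, ] <- c(loads$force, ab, aG, tau_b)
  }
  out <- as.data.frame(out)
  names(out) <- c("F_x", "F_y", "F_z", "ab_x", "ab_y", "ab_z",
                  "aG_x", "aG_y", "aG_z", "tau_x", "tau_y", "tau_z")
  cbind(t = traj$t, out)
}

#' Planar rotation angle of a trajectory
#'
#' Signed rotation angle about the +z axis of each saved orientation, in the
#' convention that positive angles are clockwise in the x-up / y-right viewing
#' plane (the stem-angle convention for a falling diaspore).
#'
#' @param traj A [simulate_trajectory()] result.
#' @return Numeric vector of angles (rad), one per sample.
#' @export
trajectory_angle_z <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  vapply(seq_len(nrow(traj)),
         function(i) quat_angle_z(as.numeric(traj[i, c("qw", "qx", "qy", "qz")])),
         numeric(1))
}

#' Mechanical energy along a trajectory
#'
#' `E = 1/2 m |u|^2 - m (1 - rho_f/rho_b) g . x`: kinetic plus reduced-gravity
#' potential energy. Conserved for a ballistic (closure-free, gust-free) fall;
#' used as an integrator sanity check.
#'
#' @param traj A [simulate_trajectory()] result.
#' @return Numeric vector (J), one value per sample.
#' @export
mechanical_energy <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  body <- attr(traj, "body"); medium <- attr(traj, "medium")
  k <- medium$density / body$density
  g <- medium$gravity
  kin <- 0.5 * body$mass * (traj$u^2 + traj$v^2 + traj$w^2)
  pot <- -body$mass * (1 - k) * (g[1] * traj$x + g[2] * traj$y + g[3] * traj$z)
  kin + pot
}

#' Map an inertial-frame trajectory into the tunnel frame
#'
#' Subtracts the gust displacement from positions and the gust velocity from
#' velocities (orientation and angular velocity are unchanged: the tunnel
#' frame does not rotate). The frames are taken to coincide at the
#' trajectory's first sample time.
#'
#' @param traj An inertial-frame [simulate_trajectory()] result.
#' @param gust The [gust_profiles] object describing the frame motion.
#' @return A `trajectory` in tunnel-frame coordinates.
#' @export
map_to_tunnel_frame <- function(traj, gust) {
  stopifnot(inherits(traj, "trajectory"), inherits(gust, "gust_profile"))
  if (!identical(attr(traj, "frame"), "inertial")) {
    stop("'traj' must be an inertial-frame trajectory", call. = FALSE)
  }
  disp <- gust_displacement(gust, traj$t)
  disp0 <- gust_displacement(gust, traj$t[1L])
  disp <- sweep(disp, 2L, disp0)
  vel <- gust_velocity(gust, traj$t)
  out <- traj
  out$x <- traj$x - disp[, 1]; out$y <- traj$y - disp[, 2]; out$z <- traj$z - disp[, 3]
  out$u <- traj$u - vel[, 1]; out$v <- traj$v - vel[, 2]; out$w <- traj$w - vel[, 3]
  attr(out, "frame") <- "tunnel"
  out
}

#' Frame-equivalence deviation between trajectories
#'
#' Maps an inertial-frame trajectory into the tunnel frame and returns the
#' maximum absolute deviation from a tunnel-frame trajectory of the same run
#' (position, velocity, quaternion and angular velocity). By the gust
#' equivalence theorem the two formulations describe the same motion, so the
#' deviation is pure integration error and shrinks at the integrator's
#' convergence order as the tolerance tightens.
#'
#' @param traj_inertial Inertial-frame trajectory.
#' @param traj_tunnel Tunnel-frame trajectory on the same time grid.
#' @param gust The shared [gust_profiles] object.
#' @return List with `position` (m), `velocity` (m s^-1), `quaternion` and
#'   `omega` (rad s^-1) maximum absolute deviations.
#' @export
equivalence_deviation <- function(traj_inertial, traj_tunnel, gust) {
  stopifnot(inherits(traj_inertial, "trajectory"), inherits(traj_tunnel, "trajectory"))
  if (!identical(attr(traj_tunnel, "frame"), "tunnel")) {
    stop("'traj_tunnel' must be a tunnel-frame trajectory", call. = FALSE)
  }
  if (!isTRUE(all.equal(traj_inertial$t, traj_tunnel$t, tolerance = 1e-12))) {
    stop("trajectories must share the same time grid", call. = FALSE)
  }
  mapped <- map_to_tunnel_frame(traj_inertial, gust)
  dpos <- max(abs(cbind(mapped$x - traj_tunnel$x, mapped$y - traj_tunnel$y,
                        mapped$z - traj_tunnel$z)))
  dvel <- max(abs(cbind(mapped$u - traj_tunnel$u, mapped$v - traj_tunnel$v,
                        mapped$w - traj_tunnel$w)))
  dq <- max(abs(as.matrix(mapped[, c("qw", "qx", "qy", "qz")]) -
                as.matrix(traj_tunnel[, c("qw", "qx", "qy", "qz")])))
  dw <- max(abs(as.matrix(mapped[, c("wx", "wy", "wz")]) -
                as.matrix(traj_tunnel[, c("wx", "wy", "wz")])))
  list(position = dpos, velocity = dvel, quaternion = dq, omega = dw)
}

#' Run the same gust encounter in both frames
#'
#' Convenience wrapper: given a tunnel-frame initial state, integrates the
#' motion in the tunnel frame and in the inertial frame (with consistently
#' transformed initial conditions, frames coinciding at the first output
#' time) and returns both trajectories with their equivalence deviation.
#'
#' @inheritParams simulate_trajectory
#' @param state0 Initial [body_state()] in the tunnel frame.
#' @return List with `tunnel`, `inertial` (trajectories) and `deviation`
#'   (see [equivalence_deviation()]).
#' @export
run_frame_pair <- function(body, medium, closure, gust = gust_none(),
                           inflow = c(0, 0, 0), state0 = body_state(),
                           times = seq(0, 5, by = 0.01),
                           rtol = 1e-8, atol = 1e-10) {
  inflow <- as_vec3(inflow, "inflow")
  tr_t <- simulate_trajectory(body, medium, closure, gust, "tunnel", inflow,
                              state0, times, rtol, atol)
  uG0 <- gust_velocity(gust, times[1L])
  state0_i <- body_state(position = state0$position,
                         velocity = state0$velocity + uG0,
                         quaternion = state0$quaternion, omega = state0$omega)
  tr_i <- simulate_trajectory(body, medium, closure, gust, "inertial", inflow,
                              state0_i, times, rtol, atol)
  list(tunnel = tr_t, inertial = tr_i,
       deviation = equivalence_deviation(tr_i, tr_t, gust))
}
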