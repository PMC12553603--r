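test_that("kinematic frame transform reproduces Coriolis, Euler and centripetal terms", {
  # identity when the frame does not move
  out <- transform_kinematics(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(out$velocity, c(4, 5, 6))
  expect_equal(out$acceleration, c(7, 8, 9))
  # Coriolis: omega = z, u' = x -> 2 omega x u' = 2 y
  out <- transform_kinematics(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0),
                              omega_G = c(0, 0, 1))
  expect_equal(out$acceleration, c(0, 2, 0))
  # pure translation: accelerations add
  out <- transform_kinematics(c(0.3, 0, 0), c(0, 0.2, 0), c(0, 0.1, 0),
                              u_G = c(0, -0.8, 0), a_G = c(0, 11, 0))
  expect_equal(out$velocity, c(0, -0.6, 0))
  expect_equal(out$acceleration, c(0, 11.1, 0))
  # centripetal + Euler on a rotating frame
  out <- transform_kinematics(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0),
                              omega_G = c(0, 0, 2), alpha_G = c(0, 0, 3))
  expect_equal(out$acceleration, c(-4, 3, 0))
})

test_that("ballistic fall matches the reduced-gravity closed form", {
  body <- test_body_air(e = 0)
  medium <- std_air()
  g_star <- reduced_gravity(9.81, 1.204, 600)
  tr <- simulate_trajectory(body, medium, zero_closure(), times = seq(0, 1, 0.01))
  expect_equal(tr$x, -0.5 * g_star * tr$t^2, tolerance = 1e-8)
  expect_equal(tr$u, -g_star * tr$t, tolerance = 1e-8)
  expect_equal(max(abs(tr$y)), 0)
})

test_that("linear drag relaxes to terminal velocity with time constant m/c", {
  body <- test_body_air(e = 0)
  medium <- std_air()
  cl <- calibrate_closure_to_terminal_velocity(0.38, body, medium, "linear")
  tau <- body$mass / cl$params$c
  tr <- simulate_trajectory(body, medium, cl, times = seq(0, 1, 0.01))
  exact <- -0.38 * (1 - exp(-tr$t / tau))
  expect_lt(max(abs(tr$u - exact)) / 0.38, 1e-7)
})

test_that("hover equilibrium is a fixed point of the tunnel-frame dynamics", {
  body <- test_body_air(e = 0)
  medium <- std_air()
  cl <- calibrate_closure_to_terminal_velocity(0.38, body, medium, "quadratic")
  tr <- simulate_trajectory(body, medium, cl, inflow = c(0.38, 0, 0),
                            times = seq(0, 10, 0.1))
  expect_lt(max(abs(tr$x)), 1e-10)
  expect_lt(max(abs(as.matrix(tr[, c("u", "v", "w")]))), 1e-10)
  r <- rhs_tunnel_frame(body_state(), 0, body, medium, cl, inflow = c(0.38, 0, 0))
  expect_lt(max(abs(r$linear)), 1e-10)
  expect_equal(r$angular, c(0, 0, 0))
})

test_that("a step gust leaves the closed-form relative-velocity decay in both frames", {
  body <- test_body_air(e = 0)
  medium <- std_air()
  cl <- calibrate_closure_to_terminal_velocity(0.38, body, medium, "linear")
  tau <- body$mass / cl$params$c
  k <- 1.204 / 600
  v1 <- 0.76
  g <- gust_step(v1, t0 = 0.1)
  pr <- run_frame_pair(body, medium, cl, g, inflow = c(0.38, 0, 0),
                       times = seq(0, 2, 0.01))
  sel <- pr$tunnel$t >= 0.1
  decay <- -(1 - k) * v1 * exp(-(pr$tunnel$t[sel] - 0.1) / tau)
  # tunnel frame: horizontal velocity relative to the (stationary) tunnel air
  expect_lt(max(abs(pr$tunnel$v[sel] - decay)) / v1, 1e-7)
  # inertial frame: same decay for velocity relative to the moving fluid
  rel_i <- pr$inertial$v[sel] - v1
  expect_lt(max(abs(rel_i - decay)) / v1, 1e-7)
})

test_that("tunnel- and inertial-frame trajectories agree after frame mapping", {
  eq <- equivalence_cases()
  # spot-check two contrasting corners here (the full matrix runs in the
  # acceptance suite): quadratic/step in air, linear/ramp in water
  for (pick in list(c("quadratic", "step", "air"), c("linear", "ramp", "water"))) {
    setup <- equivalence_setup(pick[1], pick[3])
    pr <- run_frame_pair(setup$body, setup$medium, setup$closure,
                         eq$gusts[[pick[2]]], inflow = c(0, 0, 0),
                         times = seq(0, 3, 0.05))
    expect_lt(pr$deviation$position, 1e-7)
    expect_lt(pr$deviation$velocity, 1e-7)
  }
})

test_that("equivalence deviation shrinks with the integrator tolerance", {
  setup <- equivalence_setup("quadratic", "air")
  g <- gust_sine(0.3, omega = 4)
  dev <- sapply(c(1e-6, 1e-9), function(rt) {
    pr <- run_frame_pair(setup$body, setup$medium, setup$closure, g,
                         times = seq(0, 2, 0.05), rtol = rt, atol = rt * 1e-2)
    max(pr$deviation$position, pr$deviation$velocity)
  })
  expect_lt(dev[2], dev[1] / 10)
})

test_that("mismatched gusts between frames are detected as a deviation", {
  setup <- equivalence_setup("linear", "air")
  g1 <- gust_step(0.4, 0.5)
  g2 <- gust_step(0.2, 0.5)
  t1 <- simulate_trajectory(setup$body, setup$medium, setup$closure, g1,
                            "tunnel", times = seq(0, 2, 0.05))
  t2 <- simulate_trajectory(setup$body, setup$medium, setup$closure, g2,
                            "inertial", times = seq(0, 2, 0.05))
  dev <- equivalence_deviation(t2, t1, g2)
  expect_gt(dev$velocity, 0.01)
})

test_that("gusts have no effect at neutral buoyancy (bitwise null)", {
  medium <- fluid_medium(density = 1.2, viscosity = 1.5e-5)
  body <- body_spec(mass = 1e-6, density = 1.2, length = 0.01,
                    inertia = diag(1e-11, 3))  # homogeneous: e = 0
  cl <- quadratic_drag_closure(C_D = 1, A = 1e-4, c_omega = 1e-10)
  s0 <- body_state(velocity = c(0, 0.1, 0), omega = c(0, 0, 0.5))
  times <- seq(0, 2, 0.01)
  for (g in list(gust_step(0.76, 0.5), gust_ramp(0.5, 0.2, 0.6),
                 gust_sine(0.5, 5))) {
    gusted <- simulate_trajectory(body, medium, cl, g, "tunnel",
                                  state0 = s0, times = times)
    # the ungusted control is integrated with the same restart points, so a
    # bitwise comparison is meaningful
    quiet <- simulate_trajectory(body, medium, cl, gust_none(), "tunnel",
                                 state0 = s0, times = times,
                                 breakpoints = c(gust_impulses(g)$time,
                                                 if (inherits(g, "gust_ramp")) c(0.5, 0.7)))
    expect_identical(as.matrix(as.data.frame(gusted)),
                     as.matrix(as.data.frame(quiet)))
  }
})

test_that("horizontal gust response is linear in amplitude and in (1 - rho_f/rho_b)", {
  medium <- std_air()
  times <- seq(0, 2, 0.02)
  resp <- function(density, amp) {
    body <- body_spec(mass = 1e-6, density = density, length = 0.01,
                      inertia = diag(1e-11, 3))
    cl <- linear_drag_closure(c = 2e-5)
    simulate_trajectory(body, medium, cl, gust_ramp(0.2, 0.3, amp), "tunnel",
                        times = times)$v
  }
  v1 <- resp(600, 0.1); v2 <- resp(600, 0.2); v4 <- resp(600, 0.4)
  expect_equal(v2, 2 * v1, tolerance = 1e-6)
  expect_equal(v4, 4 * v1, tolerance = 1e-6)
  # same mass and drag, double the buoyancy factor via the density ratio
  k600 <- 1.204 / 600
  d2 <- 1.204 / (2 * k600)  # body density with twice the density ratio
  vk <- resp(d2, 0.1)
  expect_equal(vk / (1 - 2 * k600), v1 / (1 - k600), tolerance = 1e-5)
})

test_that("a perturbed bottom-heavy body rights itself after the gust ends", {
  dia <- virtual_diaspore()
  s0 <- body_state(quaternion = c(cos(0.15), 0, 0, sin(0.15)))  # ~0.3 rad tilt
  tr <- simulate_trajectory(dia$body, dia$medium, dia$closure, gust_none(),
                            "tunnel", dia$inflow, s0, times = seq(0, 4, 0.02))
  th <- trajectory_angle_z(tr)
  expect_equal(th[1], 0.3, tolerance = 1e-6)
  expect_lt(max(abs(th[tr$t >= 3])), 0.01)
})

test_that("mechanical energy is conserved in ballistic reduced-gravity fall", {
  body <- test_body_air(e = 0)
  tr <- simulate_trajectory(body, std_air(), zero_closure(),
                            state0 = body_state(velocity = c(0.3, 0.2, 0)),
                            times = seq(0, 2, 0.02))
  E <- mechanical_energy(tr)
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-8)
})

test_that("trajectory diagnostics decompose the driving terms", {
  dia <- virtual_diaspore()
  g <- gust_ramp(0.1, 0.17, 0.76)
  tr <- simulate_trajectory(dia$body, dia$medium, dia$closure, g, "tunnel",
                            dia$inflow, times = seq(0, 0.5, 0.01))
  fr <- trajectory_forces(tr)
  # before the gust: hover, zero closure force imbalance and zero gust term
  expect_equal(fr$aG_y[fr$t < 0.1], rep(0, sum(fr$t < 0.1)))
  # during the ramp the reduced gust force opposes the gust direction
  mid <- fr$t > 0.12 & fr$t < 0.25
  expect_true(all(fr$aG_y[mid] < 0))
  k <- dia$medium$density / dia$body$density
  expect_equal(max(abs(fr$aG_y[mid] + (1 - k) * 0.76 / 0.17)), 0, tolerance = 1e-9)
})
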