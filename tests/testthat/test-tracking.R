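test_that("pixel-to-metre conversion uses the image resolution", {
  tr <- track_series(x_px = c(0, 1, 100), y_px = c(0, 0, 0),
                     frame_rate = 750, resolution_mm_px = 0.0805)
  pos <- pixels_to_metres(tr)
  expect_equal(pos$x, c(0, 0.0805e-3, 8.05e-3))
  expect_equal(pos$t, c(0, 1, 2) / 750)
  tr1 <- track_series(1, 1, frame_rate = 100, resolution_mm_px = 1)
  expect_equal(pixels_to_metres(tr1)$x, 0.001)
})

test_that("centred moving average preserves constants, lines and length", {
  expect_equal(moving_average(rep(3, 25)), rep(3, 25))
  # a linear ramp is invariant at interior points (symmetric window on a line)
  x <- seq_len(40)
  sm <- moving_average(x, 11)
  expect_equal(sm[6:35], as.numeric(x[6:35]))
  expect_length(sm, 40)
  # a balanced alternating series averages to zero over an even window
  alt <- rep(c(1, -1), 20)
  expect_equal(moving_average(alt, 10)[10:30], rep(0, 21))
  expect_error(moving_average(1:5, 6), "exceeds")
})

test_that("differentiation is exact for quadratics including the ends", {
  r <- 200
  t <- seq(0, 1, by = 1 / r)
  pos <- 3 * t^2 - 2 * t + 1
  d <- differentiate(pos, r)
  expect_equal(d, 6 * t - 2, tolerance = 1e-9)
  expect_equal(differentiate(rep(5, 10), r), rep(0, 10))
  expect_error(differentiate(c(1, 2), r), "3 samples")
})

test_that("differentiate inverts cumulative trapezoidal integration on smooth series", {
  r <- 500
  t <- seq(0, 1, by = 1 / r)
  v <- sin(2 * pi * t)
  pos <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2)) / r
  err <- max(abs(differentiate(pos, r) - v))
  expect_lt(err, (2 * pi / r)^2)
})

test_that("the tunnel gust profile is recovered from a synthetic marker track", {
  g <- demo_gust_profile()
  # noiseless: plateau exact to discretisation error
  tr0 <- synth_tunnel_track(g, duration = 0.4, noise_px = 0, seed = 1)
  p0 <- tunnel_gust_profile_from_track(tr0)
  expect_equal(gust_velocity(p0, 0.05)[2], -0.76, tolerance = 1e-3 * 0.76)
  # recovered peak deceleration within 1% of the profile's peak
  a0 <- gust_acceleration(p0, seq(0, 0.4, 1 / 750))[, 2]
  expect_equal(max(a0), 11, tolerance = 0.01 * 11)
  # with 1 px RMS noise the plateau is still within 2%
  tr1 <- synth_tunnel_track(g, duration = 0.4, noise_px = 1, seed = 42)
  p1 <- tunnel_gust_profile_from_track(tr1)
  plateau <- mean(gust_velocity(p1, seq(0.02, 0.08, 0.005))[, 2])
  expect_equal(plateau, -0.76, tolerance = 0.02 * 0.76)
  # constant-velocity control
  pc <- tunnel_gust_profile_from_track(
    synth_tunnel_track(gust_step(-0.3, t0 = -1), duration = 0.2, noise_px = 0, seed = 1))
  expect_equal(gust_velocity(pc, 0.1)[2], -0.3, tolerance = 1e-10)
  # degenerate track
  expect_error(tunnel_gust_profile_from_track(
    track_series(1:2, 1:2, 750, 0.0805)), "too short")
})

test_that("plateau recovery stays within noise bounds across profiles and seeds", {
  g <- gust_ramp(t0 = 0.2, duration = 0.1, dv = 0.5, direction = c(0, 1, 0))
  for (seed in 1:5) {
    tr <- synth_tunnel_track(g, duration = 0.5, noise_px = 2, seed = seed)
    p <- tunnel_gust_profile_from_track(tr)
    # plateau after the ramp: average 0.35..0.48 s
    plateau <- mean(gust_velocity(p, seq(0.36, 0.48, 0.005))[, 2])
    # 2 px noise, 10-pt average, ~25-sample plateau mean: 3-sigma ~ 0.02 m/s
    expect_lt(abs(plateau - 0.5), 0.02)
  }
})

test_that("stem angle is signed positive-clockwise and antisymmetric under mirroring", {
  rate <- 750; res <- 0.0805
  tip <- track_series(x_px = c(0, 0, 0), y_px = c(0, 0, 0), rate, res)
  # upright: centroid directly above tip
  up <- track_series(x_px = c(10, 10, 10), y_px = c(0, 0, 0), rate, res)
  expect_equal(stem_angle(tip, up)$theta, c(0, 0, 0))
  # top leaning towards +y: positive (clockwise) angle
  lean <- track_series(x_px = c(10, 10, 10), y_px = c(2, 3, 4), rate, res)
  th <- stem_angle(tip, lean)$theta
  expect_true(all(th > 0))
  expect_equal(th[1], atan2(2, 10))
  # mirroring the horizontal axis negates the angle
  mir <- track_series(x_px = lean$x_px, y_px = -lean$y_px, rate, res)
  expect_equal(stem_angle(tip, mir)$theta, -th)
  # coincident points are undefined
  expect_error(stem_angle(tip, tip), "undefined")
})

test_that("track files round-trip with their acquisition metadata", {
  g <- demo_gust_profile()
  tr <- synth_tunnel_track(g, duration = 0.1, noise_px = 1, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_series(tr, path)
  back <- read_track_series(path)
  expect_equal(back$x_px, tr$x_px, tolerance = 1e-9)
  expect_equal(attr(back, "frame_rate"), 750)
  expect_equal(attr(back, "resolution_mm_px"), 0.0805)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x_px,y_px", "0,1,2"), bad)
  expect_error(read_track_series(bad), "sidecar")
  expect_silent(read_track_series(bad, frame_rate = 100, resolution_mm_px = 1))
})

test_that("single-track kinematics reports smoothed position, velocity and acceleration", {
  # constant-acceleration track: a = 0.2 m/s^2 along y
  rate <- 750; res <- 0.0805
  t <- seq(0, 0.3, by = 1 / rate)
  y_m <- 0.5 * 0.2 * t^2
  tr <- track_series(x_px = rep(0, length(t)), y_px = y_m / (res * 1e-3),
                     frame_rate = rate, resolution_mm_px = res)
  kin <- track_kinematics(tr)
  inner <- seq(10, length(t) - 10)
  # an even (10-point) centred window is offset by half a sample, so the
  # recovered velocity is the true one evaluated half a frame later
  expect_equal(kin$v[inner], 0.2 * (t[inner] + 0.5 / rate), tolerance = 1e-6)
  expect_equal(mean(kin$ay[inner]), 0.2, tolerance = 1e-4)
})
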