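make_uniform_fields <- function(U = 1, nx = 5, ny = 7, nt = 4) {
  x <- seq(0, 0.01 * (nx - 1), by = 0.01)
  y <- seq(0, 0.01 * (ny - 1), by = 0.01)
  field_series(x, y, array(U, c(nx, ny, nt)), array(0, c(nx, ny, nt)),
               times = seq_len(nt) * 1e-3)
}

test_that("uniformity of a constant field is exact and normalises to mean one", {
  fs <- make_uniform_fields()
  rep <- flow_uniformity(fs)
  expect_equal(rep$max_deviation, 0)
  expect_equal(mean(rep$normalised), 1)
  expect_equal(rep$mean_speed, 1)
})

test_that("a prescribed 2% spatial pattern is reported as a 2% deviation", {
  nx <- 6; ny <- 8; nt <- 3
  x <- seq(0, 0.05, length.out = nx); y <- seq(0, 0.07, length.out = ny)
  s <- rep_len(c(1, -1), nx)  # +/-1 pattern along x
  u <- array(rep(1 * (1 + 0.02 * s), times = ny * nt), c(nx, ny, nt))
  fs <- field_series(x, y, u, array(0, c(nx, ny, nt)), times = 1:nt)
  rep <- flow_uniformity(fs)
  expect_equal(rep$max_deviation, 0.02, tolerance = 1e-3)
  expect_equal(mean(rep$normalised), 1, tolerance = 1e-12)
})

test_that("degenerate uniformity inputs are rejected", {
  fs <- make_uniform_fields(nt = 4)
  one <- field_series(fs$x, fs$y, fs$u[, , 1, drop = FALSE],
                      fs$v[, , 1, drop = FALSE], times = 1)
  expect_error(flow_uniformity(one), "two frames")
  expect_error(flow_uniformity(fs, window = list(xlim = c(10, 11))), "no grid points")
})

test_that("turbulence intensity is zero for a constant field and recovers noise", {
  fs <- make_uniform_fields()
  tm <- turbulence_intensity(fs)
  expect_equal(max(tm$map), 0)
  # seeded Gaussian fluctuations on both components at sigma = 0.01 U
  fs2 <- synth_field_series(mean_speed = 1, intensity = 0.01,
                            x = seq(0, 0.02, 0.002), y = seq(0, 0.02, 0.002),
                            n_frames = 2000, seed = 99)
  tm2 <- turbulence_intensity(fs2)
  expect_equal(tm2$mean_intensity, 0.01, tolerance = 3 / sqrt(2 * 2000))
  # doubling the fluctuation doubles the intensity (asymptotically)
  fs3 <- synth_field_series(mean_speed = 1, intensity = 0.02,
                            x = seq(0, 0.02, 0.002), y = seq(0, 0.02, 0.002),
                            n_frames = 2000, seed = 99)
  tm3 <- turbulence_intensity(fs3)
  expect_equal(tm3$mean_intensity / tm2$mean_intensity, 2, tolerance = 0.02)
})

test_that("zero local mean speed is masked and reported, not divided by", {
  nx <- 3; ny <- 3; nt <- 5
  u <- array(0, c(nx, ny, nt)); u[1, 1, ] <- 1
  fs <- field_series(1:3, 1:3, u, array(0, c(nx, ny, nt)), times = 1:nt)
  tm <- turbulence_intensity(fs)
  expect_equal(tm$n_undefined, nx * ny - 1)
  expect_true(is.na(tm$map[2, 2]))
  expect_equal(tm$map[1, 1], 0)
})

test_that("frame shifting subtracts the tunnel speed and preserves gradients", {
  nx <- 4; ny <- 5; nt <- 3
  x <- seq(0, 0.03, 0.01); y <- seq(0, 0.04, 0.01)
  v <- array(rep(seq(0, 0.04, 0.01), each = nx), c(nx, ny, nt))  # shear in y
  u <- array(0.38, c(nx, ny, nt))
  fs <- field_series(x, y, u, v, times = c(0.1, 0.2, 0.3))
  g <- gust_step(-0.8, t0 = 0.15)
  sh <- shift_field_frame(fs, g)
  # before onset: unchanged; after: horizontal component shifted by +0.8
  expect_equal(sh$v[, , 1], v[, , 1])
  expect_equal(sh$v[, , 2], v[, , 2] + 0.8)
  # all spatial gradients are untouched
  expect_equal(apply(sh$v, 3, function(m) diff(t(m))),
               apply(v, 3, function(m) diff(t(m))))
  # round trip and zero-shift identity
  back <- shift_field_frame(sh, function(t) -gust_velocity(g, t)[2])
  expect_equal(back$v, v)
  idn <- shift_field_frame(fs, gust_none())
  expect_equal(idn$v, v)
})

test_that("physical pressure restores hydrostatic and gust-hydrostatic terms", {
  expect_equal(physical_pressure_static(5, 0.2, 0.2, 9.81), 5)
  expect_equal(physical_pressure_static(0, -0.1, 0, 9.81), 0.981)
  expect_equal(physical_pressure_static(3, 0.4, 0.1, 0), 3)
  expect_equal(physical_pressure_gust(0, 0, 0.05, 0, 9.81, 11), -0.55)
  expect_equal(physical_pressure_gust(2, 0.1, 0.3, 0.2, 9.81, 0),
               physical_pressure_static(2, 0.1, 0.2, 9.81))
  # the added horizontal term is a uniform gradient of -a_G
  y <- seq(-0.1, 0.1, 0.01)
  p <- physical_pressure_gust(0, 0, y, 0, 9.81, 11)
  expect_equal(diff(p) / diff(y), rep(-11, length(y) - 1))
  # and both added terms are linear in the coordinates (zero Laplacian)
  x <- seq(0, 0.1, 0.01)
  px <- physical_pressure_gust(0, x, 0, 0, 9.81, 11)
  expect_equal(diff(diff(px)), rep(0, length(x) - 2))
})

test_that("field series survive a text round trip and reject malformed files", {
  fs <- synth_field_series(n_frames = 3, x = seq(0, 0.01, 0.005),
                           y = seq(0, 0.02, 0.005), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_series(fs, path)
  back <- read_field_series(path)
  expect_equal(back$u, fs$u, tolerance = 1e-12)
  expect_equal(back$v, fs$v, tolerance = 1e-12)
  expect_equal(back$times, fs$times)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_field_series(bad), "malformed")
  # drop one grid point from one frame
  df <- utils::read.csv(path)
  utils::write.csv(df[-2, ], bad, row.names = FALSE)
  expect_error(read_field_series(bad), "grid")
})
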