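#' Gridded velocity-field series
#'
#' A time series of 2D velocity snapshots on a fixed rectangular grid, as
#' produced by planar PIV of the tunnel test section: `u` is the streamwise
#' (vertical, x) component and `v` the crossflow (horizontal, y) component.
#'
#' @param x,y Strictly increasing grid coordinates (m).
#' @param u,v Arrays of dimension `length(x)` x `length(y)` x `n_frames`
#'   (m s^-1).
#' @param times Frame times (s), strictly increasing, one per frame.
#' @return An object of class `field_series`.
#' @export
field_series <- function(x, y, u, v, times) {
  x <- as.numeric(x); y <- as.numeric(y); times <- as.numeric(times)
  if (any(diff(x) <= 0) || any(diff(y) <= 0)) {
    stop("grid coordinates must be strictly increasing", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing", call. = FALSE)
  dims <- c(length(x), length(y), length(times))
  u <- array(as.numeric(u), dim = dims)
  v <- array(as.numeric(v), dim = dims)
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    stop("velocity samples must be finite", call. = FALSE)
  }
  structure(list(x = x, y = y, u = u, v = v, times = times),
            class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %d x %d grid, %d frames, t in [%.4g, %.4g] s\n",
              length(x$x), length(x$y), length(x$times),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# Logical index matrices for a window = list(xlim=, ylim=); NULL = full grid.
window_index <- function(fs, window) {
  ix <- rep(TRUE, length(fs$x)); iy <- rep(TRUE, length(fs$y))
  if (!is.null(window)) {
    if (!is.null(window$xlim)) ix <- fs$x >= window$xlim[1] & fs$x <= window$xlim[2]
    if (!is.null(window$ylim)) iy <- fs$y >= window$ylim[1] & fs$y <= window$ylim[2]
  }
  if (!any(ix) || !any(iy)) stop("window selects no grid points", call. = FALSE)
  list(ix = ix, iy = iy)
}

#' Flow uniformity report
#'
#' Time-averages each velocity component, forms the speed map `|u_bar|`,
#' normalises it by its spatial mean over the analysis window and reports the
#' maximum fractional deviation from 1. A well-conditioned tunnel shows
#' deviations of a few percent at most in the central volume.
#'
#' @param fs A [field_series()] with at least two frames.
#' @param window Optional list with `xlim` and/or `ylim` (m) restricting the
#'   averaging region; default is the full grid.
#' @return An object of class `uniformity_report`: list with `x`, `y`,
#'   `speed_map` (time-averaged speed over the window), `mean_speed`,
#'   `normalised` (map divided by its spatial mean) and `max_deviation`
#'   (max of `|normalised - 1|`).
#' @export
flow_uniformity <- function(fs, window = NULL) {
  stopifnot(inherits(fs, "field_series"))
  if (length(fs$times) < 2L) {
    stop("uniformity needs at least two frames", call. = FALSE)
  }
  w <- window_index(fs, window)
  ub <- apply(fs$u[w$ix, w$iy, , drop = FALSE], c(1, 2), mean)
  vb <- apply(fs$v[w$ix, w$iy, , drop = FALSE], c(1, 2), mean)
  speed <- sqrt(ub^2 + vb^2)
  mean_speed <- mean(speed)
  normalised <- speed / mean_speed
  structure(list(x = fs$x[w$ix], y = fs$y[w$iy],
                 speed_map = speed, mean_speed = mean_speed,
                 normalised = normalised,
                 max_deviation = max(abs(normalised - 1))),
            class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat(sprintf("<uniformity_report> mean speed %.4g m/s, max deviation %.3g%%\n",
              x$mean_speed, 100 * x$max_deviation))
  invisible(x)
}

#' Turbulence-intensity map
#'
#' Pointwise RMS velocity fluctuation normalised by the local time-averaged
#' speed:
#' `T = sqrt( (mean((u - u_bar)^2) + mean((v - v_bar)^2)) / 2 ) / |u_bar|`,
#' with time means taken at each grid point. Points with zero local mean speed
#' have undefined intensity; they are returned as `NA` and counted in
#' `n_undefined`.
#'
#' @inheritParams flow_uniformity
#' @return An object of class `turbulence_map`: list with `x`, `y`, `map`
#'   (dimensionless intensities, `NA` where undefined), `mean_intensity`
#'   (mean over defined points) and `n_undefined`.
#' @export
turbulence_intensity <- function(fs, window = NULL) {
  stopifnot(inherits(fs, "field_series"))
  if (length(fs$times) < 2L) {
    stop("turbulence intensity needs at least two frames", call. = FALSE)
  }
  w <- window_index(fs, window)
  u <- fs$u[w$ix, w$iy, , drop = FALSE]
  v <- fs$v[w$ix, w$iy, , drop = FALSE]
  ub <- apply(u, c(1, 2), mean)
  vb <- apply(v, c(1, 2), mean)
  var_u <- apply(u, c(1, 2), function(s) mean((s - mean(s))^2))
  var_v <- apply(v, c(1, 2), function(s) mean((s - mean(s))^2))
  speed <- sqrt(ub^2 + vb^2)
  map <- sqrt((var_u + var_v) / 2) / speed
  undef <- speed == 0
  map[undef] <- NA_real_
  structure(list(x = fs$x[w$ix], y = fs$y[w$iy], map = map,
                 mean_intensity = mean(map, na.rm = TRUE),
                 n_undefined = sum(undef)),
            class = "turbulence_map")
}

#' @export
print.turbulence_map <- function(x, ...) {
  cat(sprintf("<turbulence_map> mean intensity %.3g%%, %d undefined point(s)\n",
              100 * x$mean_intensity, x$n_undefined))
  invisible(x)
}

#' Shift a field series into the tunnel frame
#'
#' Subtracts the (spatially uniform) instantaneous tunnel velocity from the
#' horizontal component of every frame: `v' = v - u_G(t)`. A uniform
#' subtraction leaves all spatial gradients untouched, which is the field-side
#' statement of the gust equivalence: the flow observed in the tunnel frame is
#' unchanged by the translation.
#'
#' @param fs A [field_series()].
#' @param gust A [gust_profiles] object, or a function `u_G(t)` returning the
#'   horizontal tunnel speed (m s^-1) at each frame time.
#' @return A [field_series()] in tunnel-frame velocities.
#' @export
shift_field_frame <- function(fs, gust) {
  stopifnot(inherits(fs, "field_series"))
  ug <- if (inherits(gust, "gust_profile")) {
    gust_speed(gust, fs$times)
  } else if (is.function(gust)) {
    vapply(fs$times, gust, numeric(1))
  } else {
    stop("'gust' must be a gust_profile or a function of time", call. = FALSE)
  }
  if (any(!is.finite(ug))) {
    stop("tunnel velocity undefined at some frame times", call. = FALSE)
  }
  v <- fs$v
  for (i in seq_along(fs$times)) v[, , i] <- v[, , i] - ug[i]
  field_series(fs$x, fs$y, fs$u, v, fs$times)
}

#' Physical pressure reconstruction
#'
#' The pressure solved alongside the flow equations is net of hydrostatic
#' contributions. `physical_pressure_static()` restores the vertical
#' hydrostatic term for a quiescent-frame field:
#' `p_ph = p - g (x - x_out)`, with `x` the upward streamwise coordinate and
#' `x_out` the outlet reference. `physical_pressure_gust()` additionally
#' restores the horizontal hydrostatic pressure carried by the accelerating
#' frame: `p_ph = p' - g (x' - x_out') - a_G y'`, with `y'` the horizontal
#' coordinate along the gust, centred in the tunnel section. Both terms are
#' linear in the coordinates, so they contribute a uniform gradient and
#' nothing to the pressure Laplacian. Pressures are per unit fluid density
#' (m^2 s^-2) unless the input is already in Pa.
#'
#' @param p Pressure field (net of hydrostatic terms).
#' @param x Upward streamwise coordinate(s) (m).
#' @param y Horizontal coordinate(s) along the gust direction (m).
#' @param x_out Outlet section coordinate (m).
#' @param g Gravitational acceleration magnitude (m s^-2).
#' @param a_G Gust (tunnel) acceleration (m s^-2).
#' @return Physical pressure, same shape as `p`.
#' @export
physical_pressure_static <- function(p, x, x_out, g) {
  p - g * (x - x_out)
}

#' @rdname physical_pressure_static
#' @export
physical_pressure_gust <- function(p, x, y, x_out, g, a_G) {
  p - g * (x - x_out) - a_G * y
}

#' Read and write field series as delimited text
#'
#' Long-format CSV with a single header line and columns
#' `frame, t, x, y, u, v`, one row per grid point per frame. The reader
#' validates that every frame shares one rectangular grid and rejects
#' inconsistent files with the offending frame number.
#'
#' @param fs A [field_series()].
#' @param path File path.
#' @return `write_field_series()` returns `path` invisibly;
#'   `read_field_series()` returns a [field_series()].
#' @export
write_field_series <- function(fs, path) {
  stopifnot(inherits(fs, "field_series"))
  nx <- length(fs$x); ny <- length(fs$y); nt <- length(fs$times)
  grid <- expand.grid(x = fs$x, y = fs$y, KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(
    frame = rep(seq_len(nt), each = nx * ny),
    t = rep(fs$times, each = nx * ny),
    x = rep(grid$x, times = nt),
    y = rep(grid$y, times = nt),
    u = as.numeric(fs$u),
    v = as.numeric(fs$v)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_series
#' @export
read_field_series <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "t", "x", "y", "u", "v")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed field file '%s': needs columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  }
  frames <- sort(unique(df$frame))
  x <- sort(unique(df$x)); y <- sort(unique(df$y))
  nx <- length(x); ny <- length(y); nt <- length(frames)
  u <- array(NA_real_, c(nx, ny, nt)); v <- array(NA_real_, c(nx, ny, nt))
  times <- numeric(nt)
  for (i in seq_len(nt)) {
    sub <- df[df$frame == frames[i], , drop = FALSE]
    if (nrow(sub) != nx * ny) {
      stop(sprintf("frame %s does not cover the full %d x %d grid", frames[i], nx, ny),
           call. = FALSE)
    }
    ord <- order(sub$y, sub$x)
    sub <- sub[ord, , drop = FALSE]
    u[, , i] <- sub$u
    v[, , i] <- sub$v
    times[i] <- sub$t[1L]
  }
  field_series(x, y, u, v, times)
}
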