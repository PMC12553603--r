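# Finite differences on a (possibly non-uniform) strictly increasing grid:
# second-order central at interior points, second-order one-sided at the ends.
fd_derivative <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("differentiation needs at least 3 samples", call. = FALSE)
  d <- numeric(n)
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  d[2:(n - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(n - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(n - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:n]
  ha <- x[2] - x[1]; hb <- x[3] - x[2]
  d[1] <- -(2 * ha + hb) / (ha * (ha + hb)) * y[1] +
    (ha + hb) / (ha * hb) * y[2] - ha / (hb * (ha + hb)) * y[3]
  hc <- x[n - 1] - x[n - 2]; hd <- x[n] - x[n - 1]
  d[n] <- hd / (hc * (hc + hd)) * y[n - 2] -
    (hc + hd) / (hc * hd) * y[n - 1] + (2 * hd + hc) / (hd * (hc + hd)) * y[n]
  d
}

#' Marker track series
#'
#' A pixel-coordinate track of a marker (or body feature) from high-speed
#' imaging at a constant frame rate, with the image resolution needed to
#' convert pixels to metres. Image coordinates follow the tunnel convention:
#' `x_px` vertical (up), `y_px` horizontal.
#'
#' @param x_px,y_px Pixel coordinates, one per frame.
#' @param frame_rate Frames per second (s^-1), positive.
#' @param resolution_mm_px Image resolution (mm per pixel), positive.
#' @param frame Frame indices; default `0, 1, ...`.
#' @return An object of class `track_series`: data frame with columns `frame`,
#'   `t`, `x_px`, `y_px` and attributes `frame_rate`, `resolution_mm_px`.
#' @export
track_series <- function(x_px, y_px, frame_rate, resolution_mm_px,
                         frame = seq_along(x_px) - 1L) {
  check_positive(frame_rate, "frame_rate")
  check_positive(resolution_mm_px, "resolution_mm_px")
  x_px <- as.numeric(x_px); y_px <- as.numeric(y_px)
  if (length(x_px) == 0L || length(x_px) != length(y_px)) {
    stop("'x_px' and 'y_px' must be non-empty and of equal length", call. = FALSE)
  }
  df <- data.frame(frame = as.integer(frame), t = as.numeric(frame) / frame_rate,
                   x_px = x_px, y_px = y_px)
  structure(df, class = c("track_series", "data.frame"),
            frame_rate = frame_rate, resolution_mm_px = resolution_mm_px)
}

#' Convert a pixel track to metres
#'
#' Multiplies pixel coordinates by the image resolution (mm/px, converted to
#' m/px).
#'
#' @param track A [track_series()].
#' @return Data frame with columns `t`, `x` and `y` (m).
#' @export
pixels_to_metres <- function(track) {
  stopifnot(inherits(track, "track_series"))
  res <- attr(track, "resolution_mm_px")
  if (is.null(res) || !is.finite(res) || res <= 0) {
    stop("track has no valid resolution", call. = FALSE)
  }
  data.frame(t = track$t, x = track$x_px * res * 1e-3, y = track$y_px * res * 1e-3)
}

#' Centred moving-average de-noising
#'
#' Centred moving mean with the stated window (default ten points, the
#' standard track de-noising choice). Near the ends the window shrinks to the
#' available samples, so the series length and its timestamps are preserved —
#' event times (gust onset, tunnel stop) stay aligned with the raw series.
#'
#' @param x Numeric series.
#' @param window Window length in samples, `1 <= window <= length(x)`.
#' @return De-noised series, same length as `x`.
#' @export
moving_average <- function(x, window = 10L) {
  x <- as.numeric(x)
  window <- as.integer(window)
  if (window < 1L) stop("'window' must be >= 1", call. = FALSE)
  if (window > length(x)) {
    stop("'window' exceeds the series length", call. = FALSE)
  }
  n <- length(x)
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

#' Differentiate a uniformly sampled series
#'
#' Second-order-accurate time derivative of a series sampled at a constant
#' rate: central differences at interior points and second-order one-sided
#' stencils at the two ends (exact for quadratics everywhere).
#'
#' @param x Numeric series (>= 3 samples).
#' @param rate Sampling rate (s^-1), positive.
#' @return Derivative series, same length as `x`.
#' @export
differentiate <- function(x, rate) {
  check_positive(rate, "rate")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("differentiation needs at least 3 samples", call. = FALSE)
  fd_derivative(seq(0, by = 1 / rate, length.out = n), x)
}

#' Extract the tunnel gust profile from a marker track
#'
#' The tunnel's translation history is measured by tracking a marker mounted
#' on the tunnel. This applies the standard pipeline — pixels to metres, a
#' centred moving average (default ten points), then a second-order time
#' derivative — to the horizontal coordinate and returns the result as a
#' tabulated gust profile (whose acceleration is the finite-difference
#' derivative of the recovered velocity).
#'
#' @param track A [track_series()] of the tunnel marker.
#' @param window Moving-average window (samples).
#' @param axis Which pixel coordinate carries the translation: `"y"`
#'   (horizontal, default) or `"x"`.
#' @param direction Gust direction unit vector for the returned profile.
#' @return A [gust_tabulated()] profile sampled at the track times.
#' @export
tunnel_gust_profile_from_track <- function(track, window = 10L, axis = c("y", "x"),
                                           direction = c(0, 1, 0)) {
  stopifnot(inherits(track, "track_series"))
  axis <- match.arg(axis)
  if (nrow(track) < 3L) {
    stop("track too short to differentiate (needs >= 3 frames)", call. = FALSE)
  }
  pos <- pixels_to_metres(track)
  p <- if (axis == "y") pos$y else pos$x
  sm <- moving_average(p, window)
  vel <- differentiate(sm, attr(track, "frame_rate"))
  gust_tabulated(pos$t, vel, direction = direction)
}

#' Stem angle from tip and centroid tracks
#'
#' The orientation of a diaspore in the image plane, measured as the angle of
#' its stem axis (tip of the achene to pappus centroid, i.e. pointing up when
#' upright) from the vertical, positive clockwise in the x-up / y-right image
#' plane: a body whose top leans towards +y has a positive angle.
#'
#' @param tip_track,centroid_track Synchronised [track_series()] of the achene
#'   tip and of the shadowgraph centroid.
#' @return Data frame with columns `t` and `theta` (rad).
#' @export
stem_angle <- function(tip_track, centroid_track) {
  stopifnot(inherits(tip_track, "track_series"), inherits(centroid_track, "track_series"))
  if (nrow(tip_track) != nrow(centroid_track) ||
      max(abs(tip_track$t - centroid_track$t)) > 1e-9) {
    stop("tip and centroid tracks must be synchronised", call. = FALSE)
  }
  sx <- centroid_track$x_px - tip_track$x_px
  sy <- centroid_track$y_px - tip_track$y_px
  if (any(sx == 0 & sy == 0)) {
    stop("coincident tip and centroid points: stem angle undefined", call. = FALSE)
  }
  data.frame(t = tip_track$t, theta = atan2(sy, sx))
}

#' Track file input/output
#'
#' Delimited text with a one-line header and columns `frame, x_px, y_px`.
#' Frame rate and resolution travel in the run configuration or in a sidecar
#' metadata line of the form `# frame_rate_hz=750 resolution_mm_px=0.0805`
#' written at the top of the file.
#'
#' @param track A [track_series()].
#' @param path File path.
#' @param frame_rate,resolution_mm_px Acquisition metadata for
#'   `read_track_series()`; if `NULL`, the sidecar comment line is required.
#' @return `write_track_series()` returns `path` invisibly;
#'   `read_track_series()` returns a [track_series()].
#' @export
write_track_series <- function(track, path) {
  stopifnot(inherits(track, "track_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz=%.10g resolution_mm_px=%.10g",
                     attr(track, "frame_rate"), attr(track, "resolution_mm_px")), con)
  utils::write.csv(track[, c("frame", "x_px", "y_px")], con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_series
#' @export
read_track_series <- function(path, frame_rate = NULL, resolution_mm_px = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    fr <- regmatches(first, regexec("frame_rate_hz=([0-9.eE+-]+)", first))[[1L]]
    rs <- regmatches(first, regexec("resolution_mm_px=([0-9.eE+-]+)", first))[[1L]]
    if (length(fr) == 2L && is.null(frame_rate)) frame_rate <- as.numeric(fr[2L])
    if (length(rs) == 2L && is.null(resolution_mm_px)) resolution_mm_px <- as.numeric(rs[2L])
  }
  if (is.null(frame_rate) || is.null(resolution_mm_px)) {
    stop(sprintf("'%s': frame rate and resolution must come from the sidecar line or arguments",
                 path), call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("frame", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop(sprintf("malformed track file '%s': needs columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  }
  track_series(df$x_px, df$y_px, frame_rate, resolution_mm_px, frame = df$frame)
}

#' Kinematics from a track
#'
#' Full single-track pipeline: pixels to metres, centred moving average on
#' both coordinates, then first and second time derivatives (velocity and
#' acceleration), all second-order accurate.
#'
#' @param track A [track_series()].
#' @param window Moving-average window (samples), default 10.
#' @return A data frame with columns `t`, `x`, `y` (m), `u`, `v` (m s^-1)
#'   and `ax`, `ay` (m s^-2).
#' @export
track_kinematics <- function(track, window = 10L) {
  stopifnot(inherits(track, "track_series"))
  if (nrow(track) < 3L) {
    stop("track too short to differentiate (needs >= 3 frames)", call. = FALSE)
  }
  rate <- attr(track, "frame_rate")
  pos <- pixels_to_metres(track)
  xs <- moving_average(pos$x, window)
  ys <- moving_average(pos$y, window)
  u <- differentiate(xs, rate); v <- differentiate(ys, rate)
  data.frame(t = pos$t, x = xs, y = ys, u = u, v = v,
             ax = differentiate(u, rate), ay = differentiate(v, rate))
}
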