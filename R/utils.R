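# Internal helpers: small vector algebra, quaternions, input validation.

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

norm3 <- function(v) sqrt(sum(v * v))

as_vec3 <- function(v, name = "vector") {
  v <- as.numeric(v)
  if (length(v) == 1L) v <- c(v, 0, 0)
  if (length(v) != 3L || any(!is.finite(v))) {
    stop(sprintf("'%s' must be a finite numeric vector of length 3", name),
         call. = FALSE)
  }
  v
}

unitize <- function(v, name = "direction") {
  v <- as_vec3(v, name)
  n <- norm3(v)
  if (n < 1e-300) stop(sprintf("'%s' must be non-zero", name), call. = FALSE)
  v / n
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Hamilton product; quaternions stored as c(w, x, y, z), mapping body -> world.
quat_mul <- function(p, q) {
  c(p[1L] * q[1L] - p[2L] * q[2L] - p[3L] * q[3L] - p[4L] * q[4L],
    p[1L] * q[2L] + p[2L] * q[1L] + p[3L] * q[4L] - p[4L] * q[3L],
    p[1L] * q[3L] - p[2L] * q[4L] + p[3L] * q[1L] + p[4L] * q[2L],
    p[1L] * q[4L] + p[2L] * q[3L] - p[3L] * q[2L] + p[4L] * q[1L])
}

quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-300) stop("degenerate quaternion (zero norm)", call. = FALSE)
  q / n
}

# Rotation matrix of unit quaternion (body -> world).
quat_rotmat <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3L, byrow = TRUE)
}

quat_rotate <- function(q, v) as.numeric(quat_rotmat(q) %*% v)

# Quaternion kinematics: dq/dt = (1/2) q (x) (0, omega_body).
quat_deriv <- function(q, omega_body) {
  0.5 * quat_mul(q, c(0, omega_body))
}

# Quaternion for planar rotation by angle theta about +z (theta positive
# clockwise in the x-up / y-right viewing plane).
quat_about_z <- function(theta) c(cos(theta / 2), 0, 0, sin(theta / 2))

# Signed rotation angle about +z of a (near-planar) orientation quaternion.
quat_angle_z <- function(q) {
  2 * atan2(q[4L], q[1L])
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Cumulative trapezoidal integral of y over x, same length as x, starts at 0.
cumtrapz1 <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(0.5 * diff(x) * (y[-n] + y[-1L])))
}
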