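#' Ambient fluid medium
#'
#' Describes the fluid in which a body falls: density, kinematic viscosity and
#' the gravity vector. The package convention is x vertical upward (streamwise
#' in a vertically blowing tunnel), y horizontal (gust direction), z completing
#' the right-handed triad; gravity therefore points along -x by default.
#'
#' @param density Fluid density (kg m^-3). Default 1.204 (air at ~20 C).
#' @param viscosity Kinematic viscosity (m^2 s^-1). Default 1.5e-5 (air).
#' @param gravity Gravity vector (m s^-2), default `c(-9.81, 0, 0)`.
#' @return An object of class `fluid_medium`.
#' @examples
#' air <- fluid_medium()
#' water <- fluid_medium(density = 1000, viscosity = 1e-6)
#' @export
fluid_medium <- function(density = 1.204, viscosity = 1.5e-5,
                         gravity = c(-9.81, 0, 0)) {
  check_positive(density, "density")
  check_positive(viscosity, "viscosity")
  gravity <- as_vec3(gravity, "gravity")
  if (norm3(gravity) <= 0) stop("'gravity' must have positive magnitude", call. = FALSE)
  structure(list(density = density, viscosity = viscosity, gravity = gravity),
            class = "fluid_medium")
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf("<fluid_medium> density %.4g kg/m^3, viscosity %.4g m^2/s, |g| %.4g m/s^2\n",
              x$density, x$viscosity, norm3(x$gravity)))
  invisible(x)
}

#' Reduced gravitational acceleration
#'
#' Gravity net of the specific buoyancy force, `(1 - rho_f/rho_b) * g`.
#' The result is signed: it is negative for a buoyant body (`rho_f > rho_b`)
#' and exactly zero at neutral buoyancy.
#'
#' @param g_mag Gravitational acceleration magnitude (m s^-2).
#' @param rho_f Fluid density (kg m^-3), positive.
#' @param rho_b Body mean density (kg m^-3), positive.
#' @return Reduced gravity (m s^-2), possibly negative.
#' @examples
#' reduced_gravity(9.81, 1.2, 600)
#' @export
reduced_gravity <- function(g_mag, rho_f, rho_b) {
  if (!is.numeric(g_mag) || length(g_mag) != 1L || !is.finite(g_mag)) {
    stop("'g_mag' must be a finite number", call. = FALSE)
  }
  check_positive(rho_f, "rho_f")
  check_positive(rho_b, "rho_b")
  (1 - rho_f / rho_b) * g_mag
}

#' Gravitational velocity scale
#'
#' The velocity scale `sqrt(m * |g*| / (rho_f * l^2))` used to
#' non-dimensionalise the equations of a free-falling body. It is undefined at
#' neutral buoyancy (`g* = 0`), where the scaling breaks down and the gust
#' response vanishes; that case raises an error rather than returning 0.
#'
#' @param m Body mass (kg), positive.
#' @param g_star Reduced gravity (m s^-2); any sign, but not zero.
#' @param rho_f Fluid density (kg m^-3), positive.
#' @param l Reference length (m), positive.
#' @return Gravitational velocity (m s^-1), positive.
#' @examples
#' gravitational_velocity(1e-6, 9.79038, 1.2, 0.01)
#' @export
gravitational_velocity <- function(m, g_star, rho_f, l) {
  check_positive(m, "m")
  check_positive(rho_f, "rho_f")
  check_positive(l, "l")
  if (!is.numeric(g_star) || length(g_star) != 1L || !is.finite(g_star)) {
    stop("'g_star' must be a finite number", call. = FALSE)
  }
  if (g_star == 0) {
    stop(paste("gravitational velocity is undefined at neutral buoyancy:",
               "the non-dimensionalisation requires u_g != 0 and hence",
               "rho_f/rho_b != 1"), call. = FALSE)
  }
  sqrt(m * abs(g_star) / (rho_f * l^2))
}

#' Galilei number
#'
#' `Ga = u_g * l / nu`, the ratio of gravitational to viscous effects. Unlike
#' the Reynolds number (built on the a-posteriori terminal velocity), `Ga` is
#' known before any experiment and is the natural control parameter of free
#' fall.
#'
#' @param u_g Gravitational velocity (m s^-1), positive.
#' @param l Reference length (m), positive.
#' @param nu Kinematic viscosity (m^2 s^-1), positive.
#' @return Dimensionless Galilei number.
#' @export
galilei_number <- function(u_g, l, nu) {
  check_positive(u_g, "u_g")
  check_positive(l, "l")
  check_positive(nu, "nu")
  u_g * l / nu
}

#' Reynolds number based on terminal velocity
#'
#' `Re = u_t * l / nu`.
#'
#' @param u_t Terminal velocity (m s^-1), positive.
#' @param l Reference length (m), positive.
#' @param nu Kinematic viscosity (m^2 s^-1), positive.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(0.38, 0.01, 1.5e-5)
#' @export
reynolds_number <- function(u_t, l, nu) {
  check_positive(u_t, "u_t")
  check_positive(l, "l")
  check_positive(nu, "nu")
  u_t * l / nu
}

#' Disc geometry factor
#'
#' For a homogeneous disc of thickness `f` and diameter `l` the dimensionless
#' mass factor is `chi = pi * f / l`.
#'
#' @param f Plate thickness (m), positive.
#' @param l Disc diameter (m), positive.
#' @return Dimensionless geometry factor.
#' @export
disc_geometry_factor <- function(f, l) {
  check_positive(f, "f")
  check_positive(l, "l")
  pi * f / l
}

#' Dimensionless scale set for a body in a medium
#'
#' Derives the reporting scales from a dimensional body/medium pair: reduced
#' gravity, gravitational velocity, Galilei number, density ratio and the
#' dimensionless mass `m / (rho_f l^3)`. At neutral buoyancy the velocity-based
#' groups are undefined; they are returned as `NA` with a warning. If a
#' terminal velocity is supplied, the Reynolds number is included.
#'
#' @param body A [body_spec()].
#' @param medium A [fluid_medium()].
#' @param u_t Optional terminal velocity (m s^-1) for the Reynolds number.
#' @return An object of class `scale_set`: list with `g_star`, `u_g`, `Ga`,
#'   `rho`, `m_nd` and (optionally) `Re`.
#' @export
scale_set <- function(body, medium, u_t = NULL) {
  stopifnot(inherits(body, "body_spec"), inherits(medium, "fluid_medium"))
  g_mag <- norm3(medium$gravity)
  g_star <- reduced_gravity(g_mag, medium$density, body$density)
  rho <- medium$density / body$density
  if (g_star == 0) {
    warning("neutral buoyancy: u_g and Ga are undefined and reported as NA")
    u_g <- NA_real_
    Ga <- NA_real_
  } else {
    u_g <- gravitational_velocity(body$mass, g_star, medium$density, body$length)
    Ga <- galilei_number(u_g, body$length, medium$viscosity)
  }
  out <- list(
    g_star = g_star,
    u_g = u_g,
    Ga = Ga,
    rho = rho,
    m_nd = body$mass / (medium$density * body$length^3)
  )
  if (!is.null(u_t)) out$Re <- reynolds_number(u_t, body$length, medium$viscosity)
  structure(out, class = "scale_set")
}

#' @export
print.scale_set <- function(x, ...) {
  cat("<scale_set>\n")
  for (nm in names(x)) cat(sprintf("  %-7s %.6g\n", nm, x[[nm]]))
  invisible(x)
}
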