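#' Rigid-body specification
#'
#' Describes the falling body: mass, mean density (hence displaced volume
#' `V = m / rho_b`), reference length, inertia tensor about the centre of
#' gravity in the body frame, and the centre-of-buoyancy offset. The offset is
#' given as an eccentricity `e >= 0` (distance, m) times a unit vector `r_hat`
#' (body frame) from the centre of gravity to the centre of buoyancy. A
#' bottom-heavy body such as a dandelion diaspore has `r_hat = +x` (seed at the
#' bottom, buoyant pappus above), which generates an upright-righting buoyancy
#' couple.
#'
#' @param mass Body mass (kg), positive.
#' @param density Body mean density (kg m^-3), positive. The displaced volume
#'   is `mass / density`.
#' @param length Reference length (m), positive (e.g. pappus diameter).
#' @param inertia 3x3 symmetric positive-definite inertia tensor about the
#'   centre of gravity, body frame (kg m^2). A length-3 vector is taken as the
#'   diagonal.
#' @param e Eccentricity: distance from centre of gravity to centre of
#'   buoyancy (m), non-negative.
#' @param r_hat Unit vector (body frame) from centre of gravity to centre of
#'   buoyancy; normalised internally. Ignored when `e = 0`.
#' @return An object of class `body_spec`.
#' @examples
#' body_spec(mass = 6e-7, density = 60, length = 0.014,
#'           inertia = c(2e-12, 1.5e-11, 1.5e-11), e = 0.003, r_hat = c(1, 0, 0))
#' @export
body_spec <- function(mass, density, length, inertia, e = 0, r_hat = c(1, 0, 0)) {
  check_positive(mass, "mass")
  check_positive(density, "density")
  check_positive(length, "length")
  check_nonnegative(e, "e")
  if (is.numeric(inertia) && is.null(dim(inertia)) && length(inertia) == 3L) {
    inertia <- diag(inertia)
  }
  inertia <- as.matrix(inertia)
  if (!all(dim(inertia) == c(3L, 3L)) || any(!is.finite(inertia))) {
    stop("'inertia' must be a finite 3x3 matrix (or length-3 diagonal)", call. = FALSE)
  }
  if (max(abs(inertia - t(inertia))) > 1e-12 * max(abs(inertia))) {
    stop("'inertia' must be symmetric", call. = FALSE)
  }
  ev <- eigen(inertia, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("'inertia' must be positive definite", call. = FALSE)
  r_hat <- unitize(r_hat, "r_hat")
  structure(list(
    mass = mass, density = density, volume = mass / density,
    length = length, inertia = inertia, inertia_inv = solve(inertia),
    e = e, r_hat = r_hat
  ), class = "body_spec")
}

#' @export
print.body_spec <- function(x, ...) {
  cat(sprintf("<body_spec> m %.4g kg, rho_b %.4g kg/m^3, V %.4g m^3, l %.4g m, e %.4g m\n",
              x$mass, x$density, x$volume, x$length, x$e))
  invisible(x)
}

#' Quasi-steady aerodynamic closures
#'
#' An aerodynamic closure supplies the fluid force `F` (world frame, applied at
#' the centre of gravity) and torque `T_o` (body frame, about the centre of
#' gravity) as a function of the body's velocity relative to the ambient fluid,
#' its orientation and angular velocity. In the full problem these loads come
#' from the Navier-Stokes solution or from experiment; closures are explicit
#' quasi-steady stand-ins that make the rigid-body equations self-contained,
#' and the closure interface is the documented hook for CFD- or data-driven
#' forces. Closures obey the quasi-steady contract: zero relative velocity and
#' zero spin give exactly zero force and torque. Buoyancy-type forces are NOT
#' part of a closure; they are handled by the dynamics module so that the
#' decomposition into fluid loads and gravity/buoyancy terms is preserved.
#'
#' * `linear_drag_closure(c, c_omega)`: `F = -c * u_rel`,
#'   `T_o = -c_omega * omega_b`. Linear and isotropic; admits closed-form
#'   solutions (terminal velocity `u_t = m g* / c`, relaxation time
#'   `tau = m / c`) used as analytic oracles, and produces exactly zero
#'   vertical response to a horizontal gust.
#' * `quadratic_drag_closure(C_D, A, c_omega)`:
#'   `F = -1/2 rho_f C_D A |u_rel| u_rel`, `T_o = -c_omega * omega_b`. The
#'   bluff-body law appropriate for a drag-borne diaspore; its speed coupling
#'   `|u_rel|` is what converts a horizontal gust into a transient vertical
#'   force (altitude gain).
#' * `zero_closure()`: no fluid loads (ballistic control).
#'
#' @param c Linear drag coefficient (N s m^-1), positive.
#' @param C_D Drag coefficient (dimensionless), positive.
#' @param A Reference area (m^2), positive.
#' @param c_omega Rotational damping coefficient (N m s), non-negative.
#' @return An object of class `aero_closure` with an `evaluate(u_rel, q,
#'   omega_b, medium, body)` function returning `list(force, torque)`.
#' @name aero_closures
NULL

new_aero_closure <- function(family, params, evaluate) {
  structure(list(family = family, params = params, evaluate = evaluate),
            class = "aero_closure")
}

#' @export
print.aero_closure <- function(x, ...) {
  ps <- paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)), collapse = ", ")
  cat(sprintf("<aero_closure> family '%s' (%s)\n", x$family, ps))
  invisible(x)
}

#' @rdname aero_closures
#' @export
zero_closure <- function() {
  new_aero_closure("zero", list(), function(u_rel, q, omega_b, medium, body) {
    list(force = c(0, 0, 0), torque = c(0, 0, 0))
  })
}

#' @rdname aero_closures
#' @export
linear_drag_closure <- function(c, c_omega = 0) {
  check_positive(c, "c")
  check_nonnegative(c_omega, "c_omega")
  new_aero_closure("linear", list(c = c, c_omega = c_omega),
    function(u_rel, q, omega_b, medium, body) {
      list(force = -c * u_rel, torque = -c_omega * omega_b)
    })
}

#' @rdname aero_closures
#' @export
quadratic_drag_closure <- function(C_D, A, c_omega = 0) {
  check_positive(C_D, "C_D")
  check_positive(A, "A")
  check_nonnegative(c_omega, "c_omega")
  new_aero_closure("quadratic", list(C_D = C_D, A = A, c_omega = c_omega),
    function(u_rel, q, omega_b, medium, body) {
      list(force = -0.5 * medium$density * C_D * A * norm3(u_rel) * u_rel,
           torque = -c_omega * omega_b)
    })
}

# Vertical fluid force on a body falling steadily at speed u (> 0) through
# quiescent fluid: upward (+x) component of the closure force.
vertical_drag <- function(u, body, medium, closure) {
  f <- closure$evaluate(c(-u, 0, 0), c(1, 0, 0, 0), c(0, 0, 0), medium, body)
  f$force[1L]
}

#' Terminal velocity of a body under a closure
#'
#' Solves the steady vertical force balance: the closure drag at fall speed
#' `u_t` equals the reduced weight `m g*`. Requires a falling body
#' (`g* > 0`); at neutral buoyancy there is no terminal fall and an error is
#' raised. The root is bracketed in `[1e-6, 1e3]` m/s and solved to ~1e-12
#' relative; for the built-in closures it matches the closed forms
#' `u_t = m g* / c` (linear) and `u_t = sqrt(2 m g* / (rho_f C_D A))`
#' (quadratic) to better than 1e-9 relative.
#'
#' @param body A [body_spec()].
#' @param medium A [fluid_medium()].
#' @param closure An [aero_closures] object, monotone in fall speed.
#' @return Terminal velocity (m s^-1), positive.
#' @export
terminal_velocity <- function(body, medium, closure) {
  stopifnot(inherits(body, "body_spec"), inherits(medium, "fluid_medium"),
            inherits(closure, "aero_closure"))
  g_star <- reduced_gravity(norm3(medium$gravity), medium$density, body$density)
  if (g_star <= 0) {
    stop("terminal velocity requires a falling body (reduced gravity > 0)", call. = FALSE)
  }
  w <- body$mass * g_star
  h <- function(u) vertical_drag(u, body, medium, closure) - w
  lo <- 1e-6; hi <- 1e3
  if (h(lo) > 0 || h(hi) < 0) {
    stop("closure inconsistency: no terminal-velocity bracket in [1e-6, 1e3] m/s",
         call. = FALSE)
  }
  stats::uniroot(h, c(lo, hi), tol = 1e-14)$root
}

#' Calibrate a closure to a target terminal velocity
#'
#' Inverse problem of [terminal_velocity()]: returns a closure of the requested
#' family whose terminal velocity equals `u_t_target`. Both built-in families
#' invert in closed form: `c = m g* / u_t` (linear) and
#' `C_D = 2 m g* / (rho_f A u_t^2)` (quadratic). This mirrors the experimental
#' procedure of setting the vertical tunnel airflow to match the measured
#' terminal velocity of the specimen.
#'
#' @param u_t_target Target terminal velocity (m s^-1), positive.
#' @param body A [body_spec()].
#' @param medium A [fluid_medium()].
#' @param family `"linear"` or `"quadratic"`.
#' @param A Reference area for the quadratic family (m^2); default
#'   `pi * body$length^2 / 4`.
#' @param c_omega Rotational damping passed through to the closure (N m s).
#' @return A calibrated [aero_closures] object.
#' @export
calibrate_closure_to_terminal_velocity <- function(u_t_target, body, medium,
                                                   family = c("linear", "quadratic"),
                                                   A = NULL, c_omega = 0) {
  check_positive(u_t_target, "u_t_target")
  stopifnot(inherits(body, "body_spec"), inherits(medium, "fluid_medium"))
  family <- match.arg(family)
  g_star <- reduced_gravity(norm3(medium$gravity), medium$density, body$density)
  if (g_star <= 0) {
    stop("calibration requires a falling body (reduced gravity > 0)", call. = FALSE)
  }
  w <- body$mass * g_star
  if (family == "linear") {
    linear_drag_closure(c = w / u_t_target, c_omega = c_omega)
  } else {
    if (is.null(A)) A <- pi * body$length^2 / 4
    check_positive(A, "A")
    C_D <- 2 * w / (medium$density * A * u_t_target^2)
    quadratic_drag_closure(C_D = C_D, A = A, c_omega = c_omega)
  }
}
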