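# Shared builders for the test suite. Media and bodies are plain physical
# choices: a dense millimetre-scale body falling in air (rho < 1) and a
# buoyant body rising in water (rho > 1).

std_air <- function() fluid_medium(density = 1.204, viscosity = 1.5e-5)
std_water <- function() fluid_medium(density = 1000, viscosity = 1e-6)

test_body_air <- function(e = 0.002) {
  body_spec(mass = 1e-6, density = 600, length = 0.01,
            inertia = diag(1e-11, 3), e = e, r_hat = c(1, 0, 0))
}

test_body_water <- function(e = 0.002) {
  body_spec(mass = 4e-4, density = 800, length = 0.01,
            inertia = diag(4e-9, 3), e = e, r_hat = c(1, 0, 0))
}

# The closure x gust x density-ratio matrix used by the frame-equivalence
# checks: closures none/linear/quadratic, gusts step/ramp/sine, one medium
# with rho < 1 (air) and one with rho > 1 (water).
equivalence_cases <- function() {
  gusts <- list(step = gust_step(0.4, t0 = 0.5),
                ramp = gust_ramp(t0 = 0.5, duration = 0.3, dv = 0.4),
                sine = gust_sine(0.3, omega = 4))
  cases <- expand.grid(closure = c("zero", "linear", "quadratic"),
                       gust = names(gusts), medium = c("air", "water"),
                       stringsAsFactors = FALSE)
  list(cases = cases, gusts = gusts)
}

equivalence_setup <- function(closure_name, medium_name) {
  medium <- if (medium_name == "air") std_air() else std_water()
  body <- if (medium_name == "air") test_body_air() else test_body_water()
  closure <- switch(closure_name,
    zero = zero_closure(),
    linear = linear_drag_closure(c = body$mass / 0.05, c_omega = 1e-9),
    quadratic = quadratic_drag_closure(C_D = 1, A = 1e-4, c_omega = 1e-9))
  list(body = body, medium = medium, closure = closure)
}
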