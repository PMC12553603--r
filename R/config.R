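#' Run configuration
#'
#' Runs are declared in a structured YAML file with explicit units in the key
#' names (`mass_kg`, `onset_s`, ...), so dimensional and dimensionless
#' statements cannot be silently confused. A configuration echoes back to an
#' identical run: every command writes a sidecar with the parsed config, the
#' seed and the package version.
#'
#' Top-level keys: `medium` (`density_kg_m3`, `viscosity_m2_s`,
#' `gravity_m_s2`), `body` (`mass_kg`, `density_kg_m3`, `length_m`,
#' `inertia_kgm2` — 3 diagonal or 9 row-major values — `eccentricity_m`,
#' `r_hat`), `closure` (`family` of `zero`/`linear`/`quadratic` with raw
#' coefficients `drag_N_s_m` or `drag_coefficient` + `reference_area_m2`, or a
#' `terminal_velocity_m_s` calibration target; `rotational_damping_Nms`),
#' `gust` (`kind` of `none`/`step`/`ramp`/`sine`/`tabulated` with the matching
#' parameters, or `file` for a two-column `t, u` table), `frame`
#' (`tunnel`/`inertial`), `inflow_m_s` (scalar upward component or length-3
#' vector), `time` (`start_s`, `end_s`, `output_dt_s`), `integrator` (`rtol`,
#' `atol`) and `seed`.
#'
#' @param path Path to a YAML configuration file.
#' @return An object of class `run_config`: the raw list plus parsed
#'   `medium`, `body`, `closure`, `gust` objects and integration settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  parse_run_config(raw, dir = dirname(path))
}

need_key <- function(x, key, where) {
  if (is.null(x[[key]])) {
    stop(sprintf("invalid config: missing key '%s' in '%s'", key, where), call. = FALSE)
  }
  x[[key]]
}

#' @rdname read_run_config
#' @param raw A configuration list (as parsed from YAML).
#' @param dir Directory against which relative file references are resolved.
#' @export
parse_run_config <- function(raw, dir = ".") {
  med <- need_key(raw, "medium", "config")
  medium <- fluid_medium(
    density = need_key(med, "density_kg_m3", "medium"),
    viscosity = need_key(med, "viscosity_m2_s", "medium"),
    gravity = c(-abs(need_key(med, "gravity_m_s2", "medium")), 0, 0))

  bd <- need_key(raw, "body", "config")
  inertia <- as.numeric(need_key(bd, "inertia_kgm2", "body"))
  if (length(inertia) == 9L) inertia <- matrix(inertia, 3, 3, byrow = TRUE)
  body <- body_spec(
    mass = need_key(bd, "mass_kg", "body"),
    density = need_key(bd, "density_kg_m3", "body"),
    length = need_key(bd, "length_m", "body"),
    inertia = inertia,
    e = if (is.null(bd$eccentricity_m)) 0 else bd$eccentricity_m,
    r_hat = if (is.null(bd$r_hat)) c(1, 0, 0) else as.numeric(bd$r_hat))

  cl <- need_key(raw, "closure", "config")
  family <- need_key(cl, "family", "closure")
  c_omega <- if (is.null(cl$rotational_damping_Nms)) 0 else cl$rotational_damping_Nms
  closure <- switch(family,
    zero = zero_closure(),
    linear = {
      if (!is.null(cl$terminal_velocity_m_s)) {
        calibrate_closure_to_terminal_velocity(cl$terminal_velocity_m_s, body,
                                               medium, "linear", c_omega = c_omega)
      } else {
        linear_drag_closure(need_key(cl, "drag_N_s_m", "closure"), c_omega)
      }
    },
    quadratic = {
      if (!is.null(cl$terminal_velocity_m_s)) {
        calibrate_closure_to_terminal_velocity(cl$terminal_velocity_m_s, body,
                                               medium, "quadratic",
                                               A = cl$reference_area_m2,
                                               c_omega = c_omega)
      } else {
        quadratic_drag_closure(need_key(cl, "drag_coefficient", "closure"),
                               need_key(cl, "reference_area_m2", "closure"),
                               c_omega)
      }
    },
    stop(sprintf("invalid config: unknown closure family '%s'", family), call. = FALSE))

  gu <- raw$gust
  gust <- if (is.null(gu) || identical(gu$kind, "none")) {
    gust_none()
  } else {
    dirv <- if (is.null(gu$direction)) c(0, 1, 0) else as.numeric(gu$direction)
    switch(need_key(gu, "kind", "gust"),
      step = gust_step(need_key(gu, "amplitude_m_s", "gust"),
                       t0 = if (is.null(gu$onset_s)) 0 else gu$onset_s,
                       direction = dirv),
      ramp = gust_ramp(t0 = if (is.null(gu$onset_s)) 0 else gu$onset_s,
                       duration = need_key(gu, "duration_s", "gust"),
                       dv = need_key(gu, "dv_m_s", "gust"), direction = dirv),
      sine = gust_sine(need_key(gu, "amplitude_m_s", "gust"),
                       need_key(gu, "omega_rad_s", "gust"),
                       phase = if (is.null(gu$phase_rad)) 0 else gu$phase_rad,
                       direction = dirv),
      tabulated = {
        f <- need_key(gu, "file", "gust")
        if (!file.exists(f)) f <- file.path(dir, f)
        tab <- utils::read.csv(f)
        gust_tabulated(tab[[1L]], tab[[2L]], direction = dirv)
      },
      stop(sprintf("invalid config: unknown gust kind '%s'", gu$kind), call. = FALSE))
  }

  inflow <- if (is.null(raw$inflow_m_s)) c(0, 0, 0) else {
    v <- as.numeric(raw$inflow_m_s)
    if (length(v) == 1L) c(v, 0, 0) else as_vec3(v, "inflow_m_s")
  }

  tm <- need_key(raw, "time", "config")
  times <- seq(if (is.null(tm$start_s)) 0 else tm$start_s,
               need_key(tm, "end_s", "time"),
               by = need_key(tm, "output_dt_s", "time"))
  frame <- if (is.null(raw$frame)) "tunnel" else raw$frame
  if (!frame %in% c("tunnel", "inertial")) {
    stop(sprintf("invalid config: unknown frame '%s'", frame), call. = FALSE)
  }
  intg <- raw$integrator
  structure(list(
    raw = raw, medium = medium, body = body, closure = closure, gust = gust,
    inflow = inflow, times = times, frame = frame,
    rtol = if (is.null(intg$rtol)) 1e-8 else intg$rtol,
    atol = if (is.null(intg$atol)) 1e-10 else intg$atol,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  ), class = "run_config")
}

write_sidecar <- function(config, out_dir, extra = list()) {
  meta <- c(list(
    package = "gustfall",
    version = as.character(utils::packageVersion("gustfall")),
    seed = config$seed,
    config = config$raw
  ), extra)
  yaml::write_yaml(meta, file.path(out_dir, "run_metadata.yaml"))
}

summarise_run <- function(config, traj) {
  body <- config$body; medium <- config$medium
  g_star <- reduced_gravity(norm3(medium$gravity), medium$density, body$density)
  u_t <- tryCatch(terminal_velocity(body, medium, config$closure),
                  error = function(e) NA_real_)
  theta <- trajectory_angle_z(traj)
  gmax <- if (inherits(config$gust, "gust_none")) 0 else {
    max(abs(gust_speed(config$gust, traj$t)))
  }
  summary <- list(
    rho = medium$density / body$density,
    g_star_m_s2 = g_star,
    terminal_velocity_m_s = u_t,
    gust_ratio = if (is.na(u_t) || u_t <= 0) NA_real_ else gust_ratio(gmax, u_t),
    max_abs_theta_rad = max(abs(theta)),
    net_height_change_m = traj$x[nrow(traj)] - traj$x[1L]
  )
  if (g_star == 0) {
    warning("neutral buoyancy: dimensionless scale block omitted from the summary")
  } else {
    sc <- scale_set(body, medium, u_t = if (is.na(u_t)) NULL else u_t)
    summary <- c(summary, list(u_g_m_s = sc$u_g, Ga = sc$Ga, Re = sc$Re))
  }
  summary
}

#' Run a configured simulation
#'
#' Integrates the configured gust encounter and writes `trajectory.csv`
#' (states plus per-term diagnostics), `summary.json` (scale groups, gust
#' ratio, peak stem angle, net height change) and a `run_metadata.yaml`
#' sidecar echoing the configuration.
#'
#' @param config A `run_config`, a configuration list, or a YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_simulate <- function(config, out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- simulate_trajectory(config$body, config$medium, config$closure,
                              config$gust, config$frame, config$inflow,
                              body_state(), config$times, config$rtol, config$atol)
  diag <- trajectory_forces(traj)
  utils::write.csv(cbind(as.data.frame(traj), diag[, -1L]),
                   file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  summary <- summarise_run(config, traj)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_sidecar(config, out_dir)
  invisible(summary)
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L) return(read_run_config(config))
  if (is.list(config)) return(parse_run_config(config))
  stop("'config' must be a run_config, a list, or a YAML file path", call. = FALSE)
}

#' Run a frame-equivalence check from a configuration
#'
#' Integrates the configured encounter in both the tunnel and the inertial
#' frame, maps the inertial result into the tunnel frame and reports the
#' maximum deviations together with a pass/fail verdict at ten times the
#' integrator tolerance (scaled by the trajectory's magnitude).
#'
#' @inheritParams run_simulate
#' @return Invisibly, the deviation report list.
#' @export
run_equivalence <- function(config, out_dir) {
  config <- as_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- run_frame_pair(config$body, config$medium, config$closure, config$gust,
                         config$inflow, body_state(), config$times,
                         config$rtol, config$atol)
  dev <- pair$deviation
  pos_scale <- max(1, max(abs(as.matrix(pair$tunnel[, c("x", "y", "z")]))))
  vel_scale <- max(1, max(abs(as.matrix(pair$tunnel[, c("u", "v", "w")]))))
  tol_pos <- 10 * (config$rtol * pos_scale + config$atol)
  tol_vel <- 10 * (config$rtol * vel_scale + config$atol)
  report <- list(
    position_deviation_m = dev$position,
    velocity_deviation_m_s = dev$velocity,
    quaternion_deviation = dev$quaternion,
    omega_deviation_rad_s = dev$omega,
    position_tolerance_m = tol_pos,
    velocity_tolerance_m_s = tol_vel,
    pass = dev$position <= tol_pos && dev$velocity <= tol_vel
  )
  jsonlite::write_json(report, file.path(out_dir, "equivalence.json"),
                       auto_unbox = TRUE, digits = NA)
  write_sidecar(config, out_dir)
  invisible(report)
}

#' Characterise a measured or synthetic flow field
#'
#' Reads a long-format field-series CSV and writes the uniformity map, the
#' turbulence-intensity map and a JSON summary.
#'
#' @param field_file Path to a [write_field_series()]-format CSV.
#' @param out_dir Output directory.
#' @param window Optional analysis window (`list(xlim=, ylim=)`, m).
#' @return Invisibly, the summary list.
#' @export
run_characterise <- function(field_file, out_dir, window = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fs <- read_field_series(field_file)
  uni <- flow_uniformity(fs, window)
  tur <- turbulence_intensity(fs, window)
  grid <- expand.grid(x = uni$x, y = uni$y, KEEP.OUT.ATTRS = FALSE)
  utils::write.csv(cbind(grid, normalised_speed = as.numeric(uni$normalised)),
                   file.path(out_dir, "uniformity_map.csv"), row.names = FALSE)
  utils::write.csv(cbind(grid, intensity = as.numeric(tur$map)),
                   file.path(out_dir, "turbulence_map.csv"), row.names = FALSE)
  summary <- list(
    mean_speed_m_s = uni$mean_speed,
    max_uniformity_deviation = uni$max_deviation,
    mean_turbulence_intensity = tur$mean_intensity,
    n_undefined_points = tur$n_undefined,
    n_frames = length(fs$times)
  )
  jsonlite::write_json(summary, file.path(out_dir, "characterise.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Extract kinematics from track files
#'
#' Reads one or two track CSVs (see [write_track_series()]) and writes the
#' de-noised kinematics. With two tracks (achene tip first, centroid second)
#' the stem-angle history is included.
#'
#' @param track_files Character vector of one or two track file paths.
#' @param out_dir Output directory.
#' @param window Moving-average window (samples), default 10.
#' @return Invisibly, the kinematics data frame.
#' @export
run_kinematics <- function(track_files, out_dir, window = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- lapply(track_files, read_track_series)
  kin <- track_kinematics(tracks[[1L]], window)
  if (length(tracks) >= 2L) {
    kin$theta <- stem_angle(tracks[[1L]], tracks[[2L]])$theta
  }
  utils::write.csv(kin, file.path(out_dir, "kinematics.csv"), row.names = FALSE)
  invisible(kin)
}

#' Write the standard fixture set
#'
#' Generates and writes the synthetic inputs that exercise every analysis
#' pipeline: the demonstration tunnel track (stop gust, seeded pixel noise),
#' a low-turbulence field series, and a ready-to-run demo configuration.
#'
#' @param out_dir Output directory.
#' @param seed RNG seed for the noisy fixtures.
#' @param n_frames Frames in the field-series fixture.
#' @return Invisibly, the vector of written file paths.
#' @export
write_fixture_files <- function(out_dir, seed = 1, n_frames = 200) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gust <- demo_gust_profile()
  track <- synth_tunnel_track(gust, duration = 0.4, noise_px = 1, seed = seed)
  track_path <- file.path(out_dir, "tunnel_track.csv")
  write_track_series(track, track_path)
  fs <- synth_field_series(n_frames = n_frames, seed = seed + 1L)
  field_path <- file.path(out_dir, "field_series.csv")
  write_field_series(fs, field_path)
  cfg <- list(
    medium = list(density_kg_m3 = 1.204, viscosity_m2_s = 1.5e-5, gravity_m_s2 = 9.81),
    body = list(mass_kg = 6e-7, density_kg_m3 = 60, length_m = 0.014,
                inertia_kgm2 = c(2e-12, 1.5e-11, 1.5e-11),
                eccentricity_m = 0.003, r_hat = c(1, 0, 0)),
    closure = list(family = "quadratic", terminal_velocity_m_s = 0.38,
                   rotational_damping_Nms = 1.2e-10),
    gust = list(kind = "step", amplitude_m_s = 0.76, onset_s = 0.1),
    frame = "tunnel",
    inflow_m_s = 0.38,
    time = list(start_s = 0, end_s = 4, output_dt_s = 0.005),
    integrator = list(rtol = 1e-8, atol = 1e-10),
    seed = as.integer(seed)
  )
  cfg_path <- file.path(out_dir, "demo_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(c(track_path, field_path, cfg_path))
}
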