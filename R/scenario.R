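# Scenario configuration: YAML/JSON configs tying materials, field, particle
# and run parameters into reproducible runs. SI units are mandatory and unit
# suffixes are part of the key names (_m, _pa, _hz, _s).

.schema_version <- 1L

config_error <- function(path, msg) {
  abort(sprintf("config field `%s`: %s", path, msg),
        class = "arftrace_config_error")
}

need_number <- function(x, path, positive = TRUE, len = 1L) {
  if (is.null(x)) config_error(path, "is required")
  x <- suppressWarnings(as.numeric(x))
  if (length(x) != len || any(!is.finite(x))) {
    config_error(path, sprintf("must be %d finite number(s)", len))
  }
  if (positive && any(x <= 0)) config_error(path, "must be positive")
  x
}

#' Read a scenario configuration
#'
#' Reads a YAML (or JSON) scenario file and validates it against the
#' published schema: a `schema_version`, a `scenario` type, `materials`,
#' `field`, `particle` and `run` blocks. Physical quantities carry SI unit
#' suffixes in their key names (`wavelength_m`, `peak_pressure_pa`, ...).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A validated scenario config (class `scenario_config`).
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_scenario(cfg)
}

#' Validate a scenario configuration
#'
#' @param config A list as produced by [read_scenario()] or built in code.
#' @return The config, invisibly classed `scenario_config`, with defaults
#'   filled in; aborts with the offending field path otherwise.
#' @export
validate_scenario <- function(config) {
  if (!is.list(config)) {
    abort("scenario config must be a mapping", class = "arftrace_config_error")
  }
  ver <- config$schema_version
  if (is.null(ver) || as.integer(ver) != .schema_version) {
    config_error("schema_version", sprintf("must be %d", .schema_version))
  }
  scen <- config$scenario
  if (is.null(scen) ||
      !scen %in% c("force_curve", "force_map", "separation", "trace")) {
    config_error("scenario",
                 "must be one of force_curve, force_map, separation, trace")
  }
  for (block in c("materials", "field", "particle", "run")) {
    if (is.null(config[[block]]) || !is.list(config[[block]])) {
      config_error(block, "block is required")
    }
  }
  # materials: builtin names or symbol-keyed mappings
  flu <- config$materials$fluid
  if (is.null(flu)) config_error("materials.fluid", "is required")
  if (is.character(flu) && !flu %in% c("water")) {
    config_error("materials.fluid", "unknown builtin (available: water)")
  }
  par <- config$materials$particle
  if (is.null(par)) config_error("materials.particle", "is required")
  if (is.character(par) && !par %in% c("nih3t3")) {
    config_error("materials.particle", "unknown builtin (available: nih3t3)")
  }
  need_number(config$field$wavelength_m, "field.wavelength_m")
  need_number(config$field$peak_pressure_pa, "field.peak_pressure_pa",
              len = length(config$field$peak_pressure_pa))
  if (!is.null(config$field$axes)) {
    axes <- config$field$axes
    if (!is.list(axes) && !is.matrix(axes)) {
      config_error("field.axes", "must be a list of unit vectors")
    }
  }
  need_number(config$particle$diameter_m, "particle.diameter_m")
  structure(config, class = c("scenario_config", "list"))
}

scenario_fluid <- function(config) {
  flu <- config$materials$fluid
  if (is.character(flu)) {
    water_properties()
  } else {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(flu, tmp)
    read_material_yaml(tmp, "fluid")
  }
}

scenario_particle <- function(config) {
  radius <- need_number(config$particle$diameter_m, "particle.diameter_m") / 2
  par <- config$materials$particle
  if (is.character(par)) {
    nih3t3_properties(radius = radius)
  } else {
    par$a <- radius
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(par, tmp)
    read_material_yaml(tmp, "particle")
  }
}

scenario_wave <- function(config, fluid) {
  fld <- config$field
  axes <- fld$axes
  if (is.null(axes)) axes <- list(c(0, 1))
  if (is.list(axes)) axes <- do.call(rbind, lapply(axes, as.numeric))
  phases <- fld$phases_rad
  if (is.null(phases)) phases <- 0
  standing_wave(
    wavelength = as.numeric(fld$wavelength_m),
    peak_pressure = as.numeric(fld$peak_pressure_pa),
    axes = axes, phases = as.numeric(phases), fluid = fluid
  )
}

# provenance log on stderr: every physical parameter actually used
log_scenario <- function(config, verbose = TRUE) {
  if (!verbose) return(invisible(NULL))
  fluid <- scenario_fluid(config)
  particle <- scenario_particle(config)
  message(sprintf(
    paste0("arftrace scenario=%s schema=%d hash=%s\n",
           "  fluid: rho0=%g c=%g beta=%g mu=%g\n",
           "  particle: rho0=%g beta=%g G=%g a=%g\n",
           "  field: lambda=%g p_ac=%s"),
    config$scenario, .schema_version, rlang::hash(config),
    fluid$density, fluid$sound_speed, fluid$compressibility,
    fluid$shear_viscosity,
    particle$density, particle$compressibility, particle$shear_modulus,
    particle$radius,
    as.numeric(config$field$wavelength_m),
    paste(as.numeric(config$field$peak_pressure_pa), collapse = ",")
  ))
  invisible(NULL)
}

#' Run a force-versus-size curve scenario
#'
#' Sweeps \eqn{D_p/\lambda} for the configured 1-D field and emits the
#' small-particle force, the closed-form finite-size force and the
#' volume-averaged quadrature force, plus the relative difference metric
#' between the latter two.
#'
#' @param config A validated scenario config (see [read_scenario()]) with
#'   `scenario: force_curve`. Recognised `run` keys: `ratios` (grid of
#'   \eqn{D_p/\lambda}; default 20 points on (0.05, 1]), `h_m` (node offset;
#'   default \eqn{\lambda/8}), `output_csv` (optional path).
#' @param verbose Log parameters to standard error.
#' @return The [force_curve()] tibble (attribute `difference_closed_quad`
#'   carries the metric).
#' @export
run_force_curve <- function(config, verbose = TRUE) {
  config <- validate_scenario(config)
  if (config$scenario != "force_curve") {
    config_error("scenario", "expected force_curve")
  }
  log_scenario(config, verbose)
  fluid <- scenario_fluid(config)
  particle <- scenario_particle(config)
  wavelength <- as.numeric(config$field$wavelength_m)
  ratios <- config$run$ratios
  if (is.null(ratios)) ratios <- seq(0.05, 1, length.out = 20)
  h <- if (is.null(config$run$h_m)) wavelength / 8 else
    as.numeric(config$run$h_m)
  out <- force_curve(fluid, particle, wavelength,
                     peak_pressure = as.numeric(config$field$peak_pressure_pa),
                     ratios = as.numeric(ratios), h = h)
  if (!is.null(config$run$output_csv)) {
    utils::write.csv(as.data.frame(out), config$run$output_csv,
                     row.names = FALSE)
  }
  out
}

#' Run a force-map scenario
#'
#' Samples both force models on the configured grid and forms the ratio map
#' `|F_finite| / |F_small|` (positions where the small-particle magnitude is
#' below `ratio_floor` of its maximum are masked `NA` — at node/antinode
#' lattice points both forces vanish and the ratio is undefined).
#'
#' @param config Scenario config with `scenario: force_map`. Recognised
#'   `run` keys: `bbox_m` (length-4 `c(xmin, xmax, ymin, ymax)`; default one
#'   wavelength square), `resolution` (points per wavelength, default 16),
#'   `ratio_floor` (default 1e-3), `output_prefix` (optional: writes
#'   `<prefix>_small.csv`, `<prefix>_finite.csv`, `<prefix>_ratio.csv`).
#' @inheritParams run_force_curve
#' @return A list with `small`, `finite` (force_grid tibbles) and `ratio`
#'   (tibble with `x`, `y`, `ratio`).
#' @export
run_force_map <- function(config, verbose = TRUE) {
  config <- validate_scenario(config)
  if (config$scenario != "force_map") {
    config_error("scenario", "expected force_map")
  }
  log_scenario(config, verbose)
  fluid <- scenario_fluid(config)
  particle <- scenario_particle(config)
  wave <- scenario_wave(config, fluid)
  lam <- wave$wavelength
  bbox <- config$run$bbox_m
  if (is.null(bbox)) bbox <- c(0, lam, 0, lam)
  resolution <- if (is.null(config$run$resolution)) 16 else
    as.numeric(config$run$resolution)
  coeffs <- scattering_coefficients(particle, fluid)
  small <- force_map(wave, particle, coeffs, bbox = as.numeric(bbox),
                     resolution = resolution, model = "small_particle")
  finite <- force_map(wave, particle, coeffs, bbox = as.numeric(bbox),
                      resolution = resolution, model = "finite_size")
  floor_frac <- if (is.null(config$run$ratio_floor)) 1e-3 else
    as.numeric(config$run$ratio_floor)
  floor_val <- floor_frac * max(small$f_mag)
  ratio <- tibble(
    x = small$x, y = small$y,
    ratio = ifelse(small$f_mag > floor_val,
                   finite$f_mag / small$f_mag, NA_real_)
  )
  if (!is.null(config$run$output_prefix)) {
    pre <- config$run$output_prefix
    utils::write.csv(as.data.frame(small), paste0(pre, "_small.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(finite), paste0(pre, "_finite.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ratio), paste0(pre, "_ratio.csv"),
                     row.names = FALSE)
  }
  list(small = small, finite = finite, ratio = ratio)
}

scenario_channel <- function(config) {
  run <- config$run
  channel_spec(
    width = need_number(run$channel_width_m, "run.channel_width_m"),
    length = need_number(run$channel_length_m, "run.channel_length_m"),
    mean_speed = need_number(run$mean_speed_m_s, "run.mean_speed_m_s"),
    profile = if (is.null(run$flow_profile)) "plug" else run$flow_profile,
    cuts = need_number(run$outlet_cuts_m, "run.outlet_cuts_m",
                       len = 2L)
  )
}

#' Run a separation scenario
#'
#' Traces the configured release positions through the channel under both
#' force models and reports outlet assignments.
#'
#' @param config Scenario config with `scenario: separation`. Required `run`
#'   keys: `channel_width_m`, `channel_length_m`, `mean_speed_m_s`,
#'   `outlet_cuts_m` (two values), `release_y_m` (>= 1 value). Optional:
#'   `flow_profile`, `models`, `force_scale`, `output_prefix` (writes
#'   `<prefix>_trajectories.csv` and `<prefix>_report.csv`).
#' @inheritParams run_force_curve
#' @return A list with `report` (a [simulate_separation()] result) and
#'   `trajectories` (tibble: `particle`, `model`, `t`, `x`, `y`).
#' @export
run_separation <- function(config, verbose = TRUE) {
  config <- validate_scenario(config)
  if (config$scenario != "separation") {
    config_error("scenario", "expected separation")
  }
  log_scenario(config, verbose)
  fluid <- scenario_fluid(config)
  particle <- scenario_particle(config)
  wave <- scenario_wave(config, fluid)
  channel <- scenario_channel(config)
  release_y <- need_number(config$run$release_y_m, "run.release_y_m",
                           len = length(config$run$release_y_m))
  models <- config$run$models
  if (is.null(models)) models <- c("small_particle", "finite_size")
  force_scale <- if (is.null(config$run$force_scale)) 1 else
    as.numeric(config$run$force_scale)
  report <- simulate_separation(channel, wave, particle, release_y,
                                models = models, force_scale = force_scale)
  transit <- channel$length / channel$mean_speed
  duration <- if (channel$profile == "plug") transit else 3 * transit
  trajs <- list()
  for (model in models) {
    for (i in seq_along(release_y)) {
      tr <- advance_trajectory(wave, particle, r0 = c(0, release_y[i]),
                               duration = duration, channel = channel,
                               model = model, force_scale = force_scale)
      trajs[[length(trajs) + 1L]] <- mutate(
        as_tibble(tr), particle = paste0("P", i), model = model,
        .before = 1
      )
    }
  }
  trajectories <- bind_rows(trajs)
  if (!is.null(config$run$output_prefix)) {
    pre <- config$run$output_prefix
    utils::write.csv(as.data.frame(trajectories),
                     paste0(pre, "_trajectories.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(report$assignments),
                     paste0(pre, "_report.csv"), row.names = FALSE)
  }
  list(report = report, trajectories = trajectories)
}

#' Run a single-trajectory scenario
#'
#' @param config Scenario config with `scenario: trace`. Required `run`
#'   keys: `r0_m` (length 2), `duration_s`. Optional: `model`, `n_out`,
#'   `output_csv`.
#' @inheritParams run_force_curve
#' @return A [advance_trajectory()] tibble.
#' @export
run_trace <- function(config, verbose = TRUE) {
  config <- validate_scenario(config)
  if (config$scenario != "trace") config_error("scenario", "expected trace")
  log_scenario(config, verbose)
  fluid <- scenario_fluid(config)
  particle <- scenario_particle(config)
  wave <- scenario_wave(config, fluid)
  r0 <- need_number(config$run$r0_m, "run.r0_m", positive = FALSE, len = 2L)
  duration <- need_number(config$run$duration_s, "run.duration_s")
  model <- if (is.null(config$run$model)) "small_particle" else
    config$run$model
  n_out <- if (is.null(config$run$n_out)) 201 else
    as.integer(config$run$n_out)
  out <- advance_trajectory(wave, particle, r0 = r0, duration = duration,
                            model = model, n_out = n_out)
  if (!is.null(config$run$output_csv)) {
    utils::write.csv(as.data.frame(out), config$run$output_csv,
                     row.names = FALSE)
  }
  out
}

#' Write the built-in scenario fixtures
#'
#' Writes the standard scenario configs used by the examples and tests to a
#' directory: the 1-D force-versus-size curve, the three-particle
#' separation fixture, the perpendicular-wave force maps at
#' \eqn{D_p/\lambda} = 0.2 and 0.4, and the reference material registries.
#' Re-running overwrites the same files with identical content.
#'
#' @param dir Target directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
generate_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- list(
    schema_version = .schema_version,
    materials = list(fluid = "water", particle = "nih3t3")
  )
  cfgs <- list(
    curve_1d = modifyList(base, list(
      scenario = "force_curve",
      field = list(wavelength_m = 60e-6, peak_pressure_pa = 2e5),
      particle = list(diameter_m = 10e-6),
      run = list(ratios = seq(0.05, 1, length.out = 20))
    )),
    separation_demo = modifyList(base, list(
      scenario = "separation",
      field = list(wavelength_m = 60e-6, peak_pressure_pa = 2e5),
      particle = list(diameter_m = 10e-6),
      run = list(channel_width_m = 240e-6, channel_length_m = 200e-6,
                 mean_speed_m_s = 1e-2, flow_profile = "plug",
                 outlet_cuts_m = c(108e-6, 132e-6),
                 release_y_m = c(110e-6, 114e-6, 118e-6))
    )),
    map_perp_02 = modifyList(base, list(
      scenario = "force_map",
      field = list(wavelength_m = 60e-6, peak_pressure_pa = 2e5,
                   axes = list(c(1, 0), c(0, 1)), phases_rad = c(0, 0)),
      particle = list(diameter_m = 12e-6),
      run = list(resolution = 16)
    )),
    map_perp_04 = modifyList(base, list(
      scenario = "force_map",
      field = list(wavelength_m = 60e-6, peak_pressure_pa = 2e5,
                   axes = list(c(1, 0), c(0, 1)), phases_rad = c(0, 0)),
      particle = list(diameter_m = 24e-6),
      run = list(resolution = 16)
    ))
  )
  paths <- character(0)
  for (nm in names(cfgs)) {
    validate_scenario(cfgs[[nm]])
    p <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfgs[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "water.yaml")
  write_material_yaml(water_properties(), p)
  paths <- c(paths, p)
  p <- file.path(dir, "nih3t3.yaml")
  write_material_yaml(nih3t3_properties(), p)
  paths <- c(paths, p)
  invisible(paths)
}
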