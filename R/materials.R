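# Material properties of the host fluid and suspended bio-particles, the
# derived-quantity formulas used to fill in missing table entries, and the
# validity diagnostics (boundary-layer thicknesses, acoustic impedance).
# All quantities are SI; there is no unit-conversion layer.

stop_domain <- function(msg) abort(msg, class = "arftrace_domain_error")

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x <= 0)) {
    stop_domain(sprintf("`%s` must be finite and strictly positive", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)) || any(x < 0)) {
    stop_domain(sprintf("`%s` must be finite and non-negative", name))
  }
  invisible(x)
}

#' Host-fluid acoustic and thermophysical properties
#'
#' Bundles the fluid-side material constants used throughout the package:
#' density \eqn{\rho_{f0}}, sound speed \eqn{c_f}, isentropic compressibility
#' \eqn{\beta_f}, shear and bulk viscosities, and the thermal parameters that
#' enter the boundary-layer diagnostics. If `compressibility` is omitted it is
#' filled in as \eqn{1/(\rho c^2)}; if supplied it must agree with that value
#' to within 0.1%.
#'
#' @param density Fluid density \eqn{\rho_{f0}} (kg m^-3).
#' @param sound_speed Speed of sound \eqn{c_f} (m s^-1).
#' @param compressibility Isentropic compressibility \eqn{\beta_f} (Pa^-1), or
#'   `NULL` to derive it from `density` and `sound_speed`.
#' @param shear_viscosity Dynamic (shear) viscosity \eqn{\mu} (Pa s).
#' @param bulk_viscosity Bulk viscosity \eqn{\mu_b} (Pa s).
#' @param thermal_expansion Thermal expansion coefficient \eqn{\alpha} (K^-1).
#' @param specific_heat Specific heat at constant pressure \eqn{h_c}
#'   (J kg^-1 K^-1).
#' @param heat_ratio Ratio of specific heats \eqn{\gamma} (dimensionless).
#' @param thermal_conductivity Thermal conductivity \eqn{k_t} (W m^-1 K^-1).
#' @param name Optional label carried along for printing and logs.
#'
#' @return An object of class `fluid_properties` (a named list).
#' @seealso [water_properties()], [particle_properties()]
#' @export
#' @examples
#' fluid_properties(density = 1e3, sound_speed = 1.502e3,
#'                  shear_viscosity = 8.538e-4)
fluid_properties <- function(density, sound_speed, compressibility = NULL,
                             shear_viscosity = NA_real_,
                             bulk_viscosity = NA_real_,
                             thermal_expansion = NA_real_,
                             specific_heat = NA_real_,
                             heat_ratio = NA_real_,
                             thermal_conductivity = NA_real_,
                             name = "fluid") {
  check_positive(density, "density")
  check_positive(sound_speed, "sound_speed")
  beta_ref <- 1 / (density * sound_speed^2)
  if (is.null(compressibility)) {
    compressibility <- beta_ref
  } else {
    check_positive(compressibility, "compressibility")
    if (abs(compressibility - beta_ref) / beta_ref > 1e-3) {
      stop_domain(paste0(
        "`compressibility` is inconsistent with 1/(density * sound_speed^2) ",
        "by more than 0.1%"
      ))
    }
  }
  for (nm in c("shear_viscosity", "bulk_viscosity", "thermal_expansion",
               "specific_heat", "heat_ratio", "thermal_conductivity")) {
    val <- get(nm)
    if (!is.na(val)) check_positive(val, nm)
  }
  structure(
    list(
      name = name,
      density = density,
      sound_speed = sound_speed,
      compressibility = compressibility,
      shear_viscosity = shear_viscosity,
      bulk_viscosity = bulk_viscosity,
      thermal_expansion = thermal_expansion,
      specific_heat = specific_heat,
      heat_ratio = heat_ratio,
      thermal_conductivity = thermal_conductivity
    ),
    class = "fluid_properties"
  )
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat("<fluid_properties>", x$name, "\n")
  cat(sprintf("  density        %g kg/m^3\n", x$density))
  cat(sprintf("  sound speed    %g m/s\n", x$sound_speed))
  cat(sprintf("  compressibility %g 1/Pa\n", x$compressibility))
  if (!is.na(x$shear_viscosity))
    cat(sprintf("  shear viscosity %g Pa s\n", x$shear_viscosity))
  invisible(x)
}

#' Bio-particle material properties
#'
#' Density, isentropic compressibility, shear modulus and radius of a
#' suspended bio-particle (cell, liposome, microvesicle, virus). The
#' diameter is always exactly `2 * radius`. Longitudinal and shear wave
#' speeds may be supplied (e.g. tabulated values) or derived with
#' [longitudinal_speed()] and [shear_speed()].
#'
#' @param density Particle density \eqn{\rho_{p0}} (kg m^-3).
#' @param compressibility Isentropic compressibility \eqn{\beta_p} (Pa^-1).
#' @param radius Particle radius \eqn{a} (m).
#' @param shear_modulus Shear modulus \eqn{G} (Pa); 0 for a fluid-like
#'   particle.
#' @param longitudinal_speed Optional longitudinal (compressional) wave speed
#'   \eqn{c_p} (m s^-1).
#' @param shear_speed Optional transverse (shear) wave speed \eqn{c_s}
#'   (m s^-1).
#' @param name Optional label.
#'
#' @return An object of class `particle_properties` (a named list) with a
#'   `diameter` field equal to `2 * radius`.
#' @export
#' @examples
#' particle_properties(density = 1.079e3, compressibility = 3.78e-10,
#'                     radius = 5e-6, shear_modulus = 1.67e3)
particle_properties <- function(density, compressibility, radius,
                                shear_modulus = 0,
                                longitudinal_speed = NA_real_,
                                shear_speed = NA_real_,
                                name = "particle") {
  check_positive(density, "density")
  check_positive(compressibility, "compressibility")
  check_positive(radius, "radius")
  check_nonnegative(shear_modulus, "shear_modulus")
  structure(
    list(
      name = name,
      density = density,
      compressibility = compressibility,
      shear_modulus = shear_modulus,
      radius = radius,
      diameter = 2 * radius,
      longitudinal_speed = longitudinal_speed,
      shear_speed = shear_speed
    ),
    class = "particle_properties"
  )
}

#' @export
print.particle_properties <- function(x, ...) {
  cat("<particle_properties>", x$name, "\n")
  cat(sprintf("  density         %g kg/m^3\n", x$density))
  cat(sprintf("  compressibility %g 1/Pa\n", x$compressibility))
  cat(sprintf("  shear modulus   %g Pa\n", x$shear_modulus))
  cat(sprintf("  radius          %g m (diameter %g m)\n", x$radius, x$diameter))
  invisible(x)
}

#' Particle volume
#' @param particle A [particle_properties()] object.
#' @return Sphere volume \eqn{4\pi a^3/3} (m^3).
#' @export
particle_volume <- function(particle) {
  4 / 3 * pi * particle$radius^3
}

# ---- derived-quantity formulas ---------------------------------------------

#' Isentropic compressibility from density and sound speed
#'
#' \eqn{\beta = 1/(\rho c^2)}.
#'
#' @param density Density \eqn{\rho} (kg m^-3).
#' @param sound_speed Sound speed \eqn{c} (m s^-1).
#' @return Compressibility (Pa^-1).
#' @export
#' @examples
#' compressibility_from_speed(1.0e3, 1.502e3) # water: 4.433e-10
compressibility_from_speed <- function(density, sound_speed) {
  check_positive(density, "density")
  check_positive(sound_speed, "sound_speed")
  1 / (density * sound_speed^2)
}

#' Poisson ratio from shear and bulk moduli
#'
#' \eqn{\nu = (3\kappa - 2G) / (2(3\kappa + G))}. For a nearly
#' incompressible soft particle (\eqn{G \ll \kappa}) the ratio approaches
#' 1/2.
#'
#' @param shear_modulus Shear modulus \eqn{G} (Pa), non-negative.
#' @param bulk_modulus Bulk modulus \eqn{\kappa = 1/\beta} (Pa), positive.
#' @return Dimensionless Poisson ratio.
#' @export
#' @examples
#' poisson_ratio(1.67e3, 1 / 3.78e-10) # ~0.5 for an NIH/3T3 cell
poisson_ratio <- function(shear_modulus, bulk_modulus) {
  check_nonnegative(shear_modulus, "shear_modulus")
  check_positive(bulk_modulus, "bulk_modulus")
  (3 * bulk_modulus - 2 * shear_modulus) /
    (2 * (3 * bulk_modulus + shear_modulus))
}

#' Longitudinal (compressional) wave speed of a nearly incompressible solid
#'
#' \eqn{c = \sqrt{ [3(1-\nu)/(1+\nu)] / (\rho \beta) }}. At \eqn{\nu = 1/2}
#' this reduces to the fluid relation \eqn{c = 1/\sqrt{\rho\beta}}, making it
#' the exact inverse of [compressibility_from_speed()].
#'
#' @param density Density \eqn{\rho} (kg m^-3).
#' @param compressibility Isentropic compressibility \eqn{\beta} (Pa^-1).
#' @param poisson Poisson ratio \eqn{\nu}, in \eqn{[0, 0.5]} (a small
#'   numerical overshoot above 0.5 is tolerated).
#' @return Wave speed (m s^-1).
#' @export
#' @examples
#' longitudinal_speed(1.079e3, 3.78e-10, 0.5) # ~1566 m/s
longitudinal_speed <- function(density, compressibility, poisson) {
  check_positive(density, "density")
  check_positive(compressibility, "compressibility")
  if (!is.numeric(poisson) || !is.finite(poisson) || poisson < 0 ||
      poisson >= 1) {
    stop_domain("`poisson` must lie in [0, 1)")
  }
  sqrt((3 * (1 - poisson) / (1 + poisson)) / (density * compressibility))
}

#' Transverse (shear) wave speed
#'
#' \eqn{c_s = \sqrt{G/\rho}}.
#'
#' @param shear_modulus Shear modulus \eqn{G} (Pa), non-negative.
#' @param density Density \eqn{\rho} (kg m^-3).
#' @return Wave speed (m s^-1).
#' @export
shear_speed <- function(shear_modulus, density) {
  check_nonnegative(shear_modulus, "shear_modulus")
  check_positive(density, "density")
  sqrt(shear_modulus / density)
}

#' Specific acoustic impedance
#'
#' \eqn{Z = \rho c}. The finite-size force model assumes the particle
#' impedance is close to the fluid impedance, so the incident field is a good
#' stand-in for the transmitted field inside the particle; comparing the two
#' impedances is the first validity check for that assumption.
#'
#' @param density Density (kg m^-3).
#' @param sound_speed Sound speed (m s^-1).
#' @return Impedance (Pa s m^-1).
#' @export
acoustic_impedance <- function(density, sound_speed) {
  check_positive(density, "density")
  check_positive(sound_speed, "sound_speed")
  density * sound_speed
}

#' Viscous boundary-layer (penetration) depth
#'
#' \eqn{\delta_v = \sqrt{2\mu / (\rho\,\omega)}} with
#' \eqn{\omega = 2\pi f}. When \eqn{\delta_v} is much smaller than the
#' particle radius the ideal-fluid scattering coefficients are adequate.
#'
#' @param viscosity Shear viscosity \eqn{\mu} (Pa s).
#' @param density Fluid density (kg m^-3).
#' @param frequency Acoustic frequency \eqn{f} (Hz).
#' @return Depth (m); strictly decreasing in `frequency` as \eqn{f^{-1/2}}.
#' @export
#' @examples
#' viscous_penetration_depth(8.538e-4, 1e3, 1e6) # ~0.52 um at 1 MHz
viscous_penetration_depth <- function(viscosity, density, frequency) {
  check_positive(viscosity, "viscosity")
  check_positive(density, "density")
  check_positive(frequency, "frequency")
  sqrt(2 * viscosity / (density * 2 * pi * frequency))
}

#' Thermal boundary-layer (penetration) depth
#'
#' \eqn{\delta_t = \sqrt{2 D_{th} / \omega}} with thermal diffusivity
#' \eqn{D_{th} = k_t / (\rho h_c)}.
#'
#' @param thermal_conductivity \eqn{k_t} (W m^-1 K^-1).
#' @param density Fluid density (kg m^-3).
#' @param specific_heat \eqn{h_c} (J kg^-1 K^-1).
#' @param frequency Acoustic frequency (Hz).
#' @return Depth (m); scales as \eqn{f^{-1/2}}.
#' @export
thermal_penetration_depth <- function(thermal_conductivity, density,
                                      specific_heat, frequency) {
  check_positive(thermal_conductivity, "thermal_conductivity")
  check_positive(density, "density")
  check_positive(specific_heat, "specific_heat")
  check_positive(frequency, "frequency")
  d_th <- thermal_conductivity / (density * specific_heat)
  sqrt(2 * d_th / (2 * pi * frequency))
}

#' Small-particle / ideal-fluid validity diagnostics
#'
#' Summarises, for a given fluid, particle and frequency, the quantities that
#' decide which force model is appropriate: the viscous and thermal
#' boundary-layer depths relative to the particle radius, the size parameter
#' \eqn{\chi = ka}, and the particle/fluid impedance ratio.
#'
#' @param fluid A [fluid_properties()] object.
#' @param particle A [particle_properties()] object.
#' @param frequency Acoustic frequency (Hz).
#' @return A one-row tibble with columns `frequency`, `delta_v`, `delta_t`,
#'   `delta_v_over_a`, `delta_t_over_a`, `chi` and `impedance_ratio`.
#' @export
validity_diagnostics <- function(fluid, particle, frequency) {
  check_positive(frequency, "frequency")
  dv <- viscous_penetration_depth(fluid$shear_viscosity, fluid$density,
                                  frequency)
  dt <- thermal_penetration_depth(fluid$thermal_conductivity, fluid$density,
                                  fluid$specific_heat, frequency)
  wavelength <- fluid$sound_speed / frequency
  chi <- 2 * pi / wavelength * particle$radius
  cp <- particle$longitudinal_speed
  if (is.na(cp)) {
    cp <- longitudinal_speed(particle$density, particle$compressibility, 0.5)
  }
  z_ratio <- acoustic_impedance(particle$density, cp) /
    acoustic_impedance(fluid$density, fluid$sound_speed)
  tibble(
    frequency = frequency,
    delta_v = dv,
    delta_t = dt,
    delta_v_over_a = dv / particle$radius,
    delta_t_over_a = dt / particle$radius,
    chi = chi,
    impedance_ratio = z_ratio
  )
}

# ---- built-in registries ---------------------------------------------------

#' Water at 25 degrees C
#'
#' Reference host-fluid registry used by the worked examples and fixtures.
#' Stored constants: density 1.0e3 kg/m^3, sound speed 1.502e3 m/s,
#' compressibility 4.433e-10 1/Pa, shear viscosity 8.538e-4 Pa s, bulk
#' viscosity 2.4e-3 Pa s, thermal expansion 2.748e-4 1/K, specific heat
#' 4.181e3 J/(kg K), heat ratio 1.012, thermal conductivity 6.095e-1 W/(m K).
#'
#' @return A [fluid_properties()] object.
#' @export
#' @examples
#' water_properties()$compressibility
water_properties <- function() {
  fluid_properties(
    density = 1.0e3,
    sound_speed = 1.502e3,
    compressibility = 4.433e-10,
    shear_viscosity = 8.538e-4,
    bulk_viscosity = 2.4e-3,
    thermal_expansion = 2.748e-4,
    specific_heat = 4.181e3,
    heat_ratio = 1.012,
    thermal_conductivity = 6.095e-1,
    name = "water (25 C)"
  )
}

#' NIH/3T3 fibroblast cell
#'
#' Reference bio-particle registry: density 1.079e3 kg/m^3, isentropic
#' compressibility 3.78e-10 1/Pa, shear modulus 1.67e3 Pa, with tabulated
#' longitudinal wave speed 1.566e3 m/s (consistent with
#' [longitudinal_speed()] at Poisson ratio ~0.5) and tabulated transverse
#' wave speed 1.244e3 m/s. Note: the tabulated transverse speed is
#' inconsistent with `shear_speed(1.67e3, 1.079e3)` = 1.244 m/s — the
#' significand matches but the stored constant keeps the tabulated exponent;
#' derived-quantity helpers always follow the formulas.
#'
#' @param radius Particle radius (m); default 5e-6 (a 10 um cell).
#' @return A [particle_properties()] object.
#' @export
nih3t3_properties <- function(radius = 5e-6) {
  particle_properties(
    density = 1.079e3,
    compressibility = 3.78e-10,
    radius = radius,
    shear_modulus = 1.67e3,
    longitudinal_speed = 1.566e3,
    shear_speed = 1.244e3,
    name = "NIH/3T3 cell"
  )
}

#' Thermal side-channel registry for the NIH/3T3 cell
#'
#' The cell-side thermal constants (not needed for the ideal-fluid force
#' model, kept for completeness of the registry): thermal expansion 2.0e-4
#' 1/K, specific heat 3.421e3 J/(kg K), heat ratio 1.012, thermal
#' conductivity 4.9e-1 W/(m K).
#'
#' @return A named list of the four thermal constants.
#' @export
nih3t3_thermal_properties <- function() {
  list(
    thermal_expansion = 2.0e-4,
    specific_heat = 3.421e3,
    heat_ratio = 1.012,
    thermal_conductivity = 4.9e-1
  )
}

#' Approximate acoustic presets for common bio-particle classes
#'
#' Illustrative (approximate, order-of-magnitude) density and longitudinal
#' sound-speed entries for the bio-particle classes commonly manipulated in
#' acoustofluidic devices. These are presets for quick impedance-closeness
#' checks and demos, not measured constants; use [particle_properties()] with
#' your own values for quantitative work.
#'
#' @return A tibble with columns `class`, `density`, `sound_speed`,
#'   `impedance` and `approximate` (always `TRUE`).
#' @export
bioparticle_presets <- function() {
  out <- tibble(
    class = c("cell", "liposome", "microvesicle", "virus"),
    density = c(1.08e3, 1.02e3, 1.10e3, 1.17e3),
    sound_speed = c(1.55e3, 1.49e3, 1.57e3, 1.60e3),
    approximate = TRUE
  )
  mutate(out, impedance = .data$density * .data$sound_speed)
}

# ---- YAML interface --------------------------------------------------------

# symbol-keyed YAML mapping <-> property objects
.material_keys <- c("rho0", "c", "beta", "G", "mu", "mu_b", "alpha",
                    "h_c", "gamma", "k_t", "a")

#' Read material properties from a YAML mapping
#'
#' The mapping is keyed by the conventional symbols: `rho0` (density), `c`
#' (sound speed), `beta` (compressibility), `G` (shear modulus), `mu`
#' (shear viscosity), `mu_b` (bulk viscosity), `alpha` (thermal expansion),
#' `h_c` (specific heat), `gamma` (heat ratio), `k_t` (thermal
#' conductivity), and, for particles, `a` (radius). Unknown keys are
#' rejected.
#'
#' @param path Path to a YAML file.
#' @param type `"fluid"` or `"particle"`.
#' @return A [fluid_properties()] or [particle_properties()] object.
#' @export
read_material_yaml <- function(path, type = c("fluid", "particle")) {
  type <- match.arg(type)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_domain("material YAML must be a mapping")
  unknown <- setdiff(names(raw), .material_keys)
  if (length(unknown) > 0) {
    stop_domain(paste0("unknown material keys: ",
                       paste(unknown, collapse = ", ")))
  }
  get_key <- function(key, default = NA_real_) {
    if (is.null(raw[[key]])) default else as.numeric(raw[[key]])
  }
  if (type == "fluid") {
    fluid_properties(
      density = get_key("rho0"),
      sound_speed = get_key("c"),
      compressibility = if (is.null(raw[["beta"]])) NULL else
        as.numeric(raw[["beta"]]),
      shear_viscosity = get_key("mu"),
      bulk_viscosity = get_key("mu_b"),
      thermal_expansion = get_key("alpha"),
      specific_heat = get_key("h_c"),
      heat_ratio = get_key("gamma"),
      thermal_conductivity = get_key("k_t"),
      name = basename(path)
    )
  } else {
    if (is.null(raw[["a"]])) stop_domain("particle YAML requires radius `a`")
    particle_properties(
      density = get_key("rho0"),
      compressibility = get_key("beta"),
      radius = get_key("a"),
      shear_modulus = get_key("G", 0),
      longitudinal_speed = get_key("c"),
      name = basename(path)
    )
  }
}

#' Write material properties to a YAML mapping
#'
#' Inverse of [read_material_yaml()]; only non-missing fields are written.
#'
#' @param material A [fluid_properties()] or [particle_properties()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_material_yaml <- function(material, path) {
  if (inherits(material, "fluid_properties")) {
    vals <- list(rho0 = material$density, c = material$sound_speed,
                 beta = material$compressibility,
                 mu = material$shear_viscosity,
                 mu_b = material$bulk_viscosity,
                 alpha = material$thermal_expansion,
                 h_c = material$specific_heat,
                 gamma = material$heat_ratio,
                 k_t = material$thermal_conductivity)
  } else if (inherits(material, "particle_properties")) {
    vals <- list(rho0 = material$density, beta = material$compressibility,
                 G = material$shear_modulus, a = material$radius,
                 c = material$longitudinal_speed)
  } else {
    stop_domain("`material` must be fluid_properties or particle_properties")
  }
  vals <- vals[!vapply(vals, function(v) is.null(v) || is.na(v), logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
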