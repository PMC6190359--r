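# Acoustic radiation force on a suspended particle in a standing field.
#
# Small-particle (Gorkov) route: the force is the negative gradient of the
# radiation potential
#
#   U = V ( f1 beta_f/2 <p^2> - f2 3 rho_f0/4 <v^2> )
#
# evaluated from the incident first-order field, with the ideal-fluid
# monopole/dipole scattering coefficients. With <p^2> = A^2/2 and
# <v^2> = |grad A|^2/(2 rho^2 w^2) the analytic gradient is
#
#   F = -V ( f1 beta/2 A grad A  -  3 f2/(4 rho w^2) H_A grad A )
#
# Finite-size route: the same force field volume-averaged over the particle
# ball (the particle's acoustic impedance being close to the fluid's, the
# incident field stands in for the transmitted one). On a 1-D field the
# average has the closed form F1D = F1Ds * f_m(chi), chi = ka.

#' Ideal-fluid monopole scattering coefficient
#'
#' \eqn{f_1 = 1 - \beta_p/\beta_f}: the compressibility contrast of the
#' particle against the host fluid.
#'
#' @param particle_compressibility \eqn{\beta_p} (Pa^-1).
#' @param fluid_compressibility \eqn{\beta_f} (Pa^-1).
#' @return Dimensionless coefficient.
#' @export
#' @examples
#' monopole_coefficient(3.78e-10, 4.433e-10) # ~0.147 for a cell in water
monopole_coefficient <- function(particle_compressibility,
                                 fluid_compressibility) {
  check_positive(particle_compressibility, "particle_compressibility")
  check_positive(fluid_compressibility, "fluid_compressibility")
  1 - particle_compressibility / fluid_compressibility
}

#' Ideal-fluid dipole scattering coefficient
#'
#' \eqn{f_2 = 2(\rho_{p0} - \rho_{f0}) / (2\rho_{p0} + \rho_{f0})}: the
#' density contrast.
#'
#' @param particle_density \eqn{\rho_{p0}} (kg m^-3).
#' @param fluid_density \eqn{\rho_{f0}} (kg m^-3).
#' @return Dimensionless coefficient.
#' @export
dipole_coefficient <- function(particle_density, fluid_density) {
  check_positive(particle_density, "particle_density")
  check_positive(fluid_density, "fluid_density")
  2 * (particle_density - fluid_density) /
    (2 * particle_density + fluid_density)
}

#' Scattering coefficients and acoustic contrast factor
#'
#' Bundles the ideal-fluid monopole and dipole coefficients for a
#' particle/fluid pair with the acoustic contrast factor
#' \eqn{\Phi = \mathrm{Re}(f_1)/3 + \mathrm{Re}(f_2)/2}. The sign of
#' \eqn{\Phi} decides whether the particle migrates to pressure nodes
#' (positive) or antinodes (negative). Coefficients are kept through a
#' `Re()` accessor so complex-valued (viscous/thermoviscous) extensions do
#' not change the interface; the ideal-fluid values here are real.
#'
#' @param particle A [particle_properties()] object.
#' @param fluid A [fluid_properties()] object.
#' @return An object of class `scattering_coefficients` with fields `f1`,
#'   `f2` and `contrast_factor`.
#' @export
#' @examples
#' scattering_coefficients(nih3t3_properties(), water_properties())
scattering_coefficients <- function(particle, fluid) {
  f1 <- monopole_coefficient(particle$compressibility, fluid$compressibility)
  f2 <- dipole_coefficient(particle$density, fluid$density)
  structure(
    list(
      f1 = f1,
      f2 = f2,
      contrast_factor = Re(f1) / 3 + Re(f2) / 2
    ),
    class = "scattering_coefficients"
  )
}

#' @export
print.scattering_coefficients <- function(x, ...) {
  cat("<scattering_coefficients>\n")
  cat(sprintf("  f1 (monopole)   %.6g\n", Re(x$f1)))
  cat(sprintf("  f2 (dipole)     %.6g\n", Re(x$f2)))
  cat(sprintf("  contrast factor %.6g\n", x$contrast_factor))
  invisible(x)
}

#' Gorkov radiation potential
#'
#' \eqn{U = V_{BP}(\mathrm{Re}(f_1)\,\beta_f/2\,\langle p^2\rangle -
#' \mathrm{Re}(f_2)\,3\rho_{f0}/4\,\langle v^2\rangle)}. Takes a tibble of
#' field samples (as from [field_quantities()]) and appends the potential.
#'
#' @param samples A tibble with columns `p_sq` and `v_sq`.
#' @param coeffs A [scattering_coefficients()] object.
#' @param volume Particle volume \eqn{V_{BP}} (m^3), see
#'   [particle_volume()].
#' @param fluid A [fluid_properties()] object.
#' @return `samples` with an added `u_rad` column (J).
#' @export
gorkov_potential <- function(samples, coeffs, volume, fluid) {
  check_positive(volume, "volume")
  mutate(
    samples,
    u_rad = volume * (Re(coeffs$f1) * fluid$compressibility / 2 * .data$p_sq -
                        Re(coeffs$f2) * 3 * fluid$density / 4 * .data$v_sq)
  )
}

# Analytic small-particle force, vectorised: returns n x dim matrix (N).
small_particle_force_matrix <- function(wave, positions, particle, coeffs) {
  fa <- field_amplitude(wave, positions, need_hess = TRUE)
  v_bp <- particle_volume(particle)
  fluid <- wave$fluid
  # 1/(rho omega^2) written as beta/k^2 (compressibility-consistent speed)
  c1 <- Re(coeffs$f1) * fluid$compressibility / 2
  c2 <- 3 * Re(coeffs$f2) * fluid$compressibility / (4 * wave$wavenumber^2)
  n <- length(fa$amp)
  d <- wave$dim
  hg <- matrix(0, n, d)                  # H_A %*% grad A, row-wise
  for (p in seq_len(d)) {
    acc <- numeric(n)
    for (q in seq_len(d)) acc <- acc + fa$hess[, p, q] * fa$grad[, q]
    hg[, p] <- acc
  }
  -v_bp * (c1 * fa$amp * fa$grad - c2 * hg)
}

force_tibble <- function(positions, fmat, dim) {
  coords <- as_tibble(as.data.frame(as_position_matrix(positions, dim)))
  names(coords) <- c("x", "y", "z")[seq_len(dim)]
  ftib <- as_tibble(as.data.frame(fmat))
  names(ftib) <- paste0("f", c("x", "y", "z")[seq_len(dim)])
  bind_cols(coords, ftib)
}

#' Small-particle (Gorkov) radiation force
#'
#' \eqn{F^s = -\nabla U}, evaluated analytically from the closed-form
#' standing-wave amplitude and its derivatives. Valid when the particle is
#' much smaller than the wavelength (\eqn{ka \ll 1}).
#'
#' @param wave A [standing_wave()] object.
#' @param positions Position(s): vector, matrix or data frame.
#' @param particle A [particle_properties()] object.
#' @param coeffs A [scattering_coefficients()] object; computed from
#'   `particle` and the wave's fluid when `NULL`.
#' @return A tibble with coordinate columns and force components `fx`, `fy`
#'   (, `fz`) in newtons.
#' @export
#' @examples
#' w <- standing_wave(60e-6, 2e5, fluid = water_properties())
#' small_particle_force(w, cbind(0, 7.5e-6), nih3t3_properties())
small_particle_force <- function(wave, positions, particle, coeffs = NULL) {
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  fmat <- small_particle_force_matrix(wave, positions, particle, coeffs)
  force_tibble(positions, fmat, wave$dim)
}

#' Closed-form 1-D small-particle force
#'
#' For a one-directional standing field \eqn{p = p_{ac}\cos(ky)} the Gorkov
#' force reduces to \eqn{F^s_{1D} = 4\pi\Phi a^3 k E_{ac}\sin(2kh)}, where
#' `h` is the particle's offset from the nearest pressure node measured so
#' that the returned signed force points toward the node when the contrast
#' factor \eqn{\Phi} is positive (equivalently, `h` is the node position
#' minus the particle position along the axis).
#'
#' @param h Offset from the nearest pressure node (m); may be a vector.
#' @param radius Particle radius \eqn{a} (m).
#' @param wavenumber \eqn{k = 2\pi/\lambda} (m^-1).
#' @param energy_density \eqn{E_{ac}} (J m^-3), see
#'   [acoustic_energy_density()].
#' @param contrast_factor \eqn{\Phi}, see [scattering_coefficients()].
#' @return Signed force (N) along the axis.
#' @export
#' @examples
#' # maximal at h = lambda/8
#' closed_form_1d(60e-6 / 8, 5e-6, 2 * pi / 60e-6, 4.433, 0.0741)
closed_form_1d <- function(h, radius, wavenumber, energy_density,
                           contrast_factor) {
  check_positive(radius, "radius")
  check_positive(wavenumber, "wavenumber")
  4 * pi * contrast_factor * radius^3 * wavenumber * energy_density *
    sin(2 * wavenumber * h)
}

#' Finite-size modifying factor
#'
#' The ratio of the volume-averaged 1-D force to the small-particle value,
#' \deqn{f_m(\chi) = 3\,[\sin(2\chi) - 2\chi\cos(2\chi)]\,/\,(2\chi)^3,
#' \quad \chi = ka.}
#' It equals 1 in the point-particle limit, decreases with \eqn{\chi}, and
#' first crosses zero at \eqn{D_p \approx 0.72\lambda} (see
#' [zero_crossing_ratio()]). Below \eqn{\chi = 10^{-3}} the Taylor series
#' \eqn{1 - (2\chi)^2/10 + (2\chi)^4/280} is used to avoid cancellation.
#'
#' @param chi Size parameter \eqn{\chi = ka \ge 0}; vectorised.
#' @return Dimensionless factor.
#' @export
#' @examples
#' modifying_factor(pi * 10 / 60) # ~0.894 for a 10 um particle, 60 um wave
modifying_factor <- function(chi) {
  check_nonnegative(chi, "chi")
  x <- 2 * chi
  small <- chi < 1e-3
  out <- numeric(length(chi))
  out[small] <- 1 - x[small]^2 / 10 + x[small]^4 / 280
  xb <- x[!small]
  out[!small] <- 3 * (sin(xb) - xb * cos(xb)) / xb^3
  out
}

#' First zero crossing of the modifying factor
#'
#' Locates the smallest particle-diameter-to-wavelength ratio at which the
#' 1-D finite-size force vanishes. The root of \eqn{f_m} satisfies
#' \eqn{\tan x = x} with \eqn{x = 2\chi} on \eqn{(\pi, 3\pi/2)}, giving
#' \eqn{D_p/\lambda = \chi/\pi \approx 0.715}.
#'
#' @param tol Root-finding tolerance passed to [stats::uniroot()].
#' @return The ratio \eqn{D_p/\lambda} at the first zero.
#' @export
#' @examples
#' round(zero_crossing_ratio(), 2) # 0.72
zero_crossing_ratio <- function(tol = 1e-12) {
  root <- uniroot(function(chi) modifying_factor(chi),
                  interval = c(2, 2.5), tol = tol)
  root$root / pi
}

#' Relative difference metric between force curves
#'
#' \eqn{D = \sum_i |F_i - F^{ref}_i| / \sum_i |F^{ref}_i|}, the summed
#' absolute deviation of a force curve from a reference curve sampled on the
#' same grid, normalised by the reference. Used to quantify how far a model
#' curve departs from a trusted reference over a range of particle sizes.
#'
#' @param force Numeric vector of forces (N), or any common unit.
#' @param reference Reference forces on the same grid.
#' @return Dimensionless metric; 0 for identical curves.
#' @export
#' @examples
#' difference_metric(c(1, 2, 3), c(1, 2, 2)) # 0.2
difference_metric <- function(force, reference) {
  if (length(force) != length(reference)) {
    stop_domain("`force` and `reference` must be sampled on the same grid")
  }
  denom <- sum(abs(reference))
  if (denom == 0) {
    abort("difference metric undefined: reference curve is identically zero",
          class = "arftrace_metric_error")
  }
  sum(abs(force - reference)) / denom
}

# ---- volume-average quadrature ---------------------------------------------

# Quadrature nodes for averaging a function over the particle ball of radius
# `a`, as (offsets, weights) with weights summing to 1.
#
# method "ball": 3-D Gauss-Legendre product rule (radial x polar, uniform
#   azimuthal — exact for trigonometric azimuthal dependence). Offsets are
#   padded/truncated to `dim` ambient coordinates; for fields invariant in
#   the dropped coordinate this is exact.
# method "disk": 2-D in-plane rule with the chord weight 2*sqrt(a^2 - d^2)
#   (the out-of-plane extent of the sphere), normalised by 4*pi*a^3/3 —
#   identical to "ball" for fields constant in the third dimension.
# method "axis": fields varying along a single axis only; the ball average
#   reduces to a 1-D rule with the cross-section weight pi*(a^2 - u^2).
ball_quadrature <- function(a, order, method, dim, axis = NULL) {
  gl <- pracma::gaussLegendre(order, -1, 1)
  if (method == "axis") {
    u <- a * gl$x
    w <- gl$w * (a^2 - u^2) * a        # pi cancels in normalisation
    w <- w / sum(w)
    offs <- matrix(0, length(u), dim)
    offs <- offs + u %o% axis
    return(list(offsets = offs, weights = w))
  }
  glr <- pracma::gaussLegendre(order, 0, a)
  nphi <- max(2 * order, 8)
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  if (method == "disk") {
    # substitute rho = a*sin(psi): removes the sqrt(a^2 - rho^2) derivative
    # singularity of the chord weight at the rim, restoring spectral
    # Gauss-Legendre convergence
    glp <- pracma::gaussLegendre(order, 0, pi / 2)
    rho <- a * sin(glp$x)
    wr <- glp$w * 2 * a^3 * sin(glp$x) * cos(glp$x)^2
    offs <- cbind(as.vector(rho %o% cos(phi)), as.vector(rho %o% sin(phi)))
    w <- as.vector(wr %o% rep(1 / nphi, nphi))
    w <- w / sum(w)
    if (dim > 2) offs <- cbind(offs, matrix(0, nrow(offs), dim - 2))
    return(list(offsets = offs, weights = w))
  }
  # ball: r in (0, a], mu = cos(theta) in [-1, 1], phi uniform
  r <- glr$x
  wr <- glr$w * r^2
  mu <- gl$x
  wmu <- gl$w
  sin_th <- sqrt(pmax(1 - mu^2, 0))
  # expand grid r x mu x phi
  grid <- expand.grid(ir = seq_along(r), im = seq_along(mu),
                      ip = seq_len(nphi))
  rr <- r[grid$ir]
  st <- sin_th[grid$im]
  cm <- mu[grid$im]
  offs3 <- cbind(rr * st * cos(phi[grid$ip]),
                 rr * st * sin(phi[grid$ip]),
                 rr * cm)
  w <- wr[grid$ir] * wmu[grid$im] / nphi
  w <- w / sum(w)
  offs <- offs3[, seq_len(min(dim, 3)), drop = FALSE]
  if (dim > 3) offs <- cbind(offs, matrix(0, nrow(offs), dim - 3))
  list(offsets = offs, weights = w)
}

# Volume-averaged force at positions (n x dim), one quadrature order.
finite_size_force_order <- function(wave, r, particle, coeffs, order,
                                    method, axis) {
  quad <- ball_quadrature(particle$radius, order, method, wave$dim, axis)
  n <- nrow(r)
  q <- nrow(quad$offsets)
  # all shifted evaluation points at once: (n*q) x dim
  pts <- r[rep(seq_len(n), each = q), , drop = FALSE] +
    quad$offsets[rep(seq_len(q), times = n), , drop = FALSE]
  fs <- small_particle_force_matrix(wave, pts, particle, coeffs)
  out <- matrix(0, n, wave$dim)
  for (p in seq_len(wave$dim)) {
    out[, p] <- colSums(matrix(fs[, p], nrow = q) * quad$weights)
  }
  out
}

#' Finite-size (volume-averaged) radiation force
#'
#' Averages the small-particle force field over the particle ball of radius
#' `a` centred at each position — the finite-size correction that replaces
#' the point evaluation when the particle diameter is comparable to the
#' wavelength. Valid when the particle's acoustic impedance is close to the
#' fluid's, so the incident field approximates the transmitted field inside
#' the particle.
#'
#' The quadrature order is refined (doubled) until two successive orders
#' agree to `tol` in relative terms, up to `max_order`; non-convergence is
#' an error carrying the last two estimates.
#'
#' @inheritParams small_particle_force
#' @param method Quadrature rule: `"auto"` picks the exact 1-D reduction for
#'   single-component fields and the ball rule otherwise; `"ball"` forces
#'   the 3-D spherical product rule; `"disk"` the 2-D in-plane rule with the
#'   sphere-chord weight (for fields invariant in the third dimension);
#'   `"axis"` the 1-D reduction.
#' @param tol Relative convergence tolerance between successive quadrature
#'   refinements.
#' @param order Starting Gauss-Legendre order.
#' @param max_order Refinement cap.
#' @param adaptive If `FALSE`, evaluate once at `order` without refinement
#'   (used inside trajectory integration where speed matters and the field
#'   is smooth).
#' @return A tibble like [small_particle_force()]'s.
#' @export
#' @examples
#' w <- standing_wave(60e-6, 2e5, fluid = water_properties())
#' finite_size_force(w, cbind(0, 7.5e-6), nih3t3_properties())
finite_size_force <- function(wave, positions, particle, coeffs = NULL,
                              method = c("auto", "ball", "disk", "axis"),
                              tol = 1e-6, order = 6, max_order = 64,
                              adaptive = TRUE) {
  method <- match.arg(method)
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  r <- as_position_matrix(positions, wave$dim)
  axis <- NULL
  if (method == "auto") {
    if (nrow(wave$axes) == 1L) {
      method <- "axis"
    } else {
      method <- if (wave$dim == 2L) "disk" else "ball"
    }
  }
  if (method == "axis") {
    if (nrow(wave$axes) != 1L) {
      stop_domain("method \"axis\" requires a single-component field")
    }
    axis <- wave$axes[1, ]
  }
  if (method == "disk" && wave$dim != 2L) {
    stop_domain("method \"disk\" requires a 2-D field")
  }
  est <- finite_size_force_order(wave, r, particle, coeffs, order, method,
                                 axis)
  if (adaptive) {
    # characteristic force scale: absolute floor so symmetry points where
    # the force is identically zero still register as converged
    e_ac <- acoustic_energy_density(max(wave$peak_pressure),
                                    wave$fluid$compressibility)
    f_char <- 4 * pi * max(abs(coeffs$contrast_factor), 1e-6) *
      particle$radius^3 * wave$wavenumber * e_ac
    converged <- FALSE
    last_change <- Inf
    while (order < max_order) {
      order2 <- min(2 * order, max_order)
      est2 <- finite_size_force_order(wave, r, particle, coeffs, order2,
                                      method, axis)
      last_change <- max(abs(est2 - est))
      est <- est2
      order <- order2
      if (last_change <= tol * max(abs(est2), 1e-9 * f_char)) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      abort(
        sprintf(paste0("finite-size quadrature did not converge to %g by ",
                       "order %d (last change %g N at force scale %g N)"),
                tol, max_order, last_change, f_char),
        class = "arftrace_quadrature_error"
      )
    }
  }
  force_tibble(r, est, wave$dim)
}

#' Sample a radiation-force map on a regular grid
#'
#' Evaluates the chosen force model on a regular grid over a bounding box —
#' the standard way to visualise how the finite-size correction reshapes the
#' force pattern of a multi-directional field.
#'
#' @inheritParams small_particle_force
#' @param bbox Bounding box: a `dim x 2` matrix of (min, max) per coordinate,
#'   or a length-4 vector `c(xmin, xmax, ymin, ymax)` in 2-D.
#' @param resolution Grid points per wavelength (>= 8).
#' @param model `"small_particle"` or `"finite_size"`.
#' @param ... Passed to [finite_size_force()] (quadrature controls).
#' @return A tibble of class `force_grid` with coordinates, force
#'   components, `f_mag`, and a `model` column; attributes `wavelength`,
#'   `particle_diameter`, `peak_pressure`, `model`.
#' @export
force_map <- function(wave, particle, coeffs = NULL, bbox, resolution = 16,
                      model = c("small_particle", "finite_size"), ...) {
  model <- match.arg(model)
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  if (is.numeric(bbox) && is.null(dim(bbox))) {
    bbox <- matrix(bbox, ncol = 2, byrow = TRUE)
  }
  if (!is.matrix(bbox) || nrow(bbox) != wave$dim || ncol(bbox) != 2 ||
      any(bbox[, 2] <= bbox[, 1])) {
    abort("`bbox` must be a dim x 2 matrix with max > min per coordinate",
          class = "arftrace_config_error")
  }
  if (resolution < 8) {
    abort("`resolution` must be at least 8 points per wavelength",
          class = "arftrace_config_error")
  }
  axes_pts <- lapply(seq_len(wave$dim), function(i) {
    n <- max(2L, ceiling(resolution * (bbox[i, 2] - bbox[i, 1]) /
                           wave$wavelength) + 1L)
    seq(bbox[i, 1], bbox[i, 2], length.out = n)
  })
  grid <- as.matrix(expand.grid(axes_pts))
  colnames(grid) <- NULL
  out <- if (model == "small_particle") {
    small_particle_force(wave, grid, particle, coeffs)
  } else {
    finite_size_force(wave, grid, particle, coeffs, ...)
  }
  fcols <- intersect(c("fx", "fy", "fz"), names(out))
  out$f_mag <- sqrt(rowSums(as.matrix(out[, fcols])^2))
  out$model <- model
  structure(
    out,
    class = c("force_grid", class(out)),
    wavelength = wave$wavelength,
    particle_diameter = particle$diameter,
    peak_pressure = wave$peak_pressure,
    model = model
  )
}

#' Force-versus-size curve for a 1-D standing field
#'
#' Sweeps the particle-diameter-to-wavelength ratio and reports, at a fixed
#' offset `h` from a pressure node, the small-particle force, the
#' closed-form finite-size force (modifying factor) and the volume-averaged
#' quadrature force — the model-comparison curve for the 1-D field.
#'
#' @param fluid A [fluid_properties()] object.
#' @param particle A [particle_properties()] object (its radius is swept;
#'   density/compressibility fixed).
#' @param wavelength Wavelength (m).
#' @param peak_pressure Peak pressure (Pa).
#' @param ratios Grid of \eqn{D_p/\lambda} values; default 20 uniform points
#'   on (0.05, 1].
#' @param h Offset from the node (m); default \eqn{\lambda/8} (maximal
#'   force).
#' @param quad_method Quadrature method for the volume average (default
#'   `"ball"`, the full 3-D rule, so the closed form is checked by an
#'   independent route).
#' @return A tibble of class `force_curve` with columns `ratio`, `chi`,
#'   `f_small`, `f_closed`, `f_quad` and `f_m`; attribute
#'   `difference_closed_quad` carries the relative difference metric between
#'   the closed-form and quadrature columns.
#' @export
#' @examples
#' \donttest{
#' fc <- force_curve(water_properties(), nih3t3_properties(),
#'                   wavelength = 60e-6, peak_pressure = 2e5,
#'                   ratios = c(1 / 6, 0.4))
#' fc$f_m
#' }
force_curve <- function(fluid, particle, wavelength, peak_pressure,
                        ratios = seq(0.05, 1, length.out = 20),
                        h = wavelength / 8, quad_method = "ball") {
  check_positive(wavelength, "wavelength")
  check_positive(ratios, "ratios")
  k <- 2 * pi / wavelength
  e_ac <- acoustic_energy_density(peak_pressure, fluid$compressibility)
  rows <- lapply(ratios, function(ratio) {
    a <- ratio * wavelength / 2
    p <- particle_properties(particle$density, particle$compressibility,
                             radius = a,
                             shear_modulus = particle$shear_modulus,
                             name = particle$name)
    coeffs <- scattering_coefficients(p, fluid)
    wave <- standing_wave(wavelength, peak_pressure, axes = c(0, 1),
                          fluid = fluid)
    chi <- k * a
    f_small <- closed_form_1d(h, a, k, e_ac, coeffs$contrast_factor)
    f_closed <- f_small * modifying_factor(chi)
    # node nearest the origin sits at y = lambda/4; particle at node - h
    pos <- cbind(0, wavelength / 4 - h)
    f_quad <- finite_size_force(wave, pos, p, coeffs,
                                method = quad_method)$fy
    tibble(ratio = ratio, chi = chi, f_small = f_small,
           f_closed = f_closed, f_quad = f_quad,
           f_m = modifying_factor(chi))
  })
  out <- bind_rows(rows)
  structure(
    out,
    class = c("force_curve", class(out)),
    wavelength = wavelength,
    peak_pressure = peak_pressure,
    h = h,
    difference_closed_quad = difference_metric(out$f_quad, out$f_closed)
  )
}
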