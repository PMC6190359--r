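# Quasi-static acoustophoretic particle tracing.
#
# In the creeping-flow regime (channel Reynolds number well below 1, micron
# particles with microsecond Stokes response times) inertia is negligible and
# the particle velocity is the local fluid velocity plus the radiation force
# times the Stokes mobility:
#
#   dr/dt = u_flow(r) + F_ARF(r) / (6 pi mu a)
#
# Trajectories are integrated with deSolve (lsoda, adaptive) or a fixed-step
# RK4 fallback for bit-identical regression runs. An optional inertial mode
# (finite particle mass) exists for sensitivity checks.

#' Microfluidic channel description
#'
#' A straight channel with axial flow (x) and a lateral coordinate (y) in
#' `[0, width]`. Outlet cut positions split the lateral coordinate into a
#' centre band (between the cuts, feeding the centre outlet) and two side
#' bands (the sheath flow, feeding the side outlets).
#'
#' @param width Lateral width (m).
#' @param length Axial length (m).
#' @param mean_speed Mean axial flow speed (m s^-1).
#' @param profile `"plug"` (uniform) or `"parabolic"` (plane Poiseuille,
#'   peak 1.5x mean at the centreline, zero at the walls).
#' @param cuts Length-2 vector of lateral cut positions (m), strictly inside
#'   `(0, width)`.
#' @return An object of class `channel_spec`.
#' @export
#' @examples
#' channel_spec(240e-6, 200e-6, 1e-3, cuts = c(108e-6, 132e-6))
channel_spec <- function(width, length, mean_speed,
                         profile = c("plug", "parabolic"),
                         cuts = c(width / 4, 3 * width / 4)) {
  profile <- match.arg(profile)
  check_positive(width, "width")
  check_positive(length, "length")
  check_positive(mean_speed, "mean_speed")
  if (length(cuts) != 2L || any(cuts <= 0) || any(cuts >= width) ||
      cuts[1] >= cuts[2]) {
    stop_domain("`cuts` must be two increasing positions inside (0, width)")
  }
  structure(
    list(width = width, length = length, mean_speed = mean_speed,
         profile = profile, cuts = cuts),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("<channel_spec>\n")
  cat(sprintf("  width x length  %g x %g m, %s flow at %g m/s\n",
              x$width, x$length, x$profile, x$mean_speed))
  cat(sprintf("  outlet cuts     %g, %g m\n", x$cuts[1], x$cuts[2]))
  invisible(x)
}

#' Stokes drag mobility of a sphere
#'
#' \eqn{1 / (6\pi\mu a)}: the velocity per unit force of a sphere in
#' creeping flow.
#'
#' @param radius Particle radius (m).
#' @param viscosity Fluid shear viscosity (Pa s).
#' @return Mobility (m s^-1 N^-1).
#' @export
#' @examples
#' drag_mobility(5e-6, 8.538e-4) # ~1.24e7 for a 10 um cell in water
drag_mobility <- function(radius, viscosity) {
  check_positive(radius, "radius")
  check_positive(viscosity, "viscosity")
  1 / (6 * pi * viscosity * radius)
}

# axial flow speed at lateral position y
flow_speed <- function(channel, y) {
  if (is.null(channel)) return(0)
  if (channel$profile == "plug") {
    rep_len(channel$mean_speed, length(y))
  } else {
    1.5 * channel$mean_speed *
      (1 - (2 * (y - channel$width / 2) / channel$width)^2)
  }
}

# force model dispatcher: returns function(r_matrix) -> force matrix (N)
force_model_fn <- function(wave, particle, coeffs, model, quad_order = 12) {
  if (model == "small_particle") {
    function(r) small_particle_force_matrix(wave, r, particle, coeffs)
  } else {
    function(r) {
      out <- finite_size_force(wave, r, particle, coeffs, method = "auto",
                               order = quad_order, adaptive = FALSE)
      as.matrix(out[, paste0("f", c("x", "y", "z")[seq_len(wave$dim)])])
    }
  }
}

#' Integrate a particle trajectory
#'
#' Traces a particle through the channel under axial flow plus the acoustic
#' radiation force of the chosen model, using the quasi-static force balance
#' (particle velocity = fluid velocity + Stokes mobility x force). With
#' `inertial = TRUE` the full Newtonian equation with the particle's mass
#' and linear Stokes drag is integrated instead, for sensitivity checks.
#'
#' @param wave A [standing_wave()] object (2-D: axial x, lateral y).
#' @param particle A [particle_properties()] object.
#' @param r0 Initial position `c(x, y)` (m); must lie inside the channel if
#'   one is given.
#' @param duration Integration time (s).
#' @param channel Optional [channel_spec()]; `NULL` for force-only motion
#'   (no flow, no exit).
#' @param model `"small_particle"` or `"finite_size"`.
#' @param coeffs Optional [scattering_coefficients()].
#' @param n_out Number of output time samples.
#' @param method `"adaptive"` (lsoda) or `"fixed"` (classical RK4 at the
#'   output step — deterministic to the bit for regression tests).
#' @param rtol,atol Adaptive-solver tolerances.
#' @param force_scale Multiplier on the acoustic force (0 disables it).
#' @param quad_order Fixed Gauss-Legendre order for the finite-size model
#'   inside the integration.
#' @param inertial If `TRUE`, integrate mass x acceleration = drag + ARF.
#' @return A tibble of class `trajectory` with columns `t`, `x`, `y` and
#'   attribute `model`; rows after the particle crosses the channel end are
#'   dropped and attribute `exited` is set.
#' @export
#' @examples
#' w <- standing_wave(60e-6, 2e5, fluid = water_properties())
#' tr <- advance_trajectory(w, nih3t3_properties(), r0 = c(0, 22.5e-6),
#'                          duration = 0.05)
#' tail(tr, 1)
advance_trajectory <- function(wave, particle, r0, duration,
                               channel = NULL,
                               model = c("small_particle", "finite_size"),
                               coeffs = NULL, n_out = 201,
                               method = c("adaptive", "fixed"),
                               rtol = 1e-8, atol = 1e-12,
                               force_scale = 1, quad_order = 12,
                               inertial = FALSE) {
  model <- match.arg(model)
  method <- match.arg(method)
  check_positive(duration, "duration")
  if (length(r0) != 2L) stop_domain("`r0` must be c(x, y)")
  if (!is.null(channel) &&
      (r0[2] < 0 || r0[2] > channel$width || r0[1] < 0 ||
       r0[1] > channel$length)) {
    stop_domain("`r0` must lie inside the channel")
  }
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  if (is.na(wave$fluid$shear_viscosity)) {
    stop_domain("tracing requires the fluid's shear viscosity")
  }
  mob <- drag_mobility(particle$radius, wave$fluid$shear_viscosity)
  ffun <- force_model_fn(wave, particle, coeffs, model, quad_order)
  times <- seq(0, duration, length.out = n_out)
  if (!inertial) {
    deriv <- function(t, state, parms) {
      r <- matrix(state, nrow = 1)
      f <- ffun(r) * force_scale
      list(c(flow_speed(channel, state[2]) + mob * f[1, 1],
             mob * f[1, 2]))
    }
    sol <- deSolve::ode(y = c(x = r0[1], y = r0[2]), times = times,
                        func = deriv, parms = NULL,
                        method = if (method == "adaptive") "lsoda" else "rk4",
                        rtol = rtol, atol = atol)
    out <- tibble(t = sol[, "time"], x = sol[, "x"], y = sol[, "y"])
  } else {
    mass <- particle$density * particle_volume(particle)
    drag <- 6 * pi * wave$fluid$shear_viscosity * particle$radius
    deriv <- function(t, state, parms) {
      r <- matrix(state[1:2], nrow = 1)
      f <- ffun(r) * force_scale
      u <- c(flow_speed(channel, state[2]), 0)
      acc <- (f[1, ] - drag * (state[3:4] - u)) / mass
      list(c(state[3:4], acc))
    }
    u0 <- c(flow_speed(channel, r0[2]), 0)
    sol <- deSolve::ode(y = c(x = r0[1], y = r0[2], vx = u0[1], vy = u0[2]),
                        times = times, func = deriv, parms = NULL,
                        method = if (method == "adaptive") "lsoda" else "rk4",
                        rtol = rtol, atol = atol)
    out <- tibble(t = sol[, "time"], x = sol[, "x"], y = sol[, "y"])
  }
  exited <- FALSE
  if (!is.null(channel)) {
    past <- which(out$x > channel$length)
    if (length(past) > 0) {
      exited <- TRUE
      keep <- seq_len(min(past))   # keep first sample past the end
      out <- out[keep, ]
    }
  }
  structure(out, class = c("trajectory", class(out)), model = model,
            exited = exited)
}

#' Simulate an acoustophoretic separation run
#'
#' Releases particles at given lateral positions at the channel inlet,
#' traces each through the channel under the chosen force model, and
#' classifies its outlet: `"side"` if its lateral position at the channel
#' end lies outside the outlet cuts (it entered the sheath flow), `"center"`
#' otherwise. Because the finite-size modifying factor is below one, the
#' finite-size model never captures more particles into the side outlets
#' than the small-particle model under identical settings.
#'
#' @inheritParams advance_trajectory
#' @param channel A [channel_spec()].
#' @param release_y Lateral release positions (m) at the inlet `x = 0`.
#' @param models Character vector of force models to run (both by default).
#' @param ... Passed to [advance_trajectory()].
#' @return An object of class `separation_report`: a list with
#'   `assignments` (tibble: `particle`, `release_y`, `model`, `final_y`,
#'   `outlet`), `counts` (tibble: `model`, `outlet`, `n`) and the inputs.
#'   [tidy()] returns the assignments, [glance()] one row per model with
#'   capture counts.
#' @export
simulate_separation <- function(channel, wave, particle, release_y,
                                models = c("small_particle", "finite_size"),
                                coeffs = NULL, ...) {
  if (length(release_y) < 1L) {
    stop_domain("at least one release position is required")
  }
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  transit <- channel$length / channel$mean_speed
  duration <- if (channel$profile == "plug") transit else 3 * transit
  rows <- list()
  for (model in models) {
    for (i in seq_along(release_y)) {
      tr <- advance_trajectory(wave, particle, r0 = c(0, release_y[i]),
                               duration = duration, channel = channel,
                               model = model, coeffs = coeffs, ...)
      final_y <- tr$y[nrow(tr)]
      outlet <- if (final_y < channel$cuts[1] || final_y > channel$cuts[2]) {
        "side"
      } else {
        "center"
      }
      rows[[length(rows) + 1L]] <- tibble(
        particle = paste0("P", i), release_y = release_y[i],
        model = model, final_y = final_y, outlet = outlet
      )
    }
  }
  assignments <- bind_rows(rows)
  counts <- count(group_by(assignments, .data$model, .data$outlet),
                  name = "n")
  structure(
    list(assignments = assignments, counts = ungroup(counts),
         channel = channel, models = models),
    class = "separation_report"
  )
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report>\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}

#' @rdname simulate_separation
#' @param x A `separation_report`.
#' @export
tidy.separation_report <- function(x, ...) {
  x$assignments
}

#' @rdname simulate_separation
#' @export
glance.separation_report <- function(x, ...) {
  asg <- x$assignments
  out <- summarise(group_by(asg, .data$model),
                   n_released = dplyr::n(),
                   n_side = sum(.data$outlet == "side"),
                   n_center = sum(.data$outlet == "center"),
                   .groups = "drop")
  mutate(out, capture_fraction = .data$n_side / .data$n_released)
}

#' Locate stable equilibrium positions of the force field
#'
#' Seeds particles on a regular grid over the bounding box and relaxes each
#' down the force field by over-damped (Stokes) descent until it stops
#' moving; converged end points are de-duplicated to the set of stable
#' positions. For positive contrast factor these coincide with the pressure
#' node lattice; for negative contrast, with the antinodes.
#'
#' @inheritParams advance_trajectory
#' @param bbox A `dim x 2` matrix (or length-4 vector in 2-D) spanning at
#'   least one spatial period per axis.
#' @param n_seeds Seeds per axis.
#' @param step_tol Convergence threshold on the residual drift of a relaxed
#'   seed over the final tenth of the relaxation horizon, as a fraction of
#'   the wavelength; seeds still drifting faster are flagged unconverged.
#' @return A tibble with the equilibrium coordinates, `n_seeds` attracted to
#'   each point, `converged`, and `stable` (restoring force under small
#'   perturbations and negligible residual force; unstable stationary
#'   points such as antinodes under positive contrast are reported with
#'   `stable = FALSE`).
#' @export
find_equilibria <- function(wave, particle, bbox, coeffs = NULL,
                            model = c("small_particle", "finite_size"),
                            n_seeds = 6, step_tol = 1e-4,
                            quad_order = 8) {
  model <- match.arg(model)
  if (is.null(coeffs)) coeffs <- scattering_coefficients(particle, wave$fluid)
  if (is.numeric(bbox) && is.null(dim(bbox))) {
    bbox <- matrix(bbox, ncol = 2, byrow = TRUE)
  }
  active <- colSums(abs(wave$axes)) > 1e-12
  if (any((bbox[active, 2] - bbox[active, 1]) < wave$wavelength - 1e-12)) {
    stop_domain(
      "`bbox` must span at least one wavelength along each field axis")
  }
  if (is.na(wave$fluid$shear_viscosity)) {
    stop_domain("equilibrium search requires the fluid's shear viscosity")
  }
  ffun <- force_model_fn(wave, particle, coeffs, model, quad_order)
  lam <- wave$wavelength
  k <- wave$wavenumber
  mob <- drag_mobility(particle$radius, wave$fluid$shear_viscosity)
  # linearised node-approach rate: F' ~ 2k * 4*pi*|phi|*a^3*k*E_ac near a node
  e_ac <- acoustic_energy_density(max(wave$peak_pressure),
                                  wave$fluid$compressibility)
  f_scale <- 4 * pi * abs(coeffs$contrast_factor) * particle$radius^3 *
    k * e_ac
  rate <- 2 * k * mob * f_scale
  if (!is.finite(rate) || rate <= 0) {
    stop_domain("degenerate force field: zero contrast factor or pressure")
  }
  # cell-centred seeds avoid landing exactly on symmetry points
  seeds <- as.matrix(expand.grid(lapply(seq_len(wave$dim), function(i) {
    bbox[i, 1] + (seq_len(n_seeds) - 0.5) / n_seeds *
      (bbox[i, 2] - bbox[i, 1])
  })))
  colnames(seeds) <- NULL
  ends <- matrix(NA_real_, nrow(seeds), wave$dim)
  ok <- logical(nrow(seeds))
  deriv <- function(t, state, parms) {
    list(as.numeric(mob * ffun(matrix(state, nrow = 1))))
  }
  horizon <- 25 / rate   # ~25 e-folding times of the linearised dynamics
  for (i in seq_len(nrow(seeds))) {
    sol <- deSolve::ode(y = seeds[i, ], times = c(0, 0.9, 1) * horizon,
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = 1e-9, atol = 1e-12 * lam)
    ends[i, ] <- sol[nrow(sol), -1]
    drift <- sqrt(sum((sol[3, -1] - sol[2, -1])^2))
    ok[i] <- drift < step_tol * lam
  }
  # stability probe: restoring force under small perturbations along each
  # axis, plus a residual-force floor at the end point itself
  probe_stable <- function(r) {
    if (sqrt(sum(ffun(matrix(r, nrow = 1))^2)) > 1e-3 * f_scale) {
      return(FALSE)
    }
    for (ax in seq_len(wave$dim)) {
      for (sgn in c(-1, 1)) {
        dr <- numeric(wave$dim)
        dr[ax] <- sgn * 1e-3 * lam
        f <- ffun(matrix(r + dr, nrow = 1))
        # restoring (or neutral, for node-line directions) within noise
        if (sum(f * dr) > 1e-9 * f_scale * lam) return(FALSE)
      }
    }
    TRUE
  }
  # de-duplicate within 1% of a wavelength
  out <- list()
  used <- rep(FALSE, nrow(ends))
  for (i in seq_len(nrow(ends))) {
    if (used[i]) next
    same <- which(!used & sqrt(rowSums(sweep(ends, 2, ends[i, ])^2)) <
                    0.01 * lam)
    used[same] <- TRUE
    centre <- colMeans(ends[same, , drop = FALSE])
    out[[length(out) + 1L]] <- tibble(
      x = centre[1],
      y = if (wave$dim >= 2) centre[2] else NA_real_,
      n_seeds = length(same),
      converged = all(ok[same]),
      stable = probe_stable(centre)
    )
  }
  bind_rows(out)
}
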