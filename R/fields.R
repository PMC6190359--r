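# Standing plane-wave fields and their first-order time-averaged quantities.
#
# A field is a superposition of standing plane-wave components at a common
# frequency, all oscillating in phase in time (a single cos(omega*t) factor):
#
#   p1(r, t) = A(r) cos(omega t),   A(r) = sum_j p_j cos(k r.e_j - phi_j)
#
# The coordinate origin sits at a pressure antinode of each zero-phase
# component (cos convention). First-order velocity follows from the
# linearised momentum balance rho dv/dt = -grad p1, so
# v1 = -grad A sin(omega t) / (rho omega), and the time averages are
# <p^2> = A^2/2, <v^2> = |grad A|^2 / (2 rho^2 omega^2).
#
# Averaged quantities use the compressibility-consistent phase speed
# c = 1/sqrt(rho beta), i.e. 1/(rho omega^2) = beta/k^2: tabulated beta and c
# may disagree in their last digits (the constructor tolerates 0.1%), and
# carrying beta throughout keeps equipartition and the closed-form force
# identities exact instead of approximate at the table's rounding level.

#' Standing acoustic wave field
#'
#' Defines one or more standing plane-wave components at a common frequency.
#' Each component has a unit axis vector, a peak pressure amplitude and a
#' spatial phase offset; components are mutually in phase in time, which for
#' two equal perpendicular components produces the familiar checkerboard
#' node/antinode lattice used for particle patterning.
#'
#' @param wavelength Acoustic wavelength \eqn{\lambda} (m).
#' @param peak_pressure Peak pressure amplitude(s) \eqn{p_{ac}} (Pa), one per
#'   component (recycled if scalar).
#' @param axes Component axes: a unit vector, a list of unit vectors, or a
#'   matrix with one row per component. Defaults to a single component along
#'   the second (y) axis of a 2-D domain.
#' @param phases Spatial phase offsets \eqn{\varphi_0} (rad), one per
#'   component; default 0 (antinode at the origin).
#' @param fluid A [fluid_properties()] object for the host fluid.
#'
#' @return An object of class `standing_wave` with fields `wavelength`,
#'   `wavenumber` (\eqn{k = 2\pi/\lambda}), `omega` (\eqn{kc_f}),
#'   `frequency`, `axes` (matrix), `peak_pressure`, `phases`, `fluid` and
#'   `dim` (ambient dimension).
#' @export
#' @examples
#' w <- standing_wave(60e-6, 2e5, fluid = water_properties())
#' w2 <- standing_wave(60e-6, 2e5,
#'                     axes = list(c(1, 0), c(0, 1)),
#'                     fluid = water_properties())
standing_wave <- function(wavelength, peak_pressure,
                          axes = c(0, 1), phases = 0,
                          fluid = water_properties()) {
  check_positive(wavelength, "wavelength")
  if (!inherits(fluid, "fluid_properties")) {
    stop_domain("`fluid` must be a fluid_properties object")
  }
  if (is.numeric(axes) && is.null(dim(axes))) axes <- list(axes)
  if (is.list(axes)) axes <- do.call(rbind, axes)
  if (!is.matrix(axes) || nrow(axes) < 1L) {
    stop_domain("`axes` must give at least one component axis")
  }
  norms <- sqrt(rowSums(axes^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop_domain("component axes must be unit vectors")
  }
  m <- nrow(axes)
  peak_pressure <- rep_len(peak_pressure, m)
  phases <- rep_len(phases, m)
  check_positive(peak_pressure, "peak_pressure")
  k <- 2 * pi / wavelength
  structure(
    list(
      wavelength = wavelength,
      wavenumber = k,
      omega = k * fluid$sound_speed,
      frequency = k * fluid$sound_speed / (2 * pi),
      axes = axes,
      peak_pressure = peak_pressure,
      phases = phases,
      fluid = fluid,
      dim = ncol(axes)
    ),
    class = "standing_wave"
  )
}

#' @export
print.standing_wave <- function(x, ...) {
  cat("<standing_wave>\n")
  cat(sprintf("  wavelength  %g m  (f = %g Hz)\n", x$wavelength, x$frequency))
  cat(sprintf("  components  %d in %d-D, p_ac = %s Pa\n",
              nrow(x$axes), x$dim,
              paste(signif(x$peak_pressure, 4), collapse = ", ")))
  invisible(x)
}

# positions as an n x dim matrix, whatever the caller supplied
as_position_matrix <- function(positions, dim) {
  if (is.data.frame(positions)) {
    positions <- as.matrix(positions[, seq_len(dim), drop = FALSE])
  }
  if (is.null(base::dim(positions))) positions <- matrix(positions, nrow = 1)
  if (ncol(positions) != dim) {
    stop_domain(sprintf("positions must have %d coordinate column(s)", dim))
  }
  storage.mode(positions) <- "double"
  positions
}

# Spatial amplitude A(r) and its first/second derivatives, vectorised over
# an n x dim position matrix. Returns list(amp [n], grad [n x dim],
# hess [n x dim x dim]).
field_amplitude <- function(wave, positions, need_hess = FALSE) {
  r <- as_position_matrix(positions, wave$dim)
  n <- nrow(r)
  d <- wave$dim
  k <- wave$wavenumber
  s <- r %*% t(wave$axes)                   # n x m projections
  ph <- sweep(k * s, 2, wave$phases, "-")   # k r.e_j - phi_j
  cph <- cos(ph)
  sph <- sin(ph)
  amp <- as.numeric(cph %*% wave$peak_pressure)
  grad <- -(sweep(sph, 2, wave$peak_pressure, "*") %*% wave$axes) * k
  hess <- NULL
  if (need_hess) {
    hess <- array(0, dim = c(n, d, d))
    for (j in seq_len(nrow(wave$axes))) {
      ee <- tcrossprod(wave$axes[j, ])      # d x d
      cj <- -wave$peak_pressure[j] * k^2 * cph[, j]
      for (p in seq_len(d)) for (q in seq_len(d)) {
        hess[, p, q] <- hess[, p, q] + cj * ee[p, q]
      }
    }
  }
  list(amp = amp, grad = grad, hess = hess)
}

#' Instantaneous acoustic pressure
#'
#' First-order pressure \eqn{p_1(r,t) = A(r)\cos(\omega t)} of the standing
#' field, with \eqn{A(r)} the superposed spatial amplitude of all
#' components.
#'
#' @param wave A [standing_wave()] object.
#' @param positions Position(s): a numeric vector, matrix (rows =
#'   positions), or data frame with coordinate columns first.
#' @param time Time (s), a scalar.
#' @return Numeric vector of pressures (Pa), one per position.
#' @export
instantaneous_pressure <- function(wave, positions, time = 0) {
  if (!is.numeric(time) || length(time) != 1L || time < 0) {
    stop_domain("`time` must be a non-negative scalar")
  }
  fa <- field_amplitude(wave, positions)
  fa$amp * cos(wave$omega * time)
}

#' Time-averaged field quantities at given positions
#'
#' Computes the period-averaged squared pressure
#' \eqn{\langle p^2\rangle = A^2/2} and squared velocity
#' \eqn{\langle v^2\rangle = |\nabla A|^2/(2\rho^2\omega^2)} of the
#' first-order field.
#'
#' @inheritParams instantaneous_pressure
#' @return A tibble with the coordinate columns (`x`, `y`, and `z` as
#'   applicable) followed by `p_sq` (Pa^2) and `v_sq` (m^2 s^-2).
#' @export
#' @examples
#' w <- standing_wave(60e-6, 2e5, fluid = water_properties())
#' field_quantities(w, cbind(0, c(0, 15e-6, 30e-6)))
field_quantities <- function(wave, positions) {
  r <- as_position_matrix(positions, wave$dim)
  fa <- field_amplitude(wave, r)
  rho <- wave$fluid$density
  beta <- wave$fluid$compressibility
  p_sq <- fa$amp^2 / 2
  v_sq <- rowSums(fa$grad^2) * beta / (2 * rho * wave$wavenumber^2)
  coords <- as_tibble(as.data.frame(r))
  names(coords) <- c("x", "y", "z")[seq_len(wave$dim)]
  bind_cols(coords, tibble(p_sq = p_sq, v_sq = v_sq))
}

#' Mean-square pressure \eqn{\langle p_{in}^2 \rangle}
#' @inheritParams instantaneous_pressure
#' @return Numeric vector (Pa^2).
#' @export
mean_square_pressure <- function(wave, positions) {
  field_amplitude(wave, positions)$amp^2 / 2
}

#' Mean-square velocity \eqn{\langle v_{in}^2 \rangle}
#' @inheritParams instantaneous_pressure
#' @return Numeric vector (m^2 s^-2).
#' @export
mean_square_velocity <- function(wave, positions) {
  fa <- field_amplitude(wave, positions)
  rowSums(fa$grad^2) * wave$fluid$compressibility /
    (2 * wave$fluid$density * wave$wavenumber^2)
}

#' Acoustic energy density of a standing wave
#'
#' \eqn{E_{ac} = \beta_f p_{ac}^2 / 4}, the standing-wave energy scale that
#' sets the magnitude of the 1-D radiation force.
#'
#' @param peak_pressure Peak pressure \eqn{p_{ac}} (Pa); zero allowed.
#' @param compressibility Fluid compressibility \eqn{\beta_f} (Pa^-1).
#' @return Energy density (J m^-3).
#' @export
#' @examples
#' acoustic_energy_density(2e5, 4.433e-10) # 4.433 J/m^3
acoustic_energy_density <- function(peak_pressure, compressibility) {
  check_nonnegative(peak_pressure, "peak_pressure")
  check_positive(compressibility, "compressibility")
  compressibility * peak_pressure^2 / 4
}
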