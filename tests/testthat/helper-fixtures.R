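# Shared fixtures: the reference water/cell pair and standard fields.

water <- water_properties()
cell <- nih3t3_properties()            # 10 um NIH/3T3 cell
cell_coeffs <- scattering_coefficients(cell, water)

lam <- 60e-6
p_ac <- 2e5
wave_1d <- standing_wave(lam, p_ac, axes = c(0, 1), fluid = water)
wave_2d <- standing_wave(lam, p_ac, axes = list(c(1, 0), c(0, 1)),
                         fluid = water)
e_ac <- acoustic_energy_density(p_ac, water$compressibility)

# independent oracle: time average of f(t)^2 over one period by trapezoid
time_average_sq <- function(f, period, n = 4001) {
  t <- seq(0, period, length.out = n)
  v <- f(t)^2
  sum((v[-1] + v[-n]) / 2) * (t[2] - t[1]) / period
}

# independent oracle: average of g over the ball of radius a centred at y0,
# for g varying along y only (1-D integral with cross-section weight)
ball_average_1d <- function(g, y0, a) {
  stats::integrate(function(u) g(y0 + u) * 3 * (a^2 - u^2) / (4 * a^3),
                   lower = -a, upper = a, rel.tol = 1e-12)$value
}
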