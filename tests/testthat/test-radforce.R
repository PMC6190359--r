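test_that("ideal-fluid scattering coefficients and contrast factor", {
  expect_equal(monopole_coefficient(3.78e-10, 4.433e-10), 0.1473,
               tolerance = 1e-3)
  expect_equal(monopole_coefficient(4.433e-10, 4.433e-10), 0)
  expect_equal(monopole_coefficient(1e-30, 4.433e-10), 1, tolerance = 1e-10)
  expect_equal(dipole_coefficient(1079, 1000), 0.0500, tolerance = 1e-2)
  expect_equal(dipole_coefficient(1000, 1000), 0)
  expect_equal(dipole_coefficient(1e12, 1000), 1, tolerance = 1e-8)
  expect_equal(cell_coeffs$contrast_factor,
               Re(cell_coeffs$f1) / 3 + Re(cell_coeffs$f2) / 2)
  expect_error(monopole_coefficient(-1e-10, 4e-10),
               class = "arftrace_domain_error")
})

test_that("Gorkov potential combines the field averages linearly", {
  v_bp <- particle_volume(cell)
  z <- gorkov_potential(tibble::tibble(p_sq = 0, v_sq = 0), cell_coeffs,
                        v_bp, water)
  expect_equal(z$u_rad, 0)
  # at an antinode the velocity term vanishes
  fq <- field_quantities(wave_1d, cbind(0, 0))
  u <- gorkov_potential(fq, cell_coeffs, v_bp, water)$u_rad
  expect_equal(u, v_bp * Re(cell_coeffs$f1) * water$compressibility *
                 p_ac^2 / 4, tolerance = 1e-12)
  # sign flips when both coefficients are negated
  neg <- cell_coeffs
  neg$f1 <- -neg$f1
  neg$f2 <- -neg$f2
  fq2 <- field_quantities(wave_1d, cbind(0, 7e-6))
  expect_equal(gorkov_potential(fq2, neg, v_bp, water)$u_rad,
               -gorkov_potential(fq2, cell_coeffs, v_bp, water)$u_rad)
})

test_that("small-particle force is the negative potential gradient", {
  v_bp <- particle_volume(cell)
  step <- lam * 1e-6
  pts <- rbind(c(0, 3e-6), c(0, 7.5e-6), c(5e-6, 23e-6), c(0, 41e-6))
  for (wave in list(wave_1d, wave_2d)) {
    f <- small_particle_force(wave, pts, cell, cell_coeffs)
    f_scale <- max(abs(as.matrix(f[, c("fx", "fy")])))
    for (i in seq_len(nrow(pts))) {
      for (ax in 1:2) {
        dp <- dm <- pts[i, , drop = FALSE]
        dp[ax] <- dp[ax] + step
        dm[ax] <- dm[ax] - step
        u_p <- gorkov_potential(field_quantities(wave, dp), cell_coeffs,
                                v_bp, water)$u_rad
        u_m <- gorkov_potential(field_quantities(wave, dm), cell_coeffs,
                                v_bp, water)$u_rad
        oracle <- -(u_p - u_m) / (2 * step)
        got <- as.numeric(f[i, c("fx", "fy")][[ax]])
        expect_lt(abs(got - oracle), 1e-6 * max(abs(oracle), f_scale))
      }
    }
  }
})

test_that("1-D force vanishes at nodes and antinodes and matches the closed form", {
  extremes <- cbind(0, seq(0, lam, by = lam / 4))
  f <- small_particle_force(wave_1d, extremes, cell, cell_coeffs)
  expect_equal(f$fy, rep(0, nrow(extremes)), tolerance = 1e-25)
  expect_equal(f$fx, rep(0, nrow(extremes)), tolerance = 1e-25)
  # closed form vs analytic gradient at several offsets from the node
  hs <- c(lam / 8, lam / 16, -lam / 12, 3e-6)
  for (h in hs) {
    cf <- closed_form_1d(h, cell$radius, wave_1d$wavenumber, e_ac,
                         cell_coeffs$contrast_factor)
    fy <- small_particle_force(wave_1d, cbind(0, lam / 4 - h), cell,
                               cell_coeffs)$fy
    expect_equal(fy, cf, tolerance = 1e-10)
  }
  # h = lambda/8 is the maximum of |sin|
  expect_equal(closed_form_1d(lam / 8, cell$radius, wave_1d$wavenumber,
                              e_ac, cell_coeffs$contrast_factor),
               4 * pi * cell_coeffs$contrast_factor * cell$radius^3 *
                 wave_1d$wavenumber * e_ac)
  expect_equal(closed_form_1d(0, cell$radius, wave_1d$wavenumber, e_ac,
                              cell_coeffs$contrast_factor), 0)
})

test_that("modifying factor: closed form, series limit, quadrature oracle", {
  # 10 um particle in a 60 um wave
  expect_equal(modifying_factor(pi * 10 / 60), 0.894, tolerance = 1e-3)
  # smooth across the series switchover and -> 1 as chi -> 0
  expect_equal(modifying_factor(0), 1)
  expect_equal(modifying_factor(1e-3), modifying_factor(1.0000001e-3),
               tolerance = 1e-9)
  expect_lt(abs(modifying_factor(1e-4) - 1), 1e-7)
  # independent oracle at chi = 1: ball average of sin(2ky)/sin(2kh)
  k <- wave_1d$wavenumber
  a <- 1 / k                      # chi = ka = 1
  h <- lam / 8
  y0 <- lam / 4 - h
  oracle <- ball_average_1d(function(y) sin(2 * k * (lam / 4 - y)), y0, a) /
    sin(2 * k * h)
  expect_equal(modifying_factor(1), oracle, tolerance = 1e-9)
})

test_that("modifying factor decreases to a single zero crossing near 0.715", {
  ratio <- zero_crossing_ratio()
  expect_equal(round(ratio, 2), 0.72)
  expect_lt(abs(modifying_factor(ratio * pi)), 1e-10)
  # brute-force scan brackets the same root
  grid <- seq(1e-4, 1, by = 1e-4)
  fm <- modifying_factor(grid * pi)
  sign_change <- grid[which(diff(sign(fm)) != 0)[1]]
  expect_lt(abs(sign_change - ratio), 2e-4)
  # strictly decreasing before the crossing
  pre <- modifying_factor(seq(0.01, ratio * pi - 0.01, length.out = 100))
  expect_true(all(diff(pre) < 0))
  expect_error(modifying_factor(-0.1), class = "arftrace_domain_error")
})

test_that("volume-averaged force reproduces the closed form across sizes", {
  k <- wave_1d$wavenumber
  h <- lam / 8
  pos <- cbind(0, lam / 4 - h)
  for (ratio in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    a <- ratio * lam / 2
    p <- particle_properties(cell$density, cell$compressibility, radius = a,
                             shear_modulus = cell$shear_modulus)
    expected <- closed_form_1d(h, a, k, e_ac, cell_coeffs$contrast_factor) *
      modifying_factor(k * a)
    for (method in c("ball", "axis")) {
      got <- finite_size_force(wave_1d, pos, p, cell_coeffs,
                               method = method)$fy
      expect_equal(got, expected, tolerance = 1e-3)
    }
  }
})

test_that("finite-size force recovers the point force as a -> 0", {
  tiny <- particle_properties(cell$density, cell$compressibility,
                              radius = 1e-9,
                              shear_modulus = cell$shear_modulus)
  pos <- cbind(0, 7.5e-6)
  fs <- finite_size_force(wave_1d, pos, tiny, cell_coeffs, method = "ball")
  fp <- small_particle_force(wave_1d, pos, tiny, cell_coeffs)
  expect_equal(fs$fy, fp$fy, tolerance = 1e-6)
})

test_that("2-D disk and 3-D ball quadratures agree on a z-invariant field", {
  pts <- rbind(c(4e-6, 9e-6), c(21e-6, 33e-6))
  p <- particle_properties(cell$density, cell$compressibility,
                           radius = 6e-6,
                           shear_modulus = cell$shear_modulus)
  ball <- finite_size_force(wave_2d, pts, p, cell_coeffs, method = "ball")
  disk <- finite_size_force(wave_2d, pts, p, cell_coeffs, method = "disk")
  expect_equal(disk$fx, ball$fx, tolerance = 1e-5)
  expect_equal(disk$fy, ball$fy, tolerance = 1e-5)
})

test_that("lattice nodes and antinodes carry negligible finite-size force", {
  p <- particle_properties(cell$density, cell$compressibility,
                           radius = 0.2 * lam / 2,
                           shear_modulus = cell$shear_modulus)
  special <- rbind(c(0, 0), c(lam / 2, lam / 2),      # antinodes
                   c(lam / 4, lam / 4), c(3 * lam / 4, lam / 4))  # nodes
  f <- finite_size_force(wave_2d, special, p, cell_coeffs, method = "disk")
  # compare against the maximal force over a reference grid
  grid <- as.matrix(expand.grid(seq(0, lam, length.out = 17),
                                seq(0, lam, length.out = 17)))
  fmax <- max(sqrt(rowSums(as.matrix(
    finite_size_force(wave_2d, grid, p, cell_coeffs,
                      method = "disk")[, c("fx", "fy")])^2)))
  mags <- sqrt(f$fx^2 + f$fy^2)
  expect_true(all(mags < 1e-3 * fmax))
})

test_that("force maps inherit the field's periodicity and decay with size", {
  p02 <- particle_properties(cell$density, cell$compressibility,
                             radius = 0.2 * lam / 2,
                             shear_modulus = cell$shear_modulus)
  m_small <- force_map(wave_1d, p02, cell_coeffs,
                       bbox = c(0, lam, 0, lam), resolution = 8,
                       model = "small_particle")
  # sinusoidal with period lambda/2 along the axis
  ys <- sort(unique(m_small$y))
  prof <- dplyr::filter(m_small, .data$x == 0)
  prof <- prof$fy[match(ys, prof$y)]
  shift <- match(TRUE, abs(ys - (ys[1] + lam / 2)) < 1e-12)
  expect_equal(prof[seq_len(length(ys) - shift + 1)],
               prof[seq(shift, length(ys))], tolerance = 1e-10)
  # the ratio field F/Fs is not a constant across positions (2-D field)
  p04 <- particle_properties(cell$density, cell$compressibility,
                             radius = 0.4 * lam / 2,
                             shear_modulus = cell$shear_modulus)
  m_f02 <- force_map(wave_2d, p02, cell_coeffs, bbox = c(0, lam, 0, lam),
                     resolution = 8, model = "finite_size")
  m_s02 <- force_map(wave_2d, p02, cell_coeffs, bbox = c(0, lam, 0, lam),
                     resolution = 8, model = "small_particle")
  ratio <- m_f02$f_mag / m_s02$f_mag
  ratio <- ratio[m_s02$f_mag > 1e-3 * max(m_s02$f_mag)]
  expect_gt(stats::sd(ratio) / mean(ratio), 0.05)
  # normalised map maximum decays with particle size (f_m decay)
  m_f04 <- force_map(wave_2d, p04, cell_coeffs, bbox = c(0, lam, 0, lam),
                     resolution = 8, model = "finite_size")
  m_s04 <- force_map(wave_2d, p04, cell_coeffs, bbox = c(0, lam, 0, lam),
                     resolution = 8, model = "small_particle")
  expect_lt(max(m_f04$f_mag) / max(m_s04$f_mag),
            max(m_f02$f_mag) / max(m_s02$f_mag))
  expect_true(all(is.finite(m_f04$f_mag)))
  expect_error(force_map(wave_1d, p02, cell_coeffs,
                         bbox = c(0, lam, 0, lam), resolution = 4),
               class = "arftrace_config_error")
  expect_error(force_map(wave_1d, p02, cell_coeffs, bbox = c(0, 0, 0, lam)),
               class = "arftrace_config_error")
})

test_that("difference metric is a normalised L1 distance", {
  f_ref <- c(1, -2, 3, 0.5)
  expect_equal(difference_metric(f_ref, f_ref), 0)
  expect_equal(difference_metric(2 * f_ref, f_ref), 1)
  # hand-computed on a 20-point modifying-factor curve
  ratios <- seq(0.05, 1, length.out = 20)
  chi <- pi * ratios
  f_small <- sin(2 * pi / 3)^0 * chi^0   # constant reference, f_m = 1
  f_fin <- modifying_factor(chi)
  expect_equal(difference_metric(f_fin, f_small),
               sum(abs(f_fin - 1)) / 20)
  expect_error(difference_metric(c(1, 2), c(0, 0)),
               class = "arftrace_metric_error")
  expect_error(difference_metric(c(1, 2), c(1, 2, 3)),
               class = "arftrace_domain_error")
})

test_that("force curve couples the three routes and reports their distance", {
  fc <- force_curve(water, cell, lam, p_ac,
                    ratios = c(0.05, 1 / 6, 0.4, 0.72, 0.9))
  expect_s3_class(fc, "force_curve")
  expect_equal(fc$f_closed, fc$f_small * fc$f_m)
  expect_lt(attr(fc, "difference_closed_quad"), 1e-3)
  # F1D / F1Ds at Dp/lambda = 1/6 is ~0.894
  expect_equal(fc$f_quad[2] / fc$f_small[2], 0.894, tolerance = 1e-3)
  gl <- glance(fc)
  expect_equal(gl$n_ratios, 5L)
  td <- tidy(fc)
  expect_named(td, c("ratio", "chi", "f_small", "f_closed", "f_quad", "f_m"))
})
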