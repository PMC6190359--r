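test_that("Stokes mobility follows 1/(6 pi mu a)", {
  expect_equal(drag_mobility(5e-6, 8.538e-4), 1.243e7, tolerance = 1e-3)
  expect_equal(drag_mobility(2 * 5e-6, 8.538e-4),
               drag_mobility(5e-6, 8.538e-4) / 2)
  expect_equal(drag_mobility(1 / (6 * pi), 1), 1)
  expect_error(drag_mobility(0, 1e-3), class = "arftrace_domain_error")
})

test_that("zero acoustic pressure gives straight streamline motion", {
  ch <- channel_spec(240e-6, 200e-6, 1e-2, cuts = c(108e-6, 132e-6))
  tr <- advance_trajectory(wave_1d, cell, r0 = c(0, 97e-6),
                           duration = 0.02, channel = ch,
                           force_scale = 0)
  expect_equal(tr$y, rep(97e-6, nrow(tr)), tolerance = 1e-12)
  expect_equal(tr$x[nrow(tr)], 1e-2 * tr$t[nrow(tr)], tolerance = 1e-9)
})

test_that("particles with positive contrast converge monotonically to the node", {
  # release lambda/8 from the node at lambda/4
  r0 <- c(0, lam / 4 - lam / 8)
  tr <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 0.5)
  node <- lam / 4
  expect_lt(abs(tr$y[nrow(tr)] - node), 1e-3 * lam)
  gaps <- abs(tr$y - node)
  expect_true(all(diff(gaps) <= 1e-12))
  expect_true(all(diff(tr$t) > 0))
  expect_true(all(is.finite(tr$y)))
})

test_that("finite-size arrival is slower by 1/f_m in the linear regime", {
  fm <- modifying_factor(wave_1d$wavenumber * cell$radius)
  # small displacement about the node: rate ratio approaches f_m
  h0 <- 0.01 * lam
  t_lin <- 1e-4
  node <- lam / 4
  d_of <- function(model) {
    tr <- advance_trajectory(wave_1d, cell, r0 = c(0, node - h0),
                             duration = t_lin, model = model)
    tr$y[nrow(tr)] - (node - h0)
  }
  ratio <- d_of("finite_size") / d_of("small_particle")
  expect_equal(ratio, fm, tolerance = 1e-2)
  # arrival time to a fixed intermediate gap scales as ~1/f_m
  t_arrive <- function(model) {
    tr <- advance_trajectory(wave_1d, cell, r0 = c(0, node - lam / 12),
                             duration = 0.1, model = model, n_out = 2001)
    tr$t[match(TRUE, abs(tr$y - node) < lam / 40)]
  }
  expect_equal(t_arrive("finite_size") / t_arrive("small_particle"),
               1 / fm, tolerance = 5e-2)
})

test_that("fixed-step integration is deterministic to the bit", {
  r0 <- c(0, 22e-6)
  tr1 <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 0.01,
                            method = "fixed", n_out = 101)
  tr2 <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 0.01,
                            method = "fixed", n_out = 101)
  expect_identical(tr1$y, tr2$y)
  expect_identical(tr1$x, tr2$x)
})

test_that("tightening the solver tolerance barely moves the endpoint", {
  ch <- channel_spec(240e-6, 200e-6, 1e-2, cuts = c(108e-6, 132e-6))
  r0 <- c(0, 114e-6)
  end_y <- function(rtol) {
    tr <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 0.02,
                             channel = ch, rtol = rtol, atol = rtol * 1e-4)
    tr$y[nrow(tr)]
  }
  expect_lt(abs(end_y(1e-8) - end_y(5e-9)), 1e-4 * lam)
})

test_that("inertial mode agrees with quasi-static tracing for micron particles", {
  # Stokes response time ~ rho_p a^2 / mu is microseconds; over millisecond
  # transport the massless approximation should match closely
  r0 <- c(0, 22e-6)
  qs <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 5e-3)
  inert <- advance_trajectory(wave_1d, cell, r0 = r0, duration = 5e-3,
                              inertial = TRUE)
  expect_lt(abs(qs$y[nrow(qs)] - inert$y[nrow(inert)]), 1e-3 * lam)
})

test_that("separation fixture: finite size loses exactly the farthest particle", {
  ch <- channel_spec(240e-6, 200e-6, 1e-2, cuts = c(108e-6, 132e-6))
  rep_ <- simulate_separation(ch, wave_1d, cell,
                              release_y = c(110e-6, 114e-6, 118e-6))
  asg <- tidy(rep_)
  small <- dplyr::filter(asg, .data$model == "small_particle")
  fin <- dplyr::filter(asg, .data$model == "finite_size")
  expect_true(all(small$outlet == "side"))
  expect_equal(sum(fin$outlet == "center"), 1L)
  expect_equal(fin$outlet[fin$particle == "P3"], "center")
  # report partitions the particle set
  gl <- glance(rep_)
  expect_true(all(gl$n_side + gl$n_center == gl$n_released))
  # finite size never captures more than small-particle
  expect_lte(gl$n_side[gl$model == "finite_size"],
             gl$n_side[gl$model == "small_particle"])
})

test_that("capture count responds to pressure as expected", {
  ch <- channel_spec(240e-6, 200e-6, 1e-2, cuts = c(108e-6, 132e-6))
  release <- c(110e-6, 114e-6, 118e-6)
  n_side <- function(scale) {
    rep_ <- simulate_separation(ch, wave_1d, cell, release_y = release,
                                models = "small_particle",
                                force_scale = scale)
    glance(rep_)$n_side
  }
  # force off: all stay on their release streamline (center)
  expect_equal(n_side(0), 0L)
  # capture count is monotone non-decreasing in the force scale (p_ac^2)
  counts <- vapply(c(0, 0.25, 0.5, 1, 2), n_side, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("release outside the channel and bad channels are rejected", {
  ch <- channel_spec(240e-6, 200e-6, 1e-2, cuts = c(108e-6, 132e-6))
  expect_error(advance_trajectory(wave_1d, cell, r0 = c(0, 300e-6),
                                  duration = 0.01, channel = ch),
               class = "arftrace_domain_error")
  expect_error(channel_spec(240e-6, 200e-6, 1e-2, cuts = c(250e-6, 260e-6)),
               class = "arftrace_domain_error")
  expect_error(simulate_separation(ch, wave_1d, cell,
                                   release_y = numeric(0)),
               class = "arftrace_domain_error")
})

test_that("stable equilibria sit on the node lattice (and antinodes for negative contrast)", {
  eq <- find_equilibria(wave_1d, cell, bbox = c(-1e-6, 1e-6, 0, lam),
                        n_seeds = 4)
  stable <- dplyr::filter(eq, .data$stable)
  expect_gt(nrow(stable), 0)
  node_dist <- vapply(stable$y, function(y) {
    min(abs(y - c(lam / 4, 3 * lam / 4)))
  }, numeric(1))
  expect_true(all(node_dist < 1e-3 * lam))

  # 2-D in-phase lattice: stable points lie on the node lines
  # |cos kx + cos ky| = 0
  eq2 <- find_equilibria(wave_2d, cell, bbox = c(0, lam, 0, lam),
                         n_seeds = 4)
  stable2 <- dplyr::filter(eq2, .data$stable)
  expect_gt(nrow(stable2), 0)
  k <- wave_2d$wavenumber
  amp <- abs(cos(k * stable2$x) + cos(k * stable2$y))
  expect_true(all(amp < 1e-2))

  # compressibility-dominated negative contrast flips stability to antinodes
  bubblelike <- particle_properties(1.0e3, 9e-10, radius = 5e-6)
  expect_lt(scattering_coefficients(bubblelike, water)$contrast_factor, 0)
  eq3 <- find_equilibria(wave_1d, bubblelike,
                         bbox = c(-1e-6, 1e-6, 0, lam), n_seeds = 4)
  stable3 <- dplyr::filter(eq3, .data$stable)
  anti_dist <- vapply(stable3$y, function(y) {
    min(abs(y - c(0, lam / 2, lam)))
  }, numeric(1))
  expect_true(all(anti_dist < 1e-3 * lam))
})
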