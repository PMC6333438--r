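test_that("simulated contact force matches the Hertz closed form", {
  # independent evaluation of F = (4/3) K delta^(3/2) sqrt(R) in nN/um/Pa
  K <- 100; R <- 18.64; delta <- 10
  expected <- (4 / 3) * K * delta^1.5 * sqrt(R) * 1e-3
  expect_equal(hertz_force(K, delta, R), expected)
  expect_equal(expected, 18.2, tolerance = 0.005)

  # simulated curve with a rigid cantilever (huge k): force at given
  # piezo-depth equals the closed form because deflection is negligible
  sc <- afm_scene(noise = curve_noise_params(force_noise_sd = 0,
                                             baseline_slope = 0,
                                             baseline_offset = 0),
                  spring_constant = 1e6, max_force = 25)
  fc <- simulate_force_curve(100, sc, seed = 1)
  z_c <- attr(fc, "z_c_true_um")
  idx <- which.min(abs(fc$z_um - (z_c + 10)))
  expect_equal(fc$force_nN[idx],
               hertz_force(100, fc$z_um[idx] - z_c, 18.64),
               tolerance = 1e-7)
})

test_that("contact is continuous at zero indentation and respects coupling", {
  sc <- afm_scene(noise = curve_noise_params(force_noise_sd = 0,
                                             baseline_slope = 0,
                                             baseline_offset = 0))
  fc <- simulate_force_curve(150, sc, seed = 1)
  z_c <- attr(fc, "z_c_true_um")
  expect_equal(max(abs(fc$force_nN[fc$z_um <= z_c])), 0)
  # every contact sample satisfies the implicit deflection-coupled relation
  k <- attr(fc, "k_N_per_m")
  contact <- fc$z_um > z_c
  delta <- (fc$z_um[contact] - z_c) - fc$force_nN[contact] / (1e3 * k)
  expect_equal(fc$force_nN[contact], hertz_force(150, delta, 18.64),
               tolerance = 1e-9)
  # truncated at the first sample reaching max force
  expect_gte(max(fc$force_nN), sc$max_force)
  expect_lt(sum(fc$force_nN >= sc$max_force), 3)
})

test_that("curve simulation is bit-identical under a fixed seed", {
  sc <- tiny_scene()
  a <- simulate_force_curve(120, sc, seed = 42)
  b <- simulate_force_curve(120, sc, seed = 42)
  expect_identical(a$force_nN, b$force_nN)
  s1 <- simulate_map_series(sc)
  s2 <- simulate_map_series(sc)
  expect_identical(s1$curves[[1]][[5]]$force_nN, s2$curves[[1]][[5]]$force_nN)
  expect_identical(s1$dropout, s2$dropout)
})

test_that("dropout produces stubs at the configured rate", {
  sc <- tiny_scene(nx = 10, ny = 10, n_frames = 4, dropout = 0.2, seed = 7)
  sim <- simulate_map_series(sc)
  n <- nrow(sim$dropout)
  k <- sum(sim$dropout$stub)
  # binomial 99% interval for p = 0.2, n = 400 (computed via qbinom)
  expect_gte(k, qbinom(0.005, n, 0.2))
  expect_lte(k, qbinom(0.995, n, 0.2))
  # dropout 0 -> every node analysable
  sim0 <- simulate_map_series(tiny_scene(dropout = 0))
  expect_false(any(sim0$dropout$stub))
})

test_that("generator and fitter close the loop on a noiseless grid", {
  sc <- tiny_scene(force_noise_sd = 0, n_frames = 1)
  sim <- simulate_map_series(sc)
  m <- process_grid(sim$curves[[1]], spacing = sc$field$spacing)
  expect_true(all(m$status == "accepted"))
  rel <- abs(m$K_Pa - as.vector(sim$truth$K[, , 1])) /
    as.vector(sim$truth$K[, , 1])
  expect_lt(max(rel), 1e-6)
})
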