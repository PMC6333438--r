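test_that("deflection converts to force by Hooke's law and is idempotent", {
  d <- tibble::tibble(z_um = seq(0, 5, length.out = 100),
                      deflection_um = 0.5)
  fc <- force_curve(d, k_N_per_m = 0.03, R_um = 18.64)
  out <- deflection_to_force(fc)
  expect_equal(out$force_nN, rep(15, 100))
  expect_identical(deflection_to_force(out), out)
  z <- tibble::tibble(z_um = seq(0, 5, length.out = 100), deflection_um = 0)
  expect_equal(deflection_to_force(force_curve(z, 0.03, 18.64))$force_nN,
               rep(0, 100))
})

test_that("baseline fit recovers an injected drift and rejects noise stubs", {
  sc <- afm_scene(noise = curve_noise_params(force_noise_sd = 0.05,
                                             baseline_slope = 0.01,
                                             baseline_offset = 0.2))
  set.seed(1)
  slopes <- replicate(20, {
    fc <- simulate_force_curve(150, sc)
    fit_baseline(fc)$slope
  })
  # OLS oracle: slope estimates scatter around the injected 0.01 nN/um
  expect_equal(mean(slopes), 0.01, tolerance = 0.25)
  expect_lt(abs(mean(slopes) - 0.01), 2 * sd(slopes) / sqrt(20) + 1e-4)

  # flat zero baseline
  scf <- afm_scene(noise = curve_noise_params(force_noise_sd = 0,
                                              baseline_slope = 0,
                                              baseline_offset = 0))
  bf <- fit_baseline(simulate_force_curve(150, scf, seed = 1))
  expect_equal(bf$slope, 0, tolerance = 1e-9)
  expect_equal(bf$intercept, 0, tolerance = 1e-9)

  # pure-noise stub: baseline criterion fails
  stub <- simulate_stub_curve(sc, seed = 3)
  expect_identical(fit_baseline(stub)$status, "excluded")
  expect_identical(fit_hertz(stub)$reason, "baseline")
})

test_that("optimised contact point matches a brute-force grid search", {
  sc <- afm_scene()
  set.seed(11)
  for (rep in 1:6) {
    K_true <- runif(1, 30, 300)
    fc <- simulate_force_curve(K_true, sc, contact_frac = runif(1))
    fit <- fit_hertz(fc)
    expect_identical(fit$status, "accepted")

    # independent brute force: fine z_c grid, closed-form K per candidate
    bl <- fit_baseline(fc)
    z <- fc$z_um
    Fc <- fc$force_nN - (bl$intercept + bl$slope * z)
    k <- attr(fc, "k_N_per_m")
    pref <- (4 / 3) * sqrt(attr(fc, "R_um")) * 1e-3
    i_end <- if (any(Fc >= 10)) which(Fc >= 10)[1] else length(Fc)
    region <- max(1, bl$provisional_index - 400):i_end
    zr <- z[region]; Fr <- Fc[region]
    zc_grid <- seq(zr[1], z[which(Fc > 2)[1]], length.out = 400)
    sse <- vapply(zc_grid, function(zc) {
      ct <- zr > zc
      delta <- pmax((zr[ct] - zc) - Fr[ct] / (1e3 * k), 0)
      x <- pref * delta^1.5
      Kc <- sum(Fr[ct] * x) / sum(x * x)
      sum(Fr[!ct]^2) + sum((Fr[ct] - Kc * x)^2)
    }, numeric(1))
    zc_best <- zc_grid[which.min(sse)]
    dz_grid <- diff(zc_grid[1:2])
    expect_lt(abs(fit$contact_z_um - zc_best), 2 * dz_grid)
    ct <- zr > zc_best
    delta <- pmax((zr[ct] - zc_best) - Fr[ct] / (1e3 * k), 0)
    x <- pref * delta^1.5
    K_grid <- sum(Fr[ct] * x) / sum(x * x)
    expect_equal(fit$K_Pa, K_grid, tolerance = 0.01)
  }
})

test_that("fitting is invariant to force offsets and z shifts, linear in force", {
  scf <- afm_scene(noise = curve_noise_params(force_noise_sd = 0,
                                              baseline_slope = 0,
                                              baseline_offset = 0))
  fc <- simulate_force_curve(120, scf, seed = 5)
  base <- fit_hertz(fc)
  m <- attr(fc, "k_N_per_m")

  shifted <- force_curve(
    tibble::tibble(z_um = fc$z_um + 3.7, force_nN = fc$force_nN + 0.8),
    attr(fc, "k_N_per_m"), attr(fc, "R_um"))
  fs <- fit_hertz(shifted)
  expect_equal(fs$K_Pa, base$K_Pa, tolerance = 1e-6)
  expect_equal(fs$contact_z_um - base$contact_z_um, 3.7, tolerance = 1e-4)

  # scaling all forces by c scales K by c (analysis force scaled too)
  scaled <- force_curve(
    tibble::tibble(z_um = fc$z_um, force_nN = 0.5 * fc$force_nN),
    attr(fc, "k_N_per_m") * 0.5, attr(fc, "R_um"))
  fsc <- fit_hertz(scaled, analysis_force = 5)
  expect_equal(fsc$K_Pa, 0.5 * base$K_Pa, tolerance = 1e-4)
})

test_that("curves truncated below the analysis force are excluded", {
  sc <- afm_scene(max_force = 6)   # approach stops at 6 nN
  fc <- simulate_force_curve(120, sc, seed = 2)
  fit <- fit_hertz(fc, analysis_force = 10)
  expect_identical(fit$status, "excluded")
  expect_identical(fit$reason, "hertz_fit")
  expect_true(is.na(fit$K_Pa))
})

test_that("process_grid books missing nodes against injected stubs", {
  sc <- tiny_scene(nx = 5, ny = 4, n_frames = 1, dropout = 0.3, seed = 9)
  sim <- simulate_map_series(sc)
  m <- process_grid(sim$curves[[1]], spacing = sc$field$spacing)
  stubs <- sim$dropout$stub[sim$dropout$frame == 1]
  expect_identical(sum(m$status != "accepted"), sum(stubs))
  key <- paste(m$i, m$j)
  stub_key <- paste(sim$dropout$i, sim$dropout$j)[sim$dropout$frame == 1 & stubs]
  expect_setequal(key[m$status != "accepted"], stub_key)
  expect_error(process_grid(list()), "empty")
})
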