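test_that("rescaling follows the printed min-max formula and is idempotent", {
  expect_equal(rescale_series(c(2, 5, 8)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.5, 1)
  expect_equal(rescale_series(x), x)
  set.seed(1)
  y <- rnorm(20)
  expect_equal(rescale_series(3 * y - 7), rescale_series(y))   # affine invariance
  expect_equal(rescale_series(rescale_series(y)), rescale_series(y))
  expect_error(rescale_series(rep(1, 5)), "constant")
})

test_that("linear fits reproduce the closed-form OLS solution", {
  d <- tibble::tibble(t = 0:5, y = 2 * (0:5) + 1)
  fit <- linear_fit(d, t, y)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(linear_fit(tibble::tibble(t = 0:5, y = rep(3, 6)), t, y)$slope, 0)

  set.seed(2)
  t <- runif(15, 0, 100); y <- rnorm(15)
  fit <- linear_fit(tibble::tibble(t = t, y = y), t, y)
  # normal equations written out independently
  sxx <- sum((t - mean(t))^2); sxy <- sum((t - mean(t)) * (y - mean(y)))
  expect_equal(fit$slope, sxy / sxx)
  expect_equal(fit$intercept, mean(y) - fit$slope * mean(t))
})

test_that("onset is the zero-crossing of the rescaled fit", {
  d <- tibble::tibble(t = c(40, 120), y = c(0, 1))
  d3 <- tibble::tibble(t = c(40, 80, 120), y = c(0, 0.5, 1))
  fit <- fit_onset(d3, t, y, kind = "gradient", rescale = FALSE,
                   fit_window = "all")
  expect_equal(fit$onset_min, 40)
  # line crossing zero at t = 0
  d0 <- tibble::tibble(t = c(0, 50, 100), y = c(0, 0.5, 1))
  expect_equal(fit_onset(d0, t, y, fit_window = "all")$onset_min, 0)
  # onset undefined for non-increasing series
  dn <- tibble::tibble(t = 0:5, y = c(5, 4, 3, 2, 1, 0) + 0.01 * rnorm(6))
  expect_true(is.na(fit_onset(dn, t, y)$onset_min))
  expect_error(onset_delay(fit_onset(dn, t, y), fit_onset(d0, t, y)),
               "undefined")
})

test_that("onset extrapolation recovers the injected gradient onset", {
  sc <- afm_scene(field = field_params(gradient_onset = 40),
                  gradient_noise_sd = 0)
  g <- simulate_gradient_series(sc)
  fit <- fit_onset(g, t_min, gradient_Pa_per_um, kind = "gradient")
  # hinge sampled every 35 min: rise-window fit recovers the hinge exactly
  expect_equal(fit$onset_min, 40, tolerance = 1e-6)
})

test_that("delay subtracts per-scene onsets and summarises a cohort", {
  mk <- function(onset) {
    d <- tibble::tibble(t = seq(0, 200, 20), y = pmax(0, seq(0, 200, 20) - onset))
    fit_onset(d, t, y)
  }
  expect_equal(onset_delay(mk(40), mk(58))$delay_min, 18, tolerance = 1e-9)
  expect_equal(onset_delay(mk(40), mk(40))$delay_min, 0, tolerance = 1e-9)
  delays <- dplyr::bind_rows(lapply(c(10, 20, 30), function(d)
    onset_delay(mk(40), mk(40 + d))))
  ds <- delay_summary(delays)
  expect_equal(ds$mean_delay_min, 20, tolerance = 1e-9)
  expect_equal(ds$n, 3L)
})

test_that("delay is invariant to a common time offset", {
  sc <- afm_scene(field = field_params(gradient_onset = 40), turn_delay = 15,
                  gradient_noise_sd = 0, angle_noise_sd = 0)
  ser <- simulate_kinetics_series(sc, seed = 1)
  f1g <- fit_onset(ser, t_min, gradient_Pa_per_um, "gradient")
  f1t <- fit_onset(ser, t_min, turn_deg, "turn_angle")
  d1 <- onset_delay(f1g, f1t)$delay_min
  shifted <- dplyr::mutate(ser, t_min = t_min + 123)
  f2g <- fit_onset(shifted, t_min, gradient_Pa_per_um, "gradient")
  f2t <- fit_onset(shifted, t_min, turn_deg, "turn_angle")
  expect_equal(onset_delay(f2g, f2t)$delay_min, d1, tolerance = 1e-6)
})

test_that("stage binning and the density correlation match closed forms", {
  w <- tibble::tibble(stage = c("a", "b"), t_start = c(0, 100),
                      t_end = c(100, 200))
  d <- tibble::tibble(t = c(10, 50, 150), g = c(1, 3, 10))
  b <- bin_by_stage(d, w, t, g)
  expect_equal(b$mean_value, c(2, 10))

  prop <- tibble::tibble(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(gradient_correlation(prop, x, y)$pearson_rho, 1)
  anti <- tibble::tibble(x = c(1, 2, 3), y = c(6, 4, 2))
  expect_equal(gradient_correlation(anti, x, y)$pearson_rho, -1)

  set.seed(3)
  r <- tibble::tibble(x = rnorm(10), y = rnorm(10))
  got <- gradient_correlation(r, x, y)
  # covariance formula evaluated directly
  rho <- sum((r$x - mean(r$x)) * (r$y - mean(r$y))) /
    sqrt(sum((r$x - mean(r$x))^2) * sum((r$y - mean(r$y))^2))
  expect_equal(got$pearson_rho, rho)
  expect_error(gradient_correlation(r[1:2, ], x, y), ">= 3")
})

test_that("recovered delays track injected delays across noisy scenes", {
  set.seed(11)
  injected <- runif(12, 5, 30)
  recovered <- vapply(seq_along(injected), function(s) {
    sc <- afm_scene(field = field_params(gradient_onset = 40),
                    turn_delay = injected[s])
    ser <- simulate_kinetics_series(sc)
    fg <- fit_onset(ser, t_min, gradient_Pa_per_um, "gradient")
    ft <- fit_onset(ser, t_min, turn_deg, "turn_angle")
    onset_delay(fg, ft)$delay_min
  }, numeric(1))
  fit <- lm(recovered ~ injected)
  expect_gt(coef(fit)[2], 0.8)
  expect_lt(coef(fit)[2], 1.2)
  expect_true(all(recovered[injected >= 10] > 0))
})
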