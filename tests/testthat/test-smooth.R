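test_that("constants pass through the smoother and masked entries impute to them", {
  y <- array(7, c(5, 4, 3))
  for (s in c(0.01, 1, 100)) {
    expect_equal(dct_pls_smooth(y, s = s)$z, y)
  }
  set.seed(2)
  mask <- array(runif(60) > 0.3, c(5, 4, 3))
  sm <- dct_pls_smooth(y, mask = mask, s = 1)
  expect_equal(sm$z, y, tolerance = 1e-8)
  expect_identical(sm$n_imputed, sum(!mask))
})

test_that("DCT solution equals the dense Neumann-Laplacian solve", {
  set.seed(3)
  for (rep in 1:5) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:4, 1))
    y <- array(rnorm(prod(d), 100, 10), d)
    s <- 10^runif(1, -2, 2)
    expect_equal(dct_pls_smooth(y, s = s)$z, dense_dct_solve(y, s),
                 tolerance = 1e-10)
    mask <- array(runif(prod(d)) > 0.25, d)
    if (!any(mask)) next
    expect_lt(max(abs(dct_pls_smooth(y, mask = mask, s = s)$z -
                        dense_dct_solve(y, s, mask = mask))), 1e-8)
  }
})

test_that("axis-permuted inputs give axis-permuted results", {
  set.seed(4)
  y <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  z <- dct_pls_smooth(y, s = 2)$z
  zp <- dct_pls_smooth(aperm(y, c(2, 3, 1)), s = 2)$z
  expect_equal(aperm(zp, c(3, 1, 2)), z, tolerance = 1e-12)
})

test_that("anisotropic spacing matches the step-scaled dense penalty", {
  set.seed(5)
  y <- array(rnorm(4 * 4 * 3, 50, 5), c(4, 4, 3))
  sp <- c(20, 20, 35)
  expect_equal(dct_pls_smooth(y, s = 1e4, spacing = sp)$z,
               dense_dct_solve(y, 1e4, spacing = sp), tolerance = 1e-8)
})

test_that("smoothing is linear in y and preserves the mean with full weights", {
  set.seed(6)
  y1 <- array(rnorm(48), c(4, 4, 3))
  y2 <- array(rnorm(48), c(4, 4, 3))
  s <- 3
  z12 <- dct_pls_smooth(2 * y1 + 5 * y2, s = s)$z
  expect_equal(z12, 2 * dct_pls_smooth(y1, s = s)$z +
                 5 * dct_pls_smooth(y2, s = s)$z, tolerance = 1e-10)
  expect_equal(mean(dct_pls_smooth(y1, s = 50)$z), mean(y1))
  # s -> 0 returns the data
  expect_equal(dct_pls_smooth(y1, s = 0)$z, y1, tolerance = 1e-12)
})

test_that("GCV picks maximal smoothing for white noise, minimal for smooth signals", {
  set.seed(7)
  noise <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  grid200 <- 10^seq(-6, 6, length.out = 200)
  scores_n <- vapply(grid200, function(s) gcv_score(noise, s), numeric(1))
  s_n <- select_smoothing_parameter(noise)
  # optimiser agrees with a 200-point brute-force scan
  expect_lte(abs(log10(s_n) - log10(grid200[which.min(scores_n)])),
             diff(log10(grid200[1:2])) * 2 + 0.1)
  expect_gte(log10(s_n), 4)      # at or near the upper bound

  ramp <- array(outer(seq(0, 1, length.out = 6),
                      seq(0, 1, length.out = 6), `+`), c(6, 6, 4))
  for (f in 1:4) ramp[, , f] <- ramp[, , 1] + 0.5 * f
  scores_r <- vapply(grid200, function(s) gcv_score(ramp + 1e-9, s), numeric(1))
  s_r <- select_smoothing_parameter(ramp + 1e-9)
  expect_lte(abs(log10(s_r) - log10(grid200[which.min(scores_r)])),
             diff(log10(grid200[1:2])) * 2 + 0.1)
  sm <- dct_pls_smooth(ramp, s = s_r)
  expect_lt(max(abs(sm$z - ramp)) / diff(range(ramp)), 0.01)
})

test_that("robust mode neutralises a gross outlier and matches plain mode otherwise", {
  set.seed(8)
  field <- array(100 + outer(1:6, 1:6, `+`), c(6, 6, 4)) +
    array(rnorm(144, 0, 0.5), c(6, 6, 4))
  truth <- array(100 + outer(1:6, 1:6, `+`), c(6, 6, 4))
  clean_r <- dct_pls_smooth(field, s = 5, robust = TRUE)
  clean_p <- dct_pls_smooth(field, s = 5)
  expect_lt(max(abs(clean_r$z - clean_p$z)) / max(abs(clean_p$z)), 1e-2)

  spiked <- field
  spiked[3, 3, 2] <- field[3, 3, 2] + 10 * diff(range(truth))
  plain <- dct_pls_smooth(spiked, s = 5)
  robust <- dct_pls_smooth(spiked, s = 5, robust = TRUE)
  err_plain <- abs(plain$z[3, 3, 2] - truth[3, 3, 2])
  err_robust <- abs(robust$z[3, 3, 2] - truth[3, 3, 2])
  expect_lt(err_robust, 0.2 * err_plain)
  expect_lt(robust$robust_weights[3, 3, 2], 0.1)

  # bisquare formula evaluated independently on the final residuals
  r <- spiked - robust$z
  madr <- median(abs(r - median(r)))
  u <- abs(r[3, 3, 2]) / (1.4826 * madr)
  expect_true(u > 4.685)  # outside the bisquare support, weight must be 0
  expect_identical(robust$robust_weights[3, 3, 2], 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(dct_pls_smooth(array(NA_real_, c(3, 3, 2)), s = 1), "missing")
  y <- array(1, c(3, 3, 2))
  expect_error(dct_pls_smooth(y, mask = array(FALSE, c(3, 3, 2)), s = 1),
               "missing")
})
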