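test_that("turn angle handles collinear, right-angle and mirrored traces", {
  expect_equal(turn_angle(trace_tbl(c(0, 0), c(0, 100), c(0, 200))), 0)
  # right-angle bend toward caudal (+x)
  tr <- trace_tbl(c(0, 0), c(0, 100), c(100, 100))
  expect_equal(turn_angle(tr), 90)
  # mirror about the initial direction flips the sign, not the magnitude
  mir <- trace_tbl(c(0, 0), c(0, 100), c(-100, 100))
  expect_equal(turn_angle(mir), -90)
  # oblique case against a hand-computed interior angle
  tr2 <- trace_tbl(c(0, 0), c(0, 100), c(50, 186.6025))
  expect_equal(turn_angle(tr2), 30, tolerance = 1e-4)
  # repeats average
  expect_equal(turn_angle(list(tr, tr2)), 60, tolerance = 1e-4)
  expect_error(turn_angle(trace_tbl(c(0, 0), c(0, 0), c(1, 1))), "coincident")
})

test_that("moment-ellipse elongation recovers axis ratios and is rotation invariant", {
  circ <- ellipse_mask(30, 30)
  expect_equal(ot_elongation(circ), 1, tolerance = 0.02)
  ell <- ellipse_mask(40, 20)
  expect_equal(ot_elongation(ell), 2, tolerance = 0.03)
  # rotation by 90 degrees on the pixel grid is exact
  expect_equal(ot_elongation(t(ell)), ot_elongation(ell), tolerance = 1e-12)
  expect_error(ot_elongation(matrix(0, 5, 5)), "pixels")
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_error(ot_elongation(single), "pixels|degenerate")
})

test_that("cell density respects limits, monotonicity and the circularity filter", {
  blank <- matrix(0, 100, 100)
  expect_equal(cell_density(blank, threshold = 0.5), 0)
  full <- matrix(1, 100, 100)
  expect_equal(cell_density(full, threshold = 0.5), 1)

  # adding nuclei pixels never decreases the fraction
  img <- simulate_nuclei_image(0.15, 0.15, seed = 31, noise_sd = 0)$image
  base <- cell_density(img, threshold = 0.5)
  more <- img
  more[10:30, 10:30] <- 1
  expect_gte(cell_density(more, threshold = 0.5), base)

  # a long 1-px-wide snake has circularity below 0.2 and is filtered out
  snake <- matrix(0, 60, 60)
  snake[30, 5:55] <- 1
  blob <- snake
  blob[10:20, 10:20] <- 1
  with_snake <- cell_density(blob, sigma = 0.01, threshold = 0.5)
  expect_equal(with_snake, sum(blob[10:20, 10:20]) / length(blob),
               tolerance = 0.05)
})

test_that("density gradient, pH3 density and normalized area follow their formulas", {
  expect_equal(density_gradient(0.30, 0.20), 0.002)
  expect_equal(density_gradient(0.25, 0.25), 0)
  expect_equal(ph3_density(5, 20000), 2.5)
  expect_equal(ph3_density(0, 12345), 0)
  expect_equal(ph3_density(10, 5000), ph3_density(20, 10000))
  expect_error(ph3_density(5, 0), "> 0")
  expect_equal(normalized_brain_area(100, 100), 1)
  expect_equal(normalized_brain_area(50, 100), 0.5)
  expect_error(normalized_brain_area(1, 0), "> 0")
})

test_that("image metrics are translation invariant", {
  ell <- ellipse_mask(30, 15, pad = 25)
  shifted <- matrix(0, nrow(ell), ncol(ell))
  shifted[11:nrow(ell), 6:ncol(ell)] <- ell[1:(nrow(ell) - 10), 1:(ncol(ell) - 5)]
  expect_equal(ot_elongation(shifted), ot_elongation(ell), tolerance = 1e-6)
  tr <- trace_tbl(c(0, 0), c(0, 100), c(100, 100))
  moved <- tr; moved$x_um <- moved$x_um + 55; moved$y_um <- moved$y_um - 12
  expect_equal(turn_angle(moved), turn_angle(tr))
})

test_that("max projection takes the per-pixel maximum over slices", {
  st <- array(0, c(4, 4, 3))
  st[2, 2, 1] <- 0.3; st[2, 2, 3] <- 0.9; st[1, 4, 2] <- 0.5
  mp <- max_project(st)
  expect_equal(mp[2, 2], 0.9)
  expect_equal(mp[1, 4], 0.5)
  expect_identical(max_project(mp), mp)
})
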