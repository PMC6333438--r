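make_map <- function(K, spacing = 20, t_min = 0) {
  nx <- nrow(K); ny <- ncol(K)
  grid <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  new_stiffness_map(
    tibble::tibble(i = grid$i, j = grid$j,
                   x_um = (grid$i - 1) * spacing,
                   y_um = (grid$j - 1) * spacing,
                   K_Pa = K[cbind(grid$i, grid$j)],
                   status = "accepted", reason = NA_character_),
    x_um = (seq_len(nx) - 1) * spacing, y_um = (seq_len(ny) - 1) * spacing,
    spacing = spacing, t_min = t_min)
}

test_that("ROI means equal hand-enumerated node averages", {
  set.seed(1)
  K <- matrix(runif(8 * 6, 50, 250), 8, 6)
  m <- make_map(K)
  box <- roi_box(20, 20, 50)   # half-open: x in {20,40,60}, y in {20,40,60}
  manual <- mean(K[2:4, 2:4])
  expect_equal(roi_mean(m, box), manual)

  # uniform map
  expect_equal(roi_mean(make_map(matrix(100, 6, 6)), roi_box(0, 0, 50)), 100)

  # box straddling two uniform halves equally
  Kh <- rbind(matrix(100, 3, 6), matrix(200, 3, 6))  # rows index x

  mh <- make_map(Kh, spacing = 20)
  # box covering x in {40,60} (one column each side of the 100/200 split)
  expect_equal(roi_mean(mh, roi_box(40, 0, 40)), 150)
  expect_error(roi_mean(mh, roi_box(1e4, 0, 50)), "no grid nodes")
})

test_that("gradient statistic is the printed formula with antisymmetry and offset invariance", {
  expect_equal(stiffness_gradient(150, 100), 1.0)
  expect_equal(stiffness_gradient(100, 100), 0)
  set.seed(2)
  for (rep in 1:100) {
    K <- matrix(runif(64, 50, 250), 8, 8)
    m <- make_map(K)
    r_box <- roi_box(0, 20, 50); c_box <- roi_box(80, 20, 50)
    kr <- roi_mean(m, r_box); kc <- roi_mean(m, c_box)
    g <- stiffness_gradient(kr, kc)
    expect_equal(stiffness_gradient(kc, kr), -g)
    off <- make_map(K + 37.5)
    expect_equal(stiffness_gradient(roi_mean(off, r_box), roi_mean(off, c_box)),
                 g, tolerance = 1e-12)
  }
})

test_that("replicate placements average per the three-ROI protocol", {
  K <- matrix(rep(seq(100, 240, by = 20), 6), 8, 6)
  m <- make_map(K)
  p1 <- roi_pair(roi_box(0, 0, 50), roi_box(80, 0, 50), 1)
  p2 <- roi_pair(roi_box(0, 40, 50), roi_box(80, 40, 50), 2)
  single <- replicate_and_average(m, p1)
  trip <- replicate_and_average(m, list(p1, p1, p1))
  expect_equal(trip$gradient_Pa_per_um, single$gradient_Pa_per_um)
  both <- replicate_and_average(m, list(p1, p2))
  g1 <- single$gradient_Pa_per_um
  g2 <- replicate_and_average(m, p2)$gradient_Pa_per_um
  expect_equal(both$gradient_Pa_per_um, mean(c(g1, g2)))
  expect_error(roi_pair(roi_box(0, 0, 50), roi_box(20, 20, 50)), "overlap")
})

test_that("assemble_series sorts frames, unions masks, and rejects mismatched grids", {
  set.seed(3)
  maps <- lapply(c(70, 0, 35), function(t) {
    K <- matrix(runif(20, 50, 250), 5, 4)
    m <- make_map(K, t_min = t)
    if (t == 35) {
      m$status[3] <- "excluded"; m$reason[3] <- "baseline"
      m$K_Pa[3] <- NA_real_
    }
    m
  })
  s <- assemble_series(maps)
  expect_equal(s$t_min, c(0, 35, 70))
  expect_identical(sum(!s$mask), 1L)
  expect_false(s$mask[3, 1, 2])   # the excluded node sits in the t=35 frame
  single <- assemble_series(maps[1])
  expect_identical(dim(single$K)[3], 1L)
  bad <- make_map(matrix(1, 4, 4), t_min = 105)
  expect_error(assemble_series(c(maps, list(bad))), "geometry")
})

test_that("fold-change maps obey their algebraic identities", {
  set.seed(4)
  K <- array(runif(5 * 4, 80, 200), c(5, 4, 3))
  K[, , 2] <- K[, , 1] * 2
  K[, , 3] <- K[, , 2] * 1.5
  s <- new_stiffness_series(K, (0:4) * 20, (0:3) * 20, c(0, 35, 70), 20)

  prev <- fold_change_maps(s, "previous")
  expect_equal(as.vector(prev$K[, , 1]), rep(1, 20))
  expect_equal(as.vector(prev$K[, , 2]), rep(2, 20))
  expect_equal(as.vector(prev$K[, , 3]), rep(1.5, 20))

  first <- fold_change_maps(s, "first")
  # cumulative product of previous-mode ratios equals first-mode ratios
  expect_equal(prev$K[, , 2] * prev$K[, , 3], first$K[, , 3],
               tolerance = 1e-12)

  # static series -> all ratios 1
  Ks <- array(123, c(3, 3, 2))
  st <- new_stiffness_series(Ks, (0:2) * 20, (0:2) * 20, c(0, 35), 20)
  expect_equal(unique(as.vector(fold_change_maps(st, "previous")$K)), 1)

  # invariant to global multiplicative scaling
  s2 <- new_stiffness_series(3 * K, s$x_um, s$y_um, s$t_min, 20)
  expect_equal(fold_change_maps(s2, "first")$K, first$K, tolerance = 1e-12)
  expect_error(fold_change_maps(st, "bogus"))
  expect_error(fold_change_maps(assemble_series(list(make_map(matrix(1, 4, 4)))),
                                "previous"), "2 frames")
})
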