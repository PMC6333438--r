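# Independent dense-linear-algebra oracle for the DCT smoother:
# z = (W + s * L'L)^{-1} W y with the Neumann second-difference Laplacian
# assembled explicitly by Kronecker products (column-major vec ordering).
neumann_laplacian_1d <- function(n) {
  if (n == 1) return(matrix(0, 1, 1))
  D <- diag(2, n)
  D[1, 1] <- D[n, n] <- 1
  for (i in seq_len(n - 1)) {
    D[i, i + 1] <- -1
    D[i + 1, i] <- -1
  }
  D
}

dense_dct_solve <- function(y, s, mask = NULL, spacing = c(1, 1, 1)) {
  d <- dim(y)
  L1 <- neumann_laplacian_1d(d[1]) / spacing[1]^2
  L2 <- neumann_laplacian_1d(d[2]) / spacing[2]^2
  L3 <- neumann_laplacian_1d(d[3]) / spacing[3]^2
  I1 <- diag(d[1]); I2 <- diag(d[2]); I3 <- diag(d[3])
  L <- kronecker(I3, kronecker(I2, L1)) +
    kronecker(I3, kronecker(L2, I1)) +
    kronecker(L3, kronecker(I2, I1))
  if (is.null(mask)) mask <- array(TRUE, d)
  W <- diag(as.numeric(as.vector(mask)))
  yv <- as.vector(y)
  yv[!as.vector(mask)] <- 0
  z <- solve(W + s * crossprod(L), W %*% yv)
  array(z, d)
}

# small, fast scene for unit tests
tiny_scene <- function(n_frames = 2, nx = 4, ny = 3, dropout = 0,
                       force_noise_sd = 0.05, seed = 1L, ...) {
  afm_scene(
    field = field_params(nx = nx, ny = ny, n_frames = n_frames),
    noise = curve_noise_params(force_noise_sd = force_noise_sd,
                               dropout_prob = dropout, seed = seed),
    ...
  )
}

# straight rays radiating from a circle, for Sholl geometry checks
ray_mask <- function(n_rays = 8, r0 = 20, length_um = 60, half = 100) {
  n <- 2 * half + 1
  m <- matrix(0, n, n)
  for (a in seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]) {
    for (r in seq(r0, r0 + length_um, by = 0.25)) {
      x <- round(half + r * cos(a)) + 1L
      y <- round(half + r * sin(a)) + 1L
      m[y + c(0L, 1L), x + c(0L, 1L)] <- 1
    }
  }
  m
}

# filled ellipse mask (rows = y, cols = x), semi-axes in pixels
ellipse_mask <- function(a = 40, b = 20, pad = 10) {
  nx <- 2 * (a + pad) + 1; ny <- 2 * (b + pad) + 1
  cx <- a + pad + 1; cy <- b + pad + 1
  m <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      if (((j - cx) / a)^2 + ((i - cy) / b)^2 <= 1) m[i, j] <- 1
    }
  }
  m
}

trace_tbl <- function(chiasm, bend, end) {
  tibble::tibble(landmark = c("chiasm", "bend", "end"),
                 x_um = c(chiasm[1], bend[1], end[1]),
                 y_um = c(chiasm[2], bend[2], end[2]))
}
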