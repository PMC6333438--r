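#' Simulate a nuclei-stained image with a rostro-caudal density difference
#'
#' Draws non-overlapping disks (a hard-disk point process) independently
#' on the rostral (left) and caudal (right) half of the image until each
#' half reaches its requested painted-area fraction, then adds optional
#' background noise. Nuclei are bright (intensity ~1) on a dark
#' background, so the density chain (blur, threshold, particle filter)
#' recovers the painted fractions.
#'
#' @param density_R,density_C Requested painted-area fractions per side,
#'   in `[0, 1)`; fractions above ~0.45 are infeasible for hard disks and
#'   rejected.
#' @param nucleus_radius Disk radius (um).
#' @param pixel_size Pixel edge (um).
#' @param width_um,height_um Image extent (um).
#' @param seed Integer seed.
#' @param noise_sd Background intensity noise sd.
#' @param tol Acceptable shortfall of the realised fraction.
#' @param max_tries Dart-throwing attempts per side.
#' @return A list: `image` (matrix rows = y, cols = x, values in [0, 1]),
#'   `mask` (the clean painted mask, the pixel-count ground truth),
#'   `realised_R`, `realised_C` (painted fractions per half measured on
#'   the clean mask), `centers` (tibble of disk centres).
#' @export
#' @examples
#' img <- simulate_nuclei_image(0.2, 0.1, seed = 1)
#' img$realised_R
simulate_nuclei_image <- function(density_R, density_C, nucleus_radius = 4,
                                  pixel_size = 0.5, width_um = 100,
                                  height_um = 100, seed = 1L, noise_sd = 0.02,
                                  tol = 0.02, max_tries = 20000L) {
  check_number(density_R, "density_R", lower = 0, upper = 1, closed_upper = FALSE)
  check_number(density_C, "density_C", lower = 0, upper = 1, closed_upper = FALSE)
  if (max(density_R, density_C) > 0.45) {
    stop_bad("requested fraction infeasible for non-overlapping disks (> 0.45)")
  }
  nx <- round(width_um / pixel_size); ny <- round(height_um / pixel_size)
  r_px <- nucleus_radius / pixel_size
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  ys <- matrix(rep(seq_len(ny), nx), ny, nx)
  half <- nx / 2

  with_seed_if(seed, {
    mask <- matrix(FALSE, ny, nx)
    centers <- list()
    paint_side <- function(mask, x_lo, x_hi, target, side) {
      if (target <= 0) return(mask)
      side_px <- (x_hi - x_lo + 1) * ny
      pts <- matrix(numeric(0), 0, 2)
      frac <- 0
      tries <- 0L
      while (frac < target - tol / 2 && tries < max_tries) {
        tries <- tries + 1L
        cx <- runif(1, x_lo + r_px, x_hi - r_px)
        cy <- runif(1, 1 + r_px, ny - r_px)
        if (nrow(pts) > 0 &&
            min((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2) < (2 * r_px + 1)^2) next
        pts <- rbind(pts, c(cx, cy))
        mask <- mask | ((xs - cx)^2 + (ys - cy)^2 <= r_px^2)
        frac <- sum(mask[, x_lo:x_hi]) / side_px
      }
      centers[[side]] <<- pts
      mask
    }
    mask <- paint_side(mask, 1, floor(half), density_R, "R")
    mask <- paint_side(mask, floor(half) + 1, nx, density_C, "C")
    realised_R <- sum(mask[, 1:floor(half)]) / (floor(half) * ny)
    realised_C <- sum(mask[, (floor(half) + 1):nx]) / ((nx - floor(half)) * ny)
    img <- mask * 1 + matrix(rnorm(nx * ny, 0, noise_sd), ny, nx)
    img <- pmin(pmax(img, 0), 1)
    ctr <- list_rbind(imap(centers, function(p, side) {
      if (nrow(p) == 0) return(tibble(side = character(), x_px = numeric(),
                                      y_px = numeric()))
      tibble(side = side, x_px = p[, 1], y_px = p[, 2])
    }))
    list(image = img, mask = mask,
         realised_R = realised_R, realised_C = realised_C,
         centers = ctr)
  })
}
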