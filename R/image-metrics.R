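#' Turn angle of a tract trace
#'
#' The interior angle at the mid-tract bend between the chiasm-to-bend
#' and bend-to-end segments, subtracted from 180 degrees; the sign is
#' positive when the end landmark deviates toward the caudal direction
#' (by convention +x). A list of repeated point sets is averaged, as in
#' the triple-measurement protocol.
#'
#' @param trace Tibble with columns `landmark` (`"chiasm"`, `"bend"`,
#'   `"end"`), `x_um`, `y_um` -- or a list of such tibbles (repeats).
#' @param caudal Unit vector of the caudal direction.
#' @return Signed turn angle (deg).
#' @export
#' @examples
#' tr <- tibble::tibble(landmark = c("chiasm", "bend", "end"),
#'                      x_um = c(0, 0, 100), y_um = c(0, 100, 100))
#' turn_angle(tr)  # +90
turn_angle <- function(trace, caudal = c(1, 0)) {
  if (is.data.frame(trace)) trace <- list(trace)
  angles <- vapply(trace, turn_angle_one, numeric(1), caudal = caudal)
  mean(angles)
}

turn_angle_one <- function(trace, caudal) {
  pt <- function(which) {
    row <- trace[trace$landmark == which, , drop = FALSE]
    if (nrow(row) != 1) stop_bad("trace needs exactly one `%s` landmark", which)
    c(row$x_um, row$y_um)
  }
  chiasm <- pt("chiasm"); bend <- pt("bend"); end <- pt("end")
  u <- bend - chiasm
  w <- end - bend
  if (sqrt(sum(u^2)) == 0 || sqrt(sum(w^2)) == 0) {
    stop_bad("coincident landmarks in tract trace")
  }
  # interior angle at the bend between (chiasm - bend) and (end - bend)
  a <- chiasm - bend
  cosang <- sum(a * w) / sqrt(sum(a^2) * sum(w^2))
  interior <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  turn <- 180 - interior
  u_hat <- u / sqrt(sum(u^2))
  w_perp <- w - sum(w * u_hat) * u_hat
  s <- sign(sum(w_perp * caudal))
  if (s == 0) s <- 1
  s * turn
}

# second-central-moment equivalent ellipse of a binary mask;
# mask indexed [row = y, col = x], pixel centres at integer coordinates
moment_ellipse <- function(mask) {
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) < 2) stop_bad("mask needs >= 2 foreground pixels")
  xy <- cbind(x = px[, 2], y = px[, 1])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  S <- crossprod(cc) / nrow(cc)
  ev <- eigen(S, symmetric = TRUE)
  # axes of the ellipse with the same normalized second central moment
  list(center = ctr, values = ev$values,
       major = 4 * sqrt(ev$values[1]), minor = 4 * sqrt(ev$values[2]),
       area_px = nrow(px))
}

#' Tract elongation from a binary mask
#'
#' Major-to-minor axis ratio of the ellipse with the same normalized
#' second central moment as the mask; >= 1, rotation invariant.
#'
#' @param mask Binary matrix (rows = y, cols = x); nonzero = tract.
#' @param pixel_size Pixel edge (um); the ratio is dimensionless, the
#'   argument is accepted for interface symmetry.
#' @return Axis ratio (>= 1).
#' @export
ot_elongation <- function(mask, pixel_size = 1) {
  el <- moment_ellipse(mask)
  if (el$minor <= 0) stop_bad("degenerate mask: minor axis is zero")
  el$major / el$minor
}

#' Nuclear area fraction inside an ROI
#'
#' The density-measurement chain: Gaussian blur (sigma = 2 px), threshold
#' (explicit value, or Otsu when `NULL` -- the reproducible stand-in for a
#' manually adjusted threshold), binarise, filter connected components by
#' size (>= 1 px^2) and circularity `4 pi A / P^2` in `[0.2, 1]`, then
#' divide the retained nuclei area by the ROI area. Components touching
#' the ROI border are exempt from the circularity floor (their perimeter
#' is truncated by the crop; a full-ROI blob must pass).
#'
#' @param image Numeric grayscale matrix (rows = y, cols = x), values in
#'   `[0, 1]` or raw intensities.
#' @param roi Optional [roi_box()] in um; `NULL` measures the whole image.
#' @param pixel_size Pixel edge (um).
#' @param sigma Blur sigma in pixels.
#' @param threshold Binarisation threshold; `NULL` for Otsu.
#' @param min_size Minimum component area (px^2).
#' @param circularity Inclusive circularity range.
#' @return Area fraction in `[0, 1]`.
#' @export
cell_density <- function(image, roi = NULL, pixel_size = 1, sigma = 2,
                         threshold = NULL, min_size = 1,
                         circularity = c(0.2, 1)) {
  stopifnot(is.matrix(image))
  img <- EBImage::gblur(EBImage::Image(image), sigma = sigma)
  img <- EBImage::imageData(img)
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_box"))
    rows <- which((seq_len(nrow(img)) - 1) * pixel_size >= roi$y0 &
                    (seq_len(nrow(img)) - 1) * pixel_size < roi$y0 + roi$size)
    cols <- which((seq_len(ncol(img)) - 1) * pixel_size >= roi$x0 &
                    (seq_len(ncol(img)) - 1) * pixel_size < roi$x0 + roi$size)
    if (length(rows) == 0 || length(cols) == 0) stop_bad("ROI outside image")
    img <- img[rows, cols, drop = FALSE]
  }
  rng <- range(img)
  if (diff(rng) == 0) {
    # flat image: all background (0) or all saturated (1)
    return(as.numeric(rng[1] > 0))
  }
  thr <- if (is.null(threshold)) {
    norm <- (img - rng[1]) / diff(rng)
    EBImage::otsu(EBImage::Image(norm)) * diff(rng) + rng[1]
  } else threshold
  bw <- img > thr
  if (!any(bw)) return(0)
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = 1,
                                           dimnames = list(NULL, names(feats)))
  area <- feats[, "s.area"]
  per <- feats[, "s.perimeter"]
  circ <- ifelse(per > 0, pmin(4 * pi * area / per^2, 1), 1)
  lab_m <- EBImage::imageData(lab)
  border_ids <- unique(c(lab_m[1, ], lab_m[nrow(lab_m), ],
                         lab_m[, 1], lab_m[, ncol(lab_m)]))
  border_ids <- border_ids[border_ids > 0]
  id <- seq_along(area)
  keep <- area >= min_size &
    (id %in% border_ids | (circ >= circularity[1] & circ <= circularity[2]))
  sum(area[keep]) / length(img)
}

#' Maximum-intensity projection of adjacent slices
#'
#' Projects a y-by-x-by-slice stack by the per-pixel maximum; the density
#' protocol projects the in-focus slice with one slice above and below.
#'
#' @param stack Numeric 3-D array (rows, cols, slices) or a matrix
#'   (returned unchanged).
#' @return A matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  apply(stack, c(1, 2), max)
}

#' Cell-body density gradient between flanking ROIs
#'
#' `(D_R - D_C) / separation`, the density analogue of the stiffness
#' gradient.
#'
#' @param D_R,D_C Rostral and caudal nuclear area fractions.
#' @param separation ROI separation (um).
#' @return Gradient (fraction/um).
#' @export
#' @examples
#' density_gradient(0.30, 0.20)  # 0.002 per um
density_gradient <- function(D_R, D_C, separation = ROI_SEPARATION_UM) {
  (D_R - D_C) / separation
}

#' Mitotic-cell density per 10,000 um^2
#'
#' @param count Number of pH3-positive cells.
#' @param area_um2 Measured brain area (um^2), > 0.
#' @return Cells per 10,000 um^2.
#' @export
#' @examples
#' ph3_density(5, 20000)  # 2.5
ph3_density <- function(count, area_um2) {
  if (any(area_um2 <= 0)) stop_bad("brain area must be > 0")
  count / area_um2 * 1e4
}

#' Normalized brain area
#'
#' Ratio of the exposed hemisphere's cross-sectional area to the intact
#' hemisphere's; pixel-size independent when both areas share units.
#'
#' @param exposed_area,intact_area Areas in any common unit; intact > 0.
#' @return Dimensionless ratio.
#' @export
normalized_brain_area <- function(exposed_area, intact_area) {
  if (any(intact_area <= 0)) stop_bad("intact area must be > 0")
  exposed_area / intact_area
}
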