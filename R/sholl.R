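#' Sholl intersection profile of a neurite mask
#'
#' Counts neurite intersections with concentric circles stepping outward
#' from a start radius: each circle is sampled at sub-pixel angular
#' resolution and contiguous runs of foreground pixels along it are
#' counted as one crossing each.
#'
#' @param neurite_mask Binary matrix (rows = y, cols = x); nonzero =
#'   neurite signal.
#' @param center Circle centre `c(x, y)` in um.
#' @param start_radius Innermost radius (um).
#' @param step Radius increment (um); 5 um in the standard protocol.
#' @param max_radius Outermost radius (um); defaults to the farthest
#'   image corner.
#' @param pixel_size Pixel edge (um).
#' @return A `sholl_result`: tibble of `radius_um`, `crossings`, with the
#'   reach summary [median_sholl_radius()] available via [glance()].
#' @export
sholl_profile <- function(neurite_mask, center, start_radius, step = 5,
                          max_radius = NULL, pixel_size = 1) {
  stopifnot(is.matrix(neurite_mask), length(center) == 2)
  check_number(start_radius, "start_radius", lower = 0)
  check_number(step, "step", lower = 0, closed_lower = FALSE)
  ny <- nrow(neurite_mask); nx <- ncol(neurite_mask)
  if (is.null(max_radius)) {
    corners <- expand.grid(x = c(0, (nx - 1) * pixel_size),
                           y = c(0, (ny - 1) * pixel_size))
    max_radius <- max(sqrt((corners$x - center[1])^2 +
                             (corners$y - center[2])^2))
  }
  radii <- seq(start_radius, max_radius, by = step)
  counts <- vapply(radii, function(r) {
    n_theta <- max(64L, ceiling(2 * pi * r / (0.5 * pixel_size)))
    theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
    px <- round(center[1] / pixel_size + (r / pixel_size) * cos(theta)) + 1L
    py <- round(center[2] / pixel_size + (r / pixel_size) * sin(theta)) + 1L
    inside <- px >= 1L & px <= nx & py >= 1L & py <= ny
    hit <- logical(length(theta))
    hit[inside] <- neurite_mask[cbind(py[inside], px[inside])] != 0
    if (!any(hit)) return(0L)
    runs <- rle(hit)
    n_runs <- sum(runs$values)
    # circular wrap: a run touching both ends is one crossing
    if (hit[1] && hit[length(hit)] && n_runs > 1L) n_runs <- n_runs - 1L
    as.integer(n_runs)
  }, integer(1))
  structure(
    tibble(radius_um = radii, crossings = counts),
    start_radius = start_radius, step = step, center = center,
    class = c("sholl_result", class(tibble()))
  )
}

#' Median outgrowth radius of a Sholl profile
#'
#' Reach-based summary: the largest radius up to which the crossing count
#' has not fallen below half the count at the start radius. Returns `NA`
#' (with a warning) when no neurites cross the start radius.
#'
#' @param profile A `sholl_result`.
#' @return Radius (um), or `NA`.
#' @export
median_sholl_radius <- function(profile) {
  stopifnot(inherits(profile, "sholl_result"))
  c0 <- profile$crossings[1]
  if (c0 == 0) {
    warn("no neurite signal at the start radius; median reach undefined")
    return(NA_real_)
  }
  ok <- profile$crossings >= c0 / 2
  below <- which(!ok)
  last <- if (length(below)) below[1] - 1L else nrow(profile)
  profile$radius_um[last]
}

#' One-row summary of a Sholl profile
#'
#' @param x A `sholl_result`.
#' @param ... Unused.
#' @return Tibble with start radius, peak count and median reach.
#' @export
glance.sholl_result <- function(x, ...) {
  tibble(start_radius_um = attr(x, "start_radius"),
         max_crossings = max(x$crossings),
         median_sholl_radius_um = suppressWarnings(median_sholl_radius(x)))
}

#' Sholl analysis of an explant image
#'
#' Full chain: fit the moment ellipse of the explant mask, derive the
#' start radius from its area A (default `sqrt(A/pi)`; the alternative
#' `"area_over_pi"` rule, A/pi, is selectable), difference-of-Gaussians
#' bandpass the neurite image, threshold (explicit value or Otsu), and
#' count circle crossings outward in `step` increments.
#'
#' @param explant_mask Binary matrix of the explant body.
#' @param neurite_image Grayscale matrix of the neurite signal.
#' @param pixel_size Pixel edge (um).
#' @param step Radius increment (um).
#' @param threshold Binarisation threshold after bandpass; `NULL` = Otsu.
#' @param bandpass Small/large Gaussian sigmas (px) of the bandpass;
#'   `NULL` skips filtering.
#' @param radius_rule `"sqrt_area_over_pi"` or `"area_over_pi"`.
#' @param ... Passed to [sholl_profile()].
#' @return A `sholl_result`.
#' @export
sholl <- function(explant_mask, neurite_image, pixel_size = 1, step = 5,
                  threshold = NULL, bandpass = c(1, 20),
                  radius_rule = c("sqrt_area_over_pi", "area_over_pi"), ...) {
  radius_rule <- match.arg(radius_rule)
  el <- moment_ellipse(explant_mask)
  area_um2 <- el$area_px * pixel_size^2
  start_radius <- switch(radius_rule,
                         sqrt_area_over_pi = sqrt(area_um2 / pi),
                         area_over_pi = area_um2 / pi)
  img <- neurite_image
  if (!is.null(bandpass)) {
    lo <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), bandpass[1]))
    hi <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), bandpass[2]))
    img <- lo - hi
  }
  rng <- range(img)
  if (diff(rng) == 0) stop_bad("no neurite signal in image")
  thr <- if (is.null(threshold)) {
    EBImage::otsu(EBImage::Image((img - rng[1]) / diff(rng))) * diff(rng) + rng[1]
  } else threshold
  mask <- (img > thr) * 1
  center <- (el$center - 1) * pixel_size          # (x, y) in um
  sholl_profile(mask, center = center, start_radius = start_radius,
                step = step, pixel_size = pixel_size, ...)
}
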