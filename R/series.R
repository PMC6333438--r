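#' Spatiotemporal stiffness series
#'
#' An x-by-y-by-frame array of apparent moduli with an observation mask and
#' grid geometry; the container every smoothing, gradient and fold-change
#' operation works on. Usually built by [assemble_series()] from per-frame
#' maps or returned by [make_stiffness_field()] as ground truth.
#'
#' @param K Numeric array `nx x ny x n_frames` (Pa); `NA` where missing.
#' @param x_um,y_um Node coordinates (um), origin at the map corner,
#'   x rostral to caudal, y dorsal to ventral.
#' @param t_min Frame timestamps (min), strictly increasing.
#' @param spacing Grid step (um).
#' @param mask Logical array, `TRUE` where observed; defaults to `!is.na(K)`.
#' @return A `stiffness_series` list with elements `K`, `mask`, `x_um`,
#'   `y_um`, `t_min`, `spacing`.
#' @name stiffness_series
#' @export
new_stiffness_series <- function(K, x_um, y_um, t_min, spacing, mask = NULL) {
  stopifnot(is.array(K), length(dim(K)) == 3L)
  d <- dim(K)
  stopifnot(length(x_um) == d[1], length(y_um) == d[2], length(t_min) == d[3])
  if (is.null(mask)) mask <- !is.na(K)
  stopifnot(identical(dim(mask), d))
  if (d[3] > 1 && any(diff(t_min) <= 0)) {
    stop_bad("frame timestamps must be strictly increasing")
  }
  structure(list(K = K, mask = mask, x_um = x_um, y_um = y_um,
                 t_min = t_min, spacing = spacing),
            class = "stiffness_series")
}

#' @export
print.stiffness_series <- function(x, ...) {
  d <- dim(x$K)
  cat(sprintf("<stiffness_series> %d x %d nodes, %d frames (%g-%g min), %d missing\n",
              d[1], d[2], d[3], min(x$t_min), max(x$t_min), sum(!x$mask)))
  invisible(x)
}

#' Stack per-frame stiffness maps into a series
#'
#' Maps must share grid geometry; frames are ordered by timestamp.
#' Excluded nodes become missing entries of the array.
#'
#' @param maps List of [stiffness_map] tibbles (one per frame).
#' @return A [stiffness_series].
#' @export
assemble_series <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1)
  geom <- lapply(maps, function(m) attr(m, "geometry"))
  g0 <- geom[[1]]
  for (g in geom[-1]) {
    if (!isTRUE(all.equal(g[c("x_um", "y_um", "spacing")],
                          g0[c("x_um", "y_um", "spacing")]))) {
      stop_bad("maps do not share grid geometry")
    }
  }
  t_min <- vapply(geom, `[[`, numeric(1), "t_min")
  ord <- order(t_min)
  nx <- length(g0$x_um); ny <- length(g0$y_um)
  K <- array(NA_real_, dim = c(nx, ny, length(maps)))
  for (f in seq_along(ord)) {
    m <- maps[[ord[f]]]
    idx <- cbind(m$i, m$j, f)
    K[idx] <- ifelse(m$status == "accepted", m$K_Pa, NA_real_)
  }
  new_stiffness_series(K, g0$x_um, g0$y_um, sort(t_min), g0$spacing)
}

#' Tidy a stiffness series into a long tibble
#'
#' @param x A [stiffness_series].
#' @param ... Unused.
#' @return A tibble with one row per node per frame: `i`, `j`, `frame`,
#'   `x_um`, `y_um`, `t_min`, `K_Pa`, `observed`.
#' @export
tidy.stiffness_series <- function(x, ...) {
  d <- dim(x$K)
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), frame = seq_len(d[3]))
  tibble(
    i = grid$i, j = grid$j, frame = grid$frame,
    x_um = x$x_um[grid$i], y_um = x$y_um[grid$j], t_min = x$t_min[grid$frame],
    K_Pa = as.vector(x$K), observed = as.vector(x$mask)
  )
}

#' Smooth and impute a stiffness series
#'
#' Applies discrete-cosine penalized-least-squares smoothing
#' ([dct_pls_smooth()]) across x, y and time, with per-axis penalty scaling
#' by the physical grid steps so 20 um and ~35 min increments are weighted
#' comparably. Missing nodes are imputed from the whole array.
#'
#' @param series A [stiffness_series].
#' @param s Smoothing parameter, or `"auto"` for GCV selection.
#' @param robust Use iteratively reweighted (outlier-resistant) smoothing;
#'   intended for display arrays such as fold-change montages.
#' @param scale_axes Scale each axis's penalty by its grid step (default);
#'   `FALSE` treats all axes as unit-spaced.
#' @param ... Passed to [dct_pls_smooth()].
#' @return A [stiffness_series] with no missing values, carrying the
#'   [smoothed_series] fit as attribute `"smooth"`.
#' @export
smooth_stiffness_series <- function(series, s = "auto", robust = FALSE,
                                    scale_axes = TRUE, ...) {
  stopifnot(inherits(series, "stiffness_series"))
  spacing <- if (scale_axes) {
    dt <- if (length(series$t_min) > 1) mean(diff(series$t_min)) else 1
    c(series$spacing, series$spacing, dt)
  } else c(1, 1, 1)
  sm <- dct_pls_smooth(series$K, mask = series$mask, s = s, robust = robust,
                       spacing = spacing, ...)
  out <- new_stiffness_series(sm$z, series$x_um, series$y_um, series$t_min,
                              series$spacing,
                              mask = array(TRUE, dim(series$K)))
  attr(out, "smooth") <- sm
  out
}

#' Extract one frame of a series as a stiffness map
#'
#' @param series A [stiffness_series].
#' @param frame Frame index.
#' @return A [stiffness_map] tibble.
#' @export
series_frame <- function(series, frame) {
  stopifnot(inherits(series, "stiffness_series"))
  d <- dim(series$K)
  frame <- check_count(frame, "frame")
  if (frame > d[3]) stop_bad("frame %d out of range (%d frames)", frame, d[3])
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  K <- series$K[cbind(grid$i, grid$j, frame)]
  obs <- series$mask[cbind(grid$i, grid$j, frame)]
  new_stiffness_map(
    tibble(i = grid$i, j = grid$j,
           x_um = series$x_um[grid$i], y_um = series$y_um[grid$j],
           K_Pa = K,
           status = ifelse(obs, "accepted", "excluded"),
           reason = ifelse(obs, NA_character_, "missing")),
    x_um = series$x_um, y_um = series$y_um,
    spacing = series$spacing, t_min = series$t_min[frame]
  )
}

#' Fold-change maps of a stiffness series
#'
#' Element-wise ratio of each frame to a reference: the previous frame
#' (`"previous"`, with the first frame set to 1 everywhere) or the first
#' frame (`"first"`). Intended for the smoothed, imputed series; missing or
#' non-positive reference values propagate as missing ratios.
#'
#' @param series A [stiffness_series].
#' @param reference `"previous"` or `"first"`.
#' @return A `stiffness_series` whose `K` holds dimensionless ratios.
#' @export
fold_change_maps <- function(series, reference = c("previous", "first")) {
  stopifnot(inherits(series, "stiffness_series"))
  reference <- match.arg(reference)
  d <- dim(series$K)
  if (d[3] < 2) stop_bad("fold-change maps need at least 2 frames")
  K <- series$K
  K[!series$mask] <- NA_real_
  ratio <- array(NA_real_, d)
  if (reference == "previous") {
    ratio[, , 1] <- 1
    for (f in 2:d[3]) ratio[, , f] <- K[, , f] / K[, , f - 1]
  } else {
    for (f in seq_len(d[3])) ratio[, , f] <- K[, , f] / K[, , 1]
  }
  ratio[!is.finite(ratio)] <- NA_real_
  bad <- K <= 0
  bad[is.na(bad)] <- FALSE
  if (reference == "previous") {
    for (f in 2:d[3]) ratio[, , f][bad[, , f - 1]] <- NA_real_
  } else {
    for (f in seq_len(d[3])) ratio[, , f][bad[, , 1]] <- NA_real_
  }
  new_stiffness_series(ratio, series$x_um, series$y_um, series$t_min,
                       series$spacing)
}
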