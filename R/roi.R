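#' Axis-aligned ROI box
#'
#' A half-open `size x size` um square `[x0, x0+size) x [y0, y0+size)`;
#' nodes whose centres fall inside, or on the lower/left edge, belong to
#' the box. Half-open boxes avoid double counting by adjacent ROIs.
#'
#' @param x0,y0 Lower-left corner (um).
#' @param size Edge length (um); 50 um matches the gradient protocol.
#' @return An `roi_box` list.
#' @export
roi_box <- function(x0, y0, size = ROI_SEPARATION_UM) {
  check_number(size, "size", lower = 0, closed_lower = FALSE)
  structure(list(x0 = x0, y0 = y0, size = size), class = "roi_box")
}

#' Rostral/caudal ROI pair
#'
#' @param rostral,caudal [roi_box()]es of equal size; must not overlap.
#' @param replicate Placement replicate id.
#' @return An `roi_pair` list.
#' @export
roi_pair <- function(rostral, caudal, replicate = 1L) {
  stopifnot(inherits(rostral, "roi_box"), inherits(caudal, "roi_box"))
  if (rostral$size != caudal$size) stop_bad("ROI boxes must be equal size")
  overlap <- rostral$x0 < caudal$x0 + caudal$size &&
    caudal$x0 < rostral$x0 + rostral$size &&
    rostral$y0 < caudal$y0 + caudal$size &&
    caudal$y0 < rostral$y0 + rostral$size
  if (overlap) stop_bad("rostral and caudal ROIs overlap")
  structure(list(rostral = rostral, caudal = caudal,
                 replicate = as.integer(replicate)), class = "roi_pair")
}

roi_nodes <- function(map, box) {
  inside <- map$x_um >= box$x0 & map$x_um < box$x0 + box$size &
    map$y_um >= box$y0 & map$y_um < box$y0 + box$size
  which(inside)
}

#' Mean modulus inside an ROI
#'
#' Mean of non-missing K over grid nodes whose centres fall inside the
#' half-open box.
#'
#' @param map A [stiffness_map] tibble (or one frame via [series_frame()]).
#' @param box An [roi_box()].
#' @return Mean K (Pa).
#' @export
roi_mean <- function(map, box) {
  stopifnot(inherits(box, "roi_box"))
  idx <- roi_nodes(map, box)
  if (length(idx) == 0) stop_bad("ROI contains no grid nodes")
  K <- map$K_Pa[idx]
  ok <- map$status[idx] == "accepted" & !is.na(K)
  if (!any(ok)) return(NA_real_)
  mean(K[ok])
}

#' Stiffness gradient between flanking ROI means
#'
#' `(K_R - K_C) / separation`; positive when the rostral side is stiffer.
#'
#' @param K_R,K_C Rostral and caudal ROI means (Pa).
#' @param separation ROI separation (um); 50 um in the standard protocol.
#' @return Gradient (Pa/um).
#' @export
#' @examples
#' stiffness_gradient(150, 100)  # 1 Pa/um
stiffness_gradient <- function(K_R, K_C, separation = ROI_SEPARATION_UM) {
  (K_R - K_C) / separation
}

#' Gradient of one frame, averaged over replicate ROI placements
#'
#' Computes the rostral and caudal ROI means for each replicate placement
#' and averages the per-replicate gradients, following the
#' three-placement protocol.
#'
#' @param map A [stiffness_map] frame.
#' @param pairs List of [roi_pair()]s (typically 3 placements).
#' @return One-row tibble: `t_min`, `K_R_Pa`, `K_C_Pa`,
#'   `gradient_Pa_per_um`, `n_replicates`.
#' @export
replicate_and_average <- function(map, pairs) {
  if (inherits(pairs, "roi_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1)
  per <- lapply(pairs, function(p) {
    kr <- roi_mean(map, p$rostral)
    kc <- roi_mean(map, p$caudal)
    tibble(K_R_Pa = kr, K_C_Pa = kc,
           gradient_Pa_per_um = stiffness_gradient(kr, kc, p$rostral$size))
  }) |> list_rbind()
  t_min <- attr(map, "geometry")$t_min %||% NA_real_
  tibble(t_min = t_min,
         K_R_Pa = mean(per$K_R_Pa), K_C_Pa = mean(per$K_C_Pa),
         gradient_Pa_per_um = mean(per$gradient_Pa_per_um),
         n_replicates = nrow(per))
}

#' Automatic ROI placement flanking the map mid-line
#'
#' Places equal 50 x 50 um boxes rostral and caudal of the map's
#' mid-column at a configurable standoff, with replicate placements
#' shifted along y -- emulating manual ROI placement just ahead of the
#' advancing tract. Manual placements can always be supplied directly as
#' [roi_pair()]s.
#'
#' @param series A [stiffness_series] (or a [stiffness_map]).
#' @param standoff Gap between box edge and the mid-line (um).
#' @param size Box edge length (um).
#' @param replicate_offsets y-shifts of the replicate placements (um).
#' @return List of [roi_pair()]s.
#' @export
auto_roi_pairs <- function(series, standoff = 10, size = ROI_SEPARATION_UM,
                           replicate_offsets = c(-20, 0, 20)) {
  x <- if (inherits(series, "stiffness_series")) series$x_um else
    attr(series, "geometry")$x_um
  y <- if (inherits(series, "stiffness_series")) series$y_um else
    attr(series, "geometry")$y_um
  x_mid <- mean(range(x))
  y_c <- mean(range(y)) - size / 2
  map(seq_along(replicate_offsets), function(r) {
    yy <- y_c + replicate_offsets[r]
    yy <- min(max(yy, min(y)), max(y) - size + 1e-9)
    roi_pair(
      rostral = roi_box(x_mid - standoff - size, yy, size),
      caudal = roi_box(x_mid + standoff, yy, size),
      replicate = r
    )
  })
}

#' Gradient time series of a stiffness series
#'
#' Applies [replicate_and_average()] to every frame.
#'
#' @param series A [stiffness_series] (usually smoothed).
#' @param pairs List of [roi_pair()]s; defaults to [auto_roi_pairs()].
#' @return Tibble with one row per frame: `t_min`, `K_R_Pa`, `K_C_Pa`,
#'   `gradient_Pa_per_um`, `n_replicates`.
#' @export
#' @examples
#' truth <- make_stiffness_field(field_params(n_frames = 4))
#' gradient_series(truth)
gradient_series <- function(series, pairs = auto_roi_pairs(series)) {
  stopifnot(inherits(series, "stiffness_series"))
  map(seq_along(series$t_min), function(f) {
    replicate_and_average(series_frame(series, f), pairs)
  }) |> list_rbind()
}
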