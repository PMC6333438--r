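#' Force curve container
#'
#' One approach segment of an indentation: piezo height plus either a
#' deflection or a force channel, carrying cantilever/probe metadata as
#' attributes. Stored as a tibble so it pipes into dplyr/ggplot2 directly.
#'
#' @param data Tibble/data frame with column `z_um` (piezo height, um,
#'   strictly increasing along the approach) and one of `force_nN` or
#'   `deflection_um`.
#' @param k_N_per_m Cantilever spring constant (N/m).
#' @param R_um Probe radius (um).
#' @param i,j Grid-node index of the curve.
#' @param t_min Frame timestamp (min).
#' @return A `force_curve` tibble.
#' @export
force_curve <- function(data, k_N_per_m, R_um, i = 1L, j = 1L, t_min = 0) {
  data <- as_tibble(data)
  chan <- intersect(c("force_nN", "deflection_um"), names(data))
  if (!"z_um" %in% names(data) || length(chan) == 0) {
    stop_bad("force curve needs `z_um` and one of `force_nN`/`deflection_um`")
  }
  if (nrow(data) < 50) stop_bad("force curve needs >= 50 samples")
  dz <- diff(data$z_um)
  if (any(dz <= 0)) stop_bad("`z_um` must be strictly increasing")
  check_number(k_N_per_m, "k_N_per_m", lower = 0, closed_lower = FALSE)
  check_number(R_um, "R_um", lower = 0, closed_lower = FALSE)
  structure(data,
            k_N_per_m = k_N_per_m, R_um = R_um,
            i = as.integer(i), j = as.integer(j), t_min = t_min,
            class = c("force_curve", class(as_tibble(data))))
}

curve_meta <- function(curve) {
  list(k_N_per_m = attr(curve, "k_N_per_m"), R_um = attr(curve, "R_um"),
       i = attr(curve, "i"), j = attr(curve, "j"), t_min = attr(curve, "t_min"))
}

#' Convert a deflection channel to force
#'
#' Hooke's law `F = k d` applied element-wise (nN from N/m and um). A curve
#' that already carries a force channel is returned unchanged.
#'
#' @param curve A [force_curve()].
#' @return The curve with a `force_nN` column.
#' @export
#' @examples
#' d <- tibble::tibble(z_um = seq(0, 5, length.out = 100), deflection_um = 0.5)
#' fc <- force_curve(d, k_N_per_m = 0.03, R_um = 18.64)
#' deflection_to_force(fc)$force_nN[1]  # 15 nN
deflection_to_force <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  if ("force_nN" %in% names(curve)) return(curve)
  k <- attr(curve, "k_N_per_m")
  if (is.null(k) || !is.finite(k)) stop_bad("curve has no spring constant `k_N_per_m`")
  m <- curve_meta(curve)
  out <- as_tibble(curve)
  out$force_nN <- NM_PER_UM_FORCE * k * out$deflection_um
  out$deflection_um <- NULL
  force_curve(out, m$k_N_per_m, m$R_um, m$i, m$j, m$t_min)
}
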