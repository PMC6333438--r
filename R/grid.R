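#' Stiffness map container
#'
#' Per-frame grid of fitted moduli as a tibble (one row per node: `i`,
#' `j`, `x_um`, `y_um`, `K_Pa`, `status`, `reason`), carrying grid
#' geometry and the frame timestamp as a `geometry` attribute.
#'
#' @param data Node tibble.
#' @param x_um,y_um Node coordinate vectors (um).
#' @param spacing Grid step (um).
#' @param t_min Frame timestamp (min).
#' @return A `stiffness_map` tibble.
#' @name stiffness_map
#' @export
new_stiffness_map <- function(data, x_um, y_um, spacing, t_min) {
  data <- as_tibble(data)
  need <- c("i", "j", "x_um", "y_um", "K_Pa", "status", "reason")
  stopifnot(all(need %in% names(data)))
  structure(data,
            geometry = list(x_um = x_um, y_um = y_um, spacing = spacing,
                            t_min = t_min),
            class = c("stiffness_map", class(as_tibble(data))))
}

#' Fit a whole grid of force curves into a stiffness map
#'
#' Runs [fit_hertz()] on every curve of one frame; excluded nodes are
#' flagged missing with their QC reason recorded.
#'
#' @param curves List of [force_curve()]s sharing a frame timestamp.
#' @param spacing Grid step (um) used to lay out node coordinates.
#' @param ... Passed to [fit_hertz()].
#' @return A [stiffness_map] tibble.
#' @export
process_grid <- function(curves, spacing = 20, ...) {
  if (length(curves) == 0) stop_bad("empty grid: no curves to process")
  t_all <- vapply(curves, function(cv) attr(cv, "t_min"), numeric(1))
  if (length(unique(t_all)) > 1) {
    stop_bad("curves in one grid must share a frame timestamp")
  }
  rows <- map(curves, function(cv) glance(fit_hertz(cv, ...)))
  out <- list_rbind(rows)
  nx <- max(out$i); ny <- max(out$j)
  x_um <- (seq_len(nx) - 1) * spacing
  y_um <- (seq_len(ny) - 1) * spacing
  map_tbl <- out |>
    mutate(x_um = x_um[.data$i], y_um = y_um[.data$j]) |>
    select("i", "j", "x_um", "y_um", "K_Pa", "status", "reason",
           "rms_residual_nN", "r_squared", "max_force_reached_nN") |>
    arrange(.data$j, .data$i)
  new_stiffness_map(map_tbl, x_um, y_um, spacing, t_all[1])
}
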