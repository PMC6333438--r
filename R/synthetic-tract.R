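#' Simulate tract landmark traces over a time-lapse
#'
#' The tract is represented by its three landmarks (chiasm,
#' mid-diencephalic bend, end). The turn angle is 0 until
#' `gradient_onset + turn_delay`, then grows linearly at `turn_rate`;
#' each trace realises the current angle exactly, with the end landmark
#' deviating toward caudal (+x).
#'
#' @param scene An [afm_scene()]; `turn_delay` and `turn_rate` come from
#'   it, onset timing from its field.
#' @param t_min Times at which to trace (defaults to the scene's frames).
#' @param segment_um Length of each tract segment (um).
#' @return Tibble with one row per time and landmark: `t_min`,
#'   `turn_true_deg`, `landmark`, `x_um`, `y_um`.
#' @export
#' @examples
#' sc <- afm_scene(field = field_params(n_frames = 3))
#' simulate_tract(sc)
simulate_tract <- function(scene, t_min = scene_frame_times(scene),
                           segment_um = 100) {
  stopifnot(inherits(scene, "afm_scene"))
  onset <- scene$field$gradient_onset + scene$turn_delay
  # a tract cannot fold back past its own axis: cap below 180 deg
  ang <- pmin(pmax(0, t_min - onset) * scene$turn_rate, 179)
  out <- lapply(seq_along(t_min), function(ti) {
    th <- ang[ti] * pi / 180
    chiasm <- c(0, 0)
    bend <- c(0, segment_um)                      # initial growth along +y
    end <- bend + segment_um * c(sin(th), cos(th))  # deviates caudally (+x)
    tibble(t_min = t_min[ti], turn_true_deg = ang[ti],
           landmark = c("chiasm", "bend", "end"),
           x_um = c(chiasm[1], bend[1], end[1]),
           y_um = c(chiasm[2], bend[2], end[2]))
  })
  list_rbind(out)
}

#' Simulate a measured turn-angle time series
#'
#' Measures each frame's trace [turn_angle()] with per-repeat Gaussian
#' angle noise, averaging `n_repeats` repeats per frame as in the manual
#' three-repeat protocol.
#'
#' @param scene An [afm_scene()].
#' @param t_min Frame times (min).
#' @param seed Optional seed.
#' @return Tibble: `t_min`, `turn_deg` (measured), `turn_true_deg`.
#' @export
simulate_turn_series <- function(scene, t_min = scene_frame_times(scene),
                                 seed = NULL) {
  traces <- simulate_tract(scene, t_min)
  with_seed_if(seed, {
    out <- traces |>
      dplyr::group_by(.data$t_min) |>
      dplyr::group_modify(function(tr, key) {
        true <- turn_angle(tr)
        meas <- mean(true + rnorm(scene$n_repeats, 0, scene$angle_noise_sd))
        tibble(turn_deg = meas, turn_true_deg = tr$turn_true_deg[1])
      }) |>
      dplyr::ungroup()
    out
  })
}

#' Simulate a measured gradient time series
#'
#' Evaluates the scene's ground-truth gradient time course and adds
#' per-replicate measurement noise, averaging `n_repeats` ROI replicates
#' per frame as in the three-placement protocol.
#'
#' @inheritParams simulate_turn_series
#' @return Tibble: `t_min`, `gradient_Pa_per_um` (measured),
#'   `gradient_true_Pa_per_um`.
#' @export
simulate_gradient_series <- function(scene, t_min = scene_frame_times(scene),
                                     seed = NULL) {
  stopifnot(inherits(scene, "afm_scene"))
  g <- gradient_timecourse(scene$field, t_min)
  with_seed_if(seed, {
    meas <- vapply(g, function(gt) {
      mean(gt + rnorm(scene$n_repeats, 0, scene$gradient_noise_sd))
    }, numeric(1))
    tibble(t_min = t_min, gradient_Pa_per_um = meas,
           gradient_true_Pa_per_um = g)
  })
}

#' Simulate paired gradient and turn-angle kinetics
#'
#' Convenience wrapper producing the two measured series of one scene,
#' the inputs of the onset-delay analysis.
#'
#' @inheritParams simulate_turn_series
#' @return Tibble: `t_min`, `gradient_Pa_per_um`, `turn_deg` plus the
#'   true values.
#' @export
#' @examples
#' sc <- afm_scene(field = field_params(n_frames = 4))
#' simulate_kinetics_series(sc, seed = 1)
simulate_kinetics_series <- function(scene, t_min = scene_frame_times(scene),
                                     seed = NULL) {
  with_seed_if(seed, {
    grad <- simulate_gradient_series(scene, t_min)
    turn <- simulate_turn_series(scene, t_min)
    dplyr::left_join(grad, turn, by = "t_min")
  })
}
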