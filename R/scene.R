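#' Ground-truth stiffness-field parameters
#'
#' Describes the spatiotemporal apparent-modulus field that a simulated
#' time-lapse indentation experiment samples. The field is uniform at
#' `base_modulus` until `gradient_onset` min, after which a rostro-caudal
#' stiffness gradient grows at `ramp_rate` (Pa/um per min) up to
#' `plateau_gradient`. The gradient is realised as `rostral_fraction` of
#' stiffening on the rostral (low-x) side plus `1 - rostral_fraction` of
#' softening on the caudal side, mirroring tissue that stiffens mostly
#' rostral to the advancing axon tract.
#'
#' Defaults emulate a ~150 x 250 um map rastered at 20 um resolution every
#' ~35 min over a ~4 h session, with the gradient arising tens of minutes
#' into the recording and still growing at its end.
#'
#' @param base_modulus Uniform pre-onset modulus (Pa).
#' @param gradient_onset Time at which the gradient appears (min).
#' @param ramp_rate Growth rate of the gradient (Pa/um per min).
#' @param plateau_gradient Upper bound on the gradient (Pa/um).
#' @param rostral_fraction Share of the gradient produced by rostral
#'   stiffening (vs caudal softening), in `[0, 1]`.
#' @param nx,ny Grid nodes along x (rostral to caudal) and y.
#' @param spacing Grid step (um).
#' @param frame_interval Time between successive maps (min).
#' @param n_frames Number of maps in the time-lapse.
#' @param ramp_shape `"hinge"` (piecewise linear, default) or `"logistic"`
#'   (smooth ramp of the same limiting slope).
#' @return A `field_params` list.
#' @export
#' @examples
#' field_params(n_frames = 4)
field_params <- function(base_modulus = 150,
                         gradient_onset = 40,
                         ramp_rate = 0.02,
                         plateau_gradient = 4.5,
                         rostral_fraction = 0.8,
                         nx = 13, ny = 8,
                         spacing = 20,
                         frame_interval = 35,
                         n_frames = 8,
                         ramp_shape = c("hinge", "logistic")) {
  check_number(base_modulus, "base_modulus", lower = 0, closed_lower = FALSE)
  check_number(ramp_rate, "ramp_rate", lower = 0)
  check_number(plateau_gradient, "plateau_gradient", lower = 0)
  check_number(rostral_fraction, "rostral_fraction", lower = 0, upper = 1)
  check_number(spacing, "spacing", lower = 0, closed_lower = FALSE)
  check_number(frame_interval, "frame_interval", lower = 0, closed_lower = FALSE)
  structure(list(
    base_modulus = base_modulus,
    gradient_onset = gradient_onset,
    ramp_rate = ramp_rate,
    plateau_gradient = plateau_gradient,
    rostral_fraction = rostral_fraction,
    nx = check_count(nx, "nx"), ny = check_count(ny, "ny"),
    spacing = spacing,
    frame_interval = frame_interval,
    n_frames = check_count(n_frames, "n_frames"),
    ramp_shape = match.arg(ramp_shape)
  ), class = "field_params")
}

#' Measurement-noise parameters for simulated force curves
#'
#' @param force_noise_sd Gaussian force noise per sample (nN).
#' @param baseline_slope Linear drift of the non-contact baseline (nN/um).
#' @param baseline_offset Constant force offset (nN).
#' @param dropout_prob Probability that a grid node yields an unanalysable
#'   curve (a pure-noise stub with no contact region), in `[0, 1)`.
#' @param stub_noise_sd Noise level of unanalysable stubs (nN); large by
#'   construction so baseline fits fail on them.
#' @param seed Integer seed making the whole simulated series reproducible.
#' @return A `curve_noise_params` list.
#' @export
curve_noise_params <- function(force_noise_sd = 0.05,
                               baseline_slope = 0.01,
                               baseline_offset = 0.2,
                               dropout_prob = 0.1,
                               stub_noise_sd = 5,
                               seed = 1L) {
  check_number(force_noise_sd, "force_noise_sd", lower = 0)
  check_number(dropout_prob, "dropout_prob", lower = 0, upper = 1,
               closed_upper = FALSE)
  check_number(stub_noise_sd, "stub_noise_sd", lower = 0)
  structure(list(
    force_noise_sd = force_noise_sd,
    baseline_slope = baseline_slope,
    baseline_offset = baseline_offset,
    dropout_prob = dropout_prob,
    stub_noise_sd = stub_noise_sd,
    seed = as.integer(seed)
  ), class = "curve_noise_params")
}

#' Synthetic indentation-experiment scene
#'
#' Bundles the ground-truth field, the curve noise model, the probe and
#' cantilever, and the axon-tract kinetics into one provenance record from
#' which every simulated input of the pipeline derives. Probe and ramp
#' defaults reproduce the experimental settings: an 18.64-um-radius
#' spherical probe on a 0.02-0.04 N/m cantilever, 10 nN maximum force,
#' 5 um/s approach at 1000 Hz.
#'
#' @param field A [field_params()] object.
#' @param noise A [curve_noise_params()] object.
#' @param probe_radius Probe radius R (um).
#' @param spring_constant Cantilever spring constant k (N/m).
#' @param max_force Force at which each approach stops (nN).
#' @param approach_speed Piezo approach speed (um/s).
#' @param data_rate Sampling rate (Hz).
#' @param baseline_length Non-contact approach distance before the surface
#'   (um); determines how many baseline samples each curve carries.
#' @param turn_delay Delay between gradient onset and turning onset (min).
#' @param turn_rate Post-onset growth rate of the turn angle (deg/min).
#' @param angle_noise_sd Per-repeat measurement noise on the turn angle
#'   (deg); each frame is measured as the mean of `n_repeats` noisy repeats.
#' @param gradient_noise_sd Per-replicate noise on simulated gradient
#'   samples (Pa/um).
#' @param n_repeats Measurement repeats averaged per frame (tract angles
#'   and ROI replicates alike).
#' @return An `afm_scene` list.
#' @export
#' @examples
#' sc <- afm_scene(field = field_params(n_frames = 3))
#' sc$probe_radius
afm_scene <- function(field = field_params(),
                      noise = curve_noise_params(),
                      probe_radius = 18.64,
                      spring_constant = 0.03,
                      max_force = 10,
                      approach_speed = 5,
                      data_rate = 1000,
                      baseline_length = 5,
                      turn_delay = 18,
                      turn_rate = 0.3,
                      angle_noise_sd = 0.5,
                      gradient_noise_sd = 0.035,
                      n_repeats = 3L) {
  stopifnot(inherits(field, "field_params"), inherits(noise, "curve_noise_params"))
  check_number(probe_radius, "probe_radius", lower = 0, closed_lower = FALSE)
  check_number(spring_constant, "spring_constant", lower = 0, closed_lower = FALSE)
  check_number(max_force, "max_force", lower = 0, closed_lower = FALSE)
  check_number(approach_speed, "approach_speed", lower = 0, closed_lower = FALSE)
  check_number(data_rate, "data_rate", lower = 0, closed_lower = FALSE)
  check_number(turn_delay, "turn_delay", lower = 0)
  structure(list(
    field = field, noise = noise,
    probe_radius = probe_radius,
    spring_constant = spring_constant,
    max_force = max_force,
    approach_speed = approach_speed,
    data_rate = data_rate,
    baseline_length = baseline_length,
    turn_delay = turn_delay,
    turn_rate = turn_rate,
    angle_noise_sd = angle_noise_sd,
    gradient_noise_sd = gradient_noise_sd,
    n_repeats = check_count(n_repeats, "n_repeats")
  ), class = "afm_scene")
}

#' @export
print.afm_scene <- function(x, ...) {
  f <- x$field
  cat(sprintf(
    "<afm_scene> %dx%d grid @ %g um, %d frames @ %g min\n", f$nx, f$ny,
    f$spacing, f$n_frames, f$frame_interval))
  cat(sprintf("  probe R = %g um, k = %g N/m, F_max = %g nN\n",
              x$probe_radius, x$spring_constant, x$max_force))
  cat(sprintf("  gradient onset %g min, ramp %g Pa/um/min, turn delay %g min\n",
              f$gradient_onset, f$ramp_rate, x$turn_delay))
  invisible(x)
}

scene_frame_times <- function(scene) {
  f <- scene$field
  seq(0, by = f$frame_interval, length.out = f$n_frames)
}
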