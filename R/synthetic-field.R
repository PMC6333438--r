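#' Ground-truth gradient time course
#'
#' The stiffness gradient implied by a parameter set at arbitrary times:
#' zero until `gradient_onset`, then growing at `ramp_rate` until
#' `plateau_gradient` (hinge shape), or a logistic ramp of the same
#' limiting slope when `ramp_shape = "logistic"`.
#'
#' @param params A [field_params()] object.
#' @param t_min Times (min) at which to evaluate.
#' @return Gradient values (Pa/um), same length as `t_min`.
#' @export
#' @examples
#' gradient_timecourse(field_params(ramp_rate = 0.05), c(30, 50))
gradient_timecourse <- function(params, t_min) {
  stopifnot(inherits(params, "field_params"))
  dt <- t_min - params$gradient_onset
  if (params$ramp_shape == "hinge") {
    pmin(pmax(dt, 0) * params$ramp_rate, params$plateau_gradient)
  } else {
    # logistic with maximal slope ramp_rate at its midpoint, centred so the
    # curve passes plateau/2 at onset + plateau/(2*ramp_rate)
    g <- params$plateau_gradient
    if (g == 0 || params$ramp_rate == 0) return(rep(0, length(t_min)))
    rate <- 4 * params$ramp_rate / g
    mid <- params$gradient_onset + g / (2 * params$ramp_rate)
    g / (1 + exp(-rate * (t_min - mid)))
  }
}

#' Ground-truth apparent-modulus field
#'
#' Builds the x-by-y-by-frame array of true moduli for a scene: uniform
#' before gradient onset, then the rostral (low-x) half stiffens by
#' `rostral_fraction` of the gradient amplitude while the caudal half
#' softens by the remainder. The mid-column (present when `nx` is odd)
#' stays at the base modulus, standing in for the tract zone the gradient
#' flanks. Deterministic given its parameters.
#'
#' @param params A [field_params()] object.
#' @return A [stiffness_series] whose `K` holds true moduli (Pa), with a
#'   full observation mask.
#' @export
#' @examples
#' truth <- make_stiffness_field(field_params(n_frames = 3))
#' dim(truth$K)
make_stiffness_field <- function(params) {
  stopifnot(inherits(params, "field_params"))
  nx <- params$nx; ny <- params$ny; nf <- params$n_frames
  t_min <- seq(0, by = params$frame_interval, length.out = nf)
  g <- gradient_timecourse(params, t_min)               # Pa/um
  amp <- g * ROI_SEPARATION_UM                          # K_R - K_C in Pa
  x <- (seq_len(nx) - 1) * params$spacing
  mid <- (nx + 1) / 2
  side <- sign(mid - seq_len(nx))                       # +1 rostral, -1 caudal, 0 mid
  shift <- ifelse(side > 0, params$rostral_fraction,
                  ifelse(side < 0, -(1 - params$rostral_fraction), 0))
  K <- array(params$base_modulus, dim = c(nx, ny, nf))
  for (f in seq_len(nf)) {
    K[, , f] <- params$base_modulus + outer(shift * amp[f], rep(1, ny))
  }
  new_stiffness_series(K,
                       x_um = x,
                       y_um = (seq_len(ny) - 1) * params$spacing,
                       t_min = t_min,
                       spacing = params$spacing)
}
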