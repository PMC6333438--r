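#' Simulate one approach force curve
#'
#' Forward model of a spherical-probe indentation: uniform piezo sampling
#' at `approach_speed / data_rate`, a linear drifting baseline with
#' Gaussian noise before contact, and beyond the contact point the Hertz
#' force with cantilever-deflection coupling (the implicit relation
#' \eqn{F = (4/3) K [(z - z_c) - F/k]^{3/2} \sqrt{R}}, solved per sample),
#' truncated at the first sample reaching `max_force`.
#'
#' @param K_true True reduced apparent modulus (Pa), > 0.
#' @param scene An [afm_scene()].
#' @param i,j,t_min Node index and frame timestamp stamped on the curve.
#' @param contact_frac Position of the contact point inside its sampling
#'   interval (0-1); keeps the true contact off the sample grid.
#' @param seed Optional integer seed for the curve's noise; when `NULL`
#'   the current RNG stream is used.
#' @return A [force_curve()] with a `force_nN` channel. The true contact
#'   point is recorded in attribute `z_c_true_um`.
#' @export
#' @examples
#' sc <- afm_scene(noise = curve_noise_params(force_noise_sd = 0))
#' fc <- simulate_force_curve(100, sc, seed = 1)
#' range(fc$force_nN)
simulate_force_curve <- function(K_true, scene, i = 1L, j = 1L, t_min = 0,
                                 contact_frac = 0.37, seed = NULL) {
  stopifnot(inherits(scene, "afm_scene"))
  check_number(K_true, "K_true", lower = 0, closed_lower = FALSE)
  with_seed_if(seed, {
    dz <- scene$approach_speed / scene$data_rate
    k <- scene$spring_constant
    pref <- hertz_prefactor(scene$probe_radius)
    z_c <- scene$baseline_length + contact_frac * dz
    # indentation depth at which the *noiseless* Hertz force reaches max_force
    delta_max <- (scene$max_force / (pref * K_true))^(2 / 3)
    z_max <- z_c + delta_max + scene$max_force / (NM_PER_UM_FORCE * k)
    z <- seq(0, z_max + 2 * dz, by = dz)

    F_true <- numeric(length(z))
    past <- z > z_c
    if (any(past)) {
      zz <- z[past] - z_c
      Fi <- pref * K_true * zz^1.5          # start from rigid-cantilever guess
      for (it in 1:60) {
        Fi_new <- pref * K_true * pmax(zz - Fi / (NM_PER_UM_FORCE * k), 0)^1.5
        if (max(abs(Fi_new - Fi)) < 1e-12) { Fi <- Fi_new; break }
        Fi <- Fi_new
      }
      F_true[past] <- Fi
    }
    stop_at <- which(F_true >= scene$max_force)
    if (length(stop_at)) {
      keep <- seq_len(stop_at[1])
      z <- z[keep]; F_true <- F_true[keep]
    }
    noise <- scene$noise
    F_obs <- F_true + noise$baseline_offset + noise$baseline_slope * z +
      rnorm(length(z), 0, noise$force_noise_sd)
    out <- force_curve(tibble(z_um = z, force_nN = F_obs),
                       k_N_per_m = k, R_um = scene$probe_radius,
                       i = i, j = j, t_min = t_min)
    attr(out, "z_c_true_um") <- z_c
    out
  })
}

#' Simulate an unanalysable stub curve
#'
#' Pure wide-band noise with no contact region; triggers the baseline
#' exclusion criterion in [fit_baseline()] by construction.
#'
#' @inheritParams simulate_force_curve
#' @return A [force_curve()] flagged with attribute `stub = TRUE`.
#' @export
simulate_stub_curve <- function(scene, i = 1L, j = 1L, t_min = 0, seed = NULL) {
  stopifnot(inherits(scene, "afm_scene"))
  with_seed_if(seed, {
    dz <- scene$approach_speed / scene$data_rate
    z <- seq(0, scene$baseline_length * 2, by = dz)
    F_obs <- rnorm(length(z), 0, scene$noise$stub_noise_sd)
    out <- force_curve(tibble(z_um = z, force_nN = F_obs),
                       k_N_per_m = scene$spring_constant,
                       R_um = scene$probe_radius, i = i, j = j, t_min = t_min)
    attr(out, "stub") <- TRUE
    out
  })
}

#' Simulate a full time-lapse grid of force curves
#'
#' One curve per grid node per frame, sampled from the scene's
#' ground-truth field; each node is independently replaced by an
#' unanalysable stub with probability `dropout_prob`. Fully deterministic
#' given the scene's noise seed.
#'
#' @param scene An [afm_scene()].
#' @return A list with `curves` (list of frames, each a list of
#'   [force_curve()]s), `truth` (the ground-truth [stiffness_series]) and
#'   `dropout` (tibble of node/frame stub indicators).
#' @export
#' @examples
#' sc <- afm_scene(field = field_params(nx = 3, ny = 2, n_frames = 2))
#' sim <- simulate_map_series(sc)
#' length(sim$curves[[1]])
simulate_map_series <- function(scene) {
  stopifnot(inherits(scene, "afm_scene"))
  truth <- make_stiffness_field(scene$field)
  d <- dim(truth$K)
  with_seed_if(scene$noise$seed, {
    dropout <- array(runif(prod(d)) < scene$noise$dropout_prob, dim = d)
    frames <- vector("list", d[3])
    for (f in seq_len(d[3])) {
      cur <- vector("list", d[1] * d[2])
      idx <- 1L
      for (j in seq_len(d[2])) {
        for (i in seq_len(d[1])) {
          cur[[idx]] <- if (dropout[i, j, f]) {
            simulate_stub_curve(scene, i = i, j = j, t_min = truth$t_min[f])
          } else {
            simulate_force_curve(truth$K[i, j, f], scene, i = i, j = j,
                                 t_min = truth$t_min[f])
          }
          idx <- idx + 1L
        }
      }
      frames[[f]] <- cur
    }
    grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                        frame = seq_len(d[3]))
    list(curves = frames, truth = truth,
         dropout = tibble(i = grid$i, j = grid$j, frame = grid$frame,
                          stub = as.vector(dropout)))
  })
}
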