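#' Fit the non-contact baseline of a force curve
#'
#' Locates a provisional contact point (first sample exceeding the
#' baseline noise by 5 sd, sustained over the following samples), fits an
#' ordinary least-squares line through the first 60% of samples before it,
#' and flags curves whose baseline cannot be fitted -- the first exclusion
#' criterion of the curve-processing protocol.
#'
#' @param curve A [force_curve()] (deflection curves are converted first).
#' @param analysis_force Force at which curves are analysed (nN); the
#'   baseline residual criterion is expressed relative to it.
#' @param max_resid_frac Baseline failure threshold: residual sd of the
#'   baseline fit above this fraction of `analysis_force` marks the curve
#'   `excluded(baseline)`.
#' @param noise_k Provisional-contact detection threshold in baseline-noise
#'   sd units.
#' @return A list with `slope` (nN/um), `intercept` (nN), `resid_sd`,
#'   `noise_sd`, `provisional_index`, `status` and `reason`.
#' @export
fit_baseline <- function(curve, analysis_force = 10, max_resid_frac = 0.25,
                         noise_k = 5) {
  curve <- deflection_to_force(curve)
  z <- curve$z_um; F <- curve$force_nN
  n <- length(z)

  # baseline noise from the detrended first quarter of the approach
  head_idx <- seq_len(max(20L, floor(0.25 * n)))
  head_fit <- lm.fit(cbind(1, z[head_idx]), F[head_idx])
  noise_sd <- sd(head_fit$residuals)
  trend <- cbind(1, z) %*% head_fit$coefficients
  above <- (F - trend) > noise_k * max(noise_sd, .Machine$double.eps)

  # sustained exceedance: the sample and its next 9 neighbours all above
  run <- 10L
  wins <- stats::filter(as.numeric(above), rep(1, run), sides = 1)
  hit <- which(!is.na(wins) & wins == run)
  prov <- if (length(hit)) hit[1] - run + 1L else NA_integer_

  window <- if (is.na(prov)) seq_len(floor(0.6 * n)) else seq_len(floor(0.6 * (prov - 1)))
  if (length(window) < 20L) {
    return(list(slope = NA_real_, intercept = NA_real_, resid_sd = NA_real_,
                noise_sd = noise_sd, provisional_index = prov,
                status = "excluded", reason = "baseline"))
  }
  fit <- lm.fit(cbind(1, z[window]), F[window])
  resid_sd <- sd(fit$residuals)
  bad <- is.na(prov) || resid_sd > max_resid_frac * analysis_force
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       resid_sd = resid_sd, noise_sd = noise_sd, provisional_index = prov,
       status = if (bad) "excluded" else "ok",
       reason = if (bad) "baseline" else NA_character_)
}

hertz_fit_obj <- function(meta, analysis_force, status, reason,
                          K = NA_real_, z_c = NA_real_, baseline = NULL,
                          rms = NA_real_, r2 = NA_real_, fmax = NA_real_,
                          n_contact = NA_integer_) {
  structure(list(
    K_Pa = K, contact_z_um = z_c,
    baseline_slope = baseline$slope %||% NA_real_,
    baseline_intercept = baseline$intercept %||% NA_real_,
    rms_residual_nN = rms, r_squared = r2,
    max_force_reached_nN = fmax, n_contact = n_contact,
    analysis_force_nN = analysis_force,
    i = meta$i, j = meta$j, t_min = meta$t_min,
    status = status, reason = reason
  ), class = "hertz_fit")
}

#' Fit the Hertz contact model to a force curve
#'
#' Baseline-subtracts the force channel, then finds the contact point
#' \eqn{z_c} and reduced apparent modulus K minimising the squared
#' residuals of \eqn{F = (4/3) K \delta^{3/2} \sqrt{R}} over the contact
#' region up to the analysis force. Indentation uses tip-sample separation,
#' \eqn{\delta = (z - z_c) - F/k}. The contact point is scanned over
#' candidate samples -- K has a closed-form least-squares solution per
#' candidate -- and the best pair is refined by bounded continuous
#' optimisation. Curves whose Hertzian fit does not align with the data
#' (high residual, low R-squared, or force never reaching the analysis
#' force) are marked `excluded(hertz_fit)`, the protocol's second
#' exclusion criterion.
#'
#' @inheritParams fit_baseline
#' @param baseline Optional result of [fit_baseline()]; computed if `NULL`.
#' @param max_rms_frac Exclusion threshold: fit RMS residual over the
#'   contact region above this fraction of `analysis_force`.
#' @param min_r_squared Exclusion threshold on the Hertz-fit R-squared.
#' @param force_tol Relative shortfall of the maximum reached force below
#'   `analysis_force` that is still tolerated.
#' @param n_candidates Maximum number of contact-point candidates scanned.
#' @return A `hertz_fit` object; see [tidy.hertz_fit()] / [glance.hertz_fit()].
#' @export
#' @examples
#' sc <- afm_scene(field = field_params(n_frames = 1),
#'                 noise = curve_noise_params(force_noise_sd = 0))
#' fc <- simulate_force_curve(120, sc, seed = 1)
#' fit <- fit_hertz(fc)
#' fit$K_Pa
fit_hertz <- function(curve, analysis_force = 10, baseline = NULL,
                      max_rms_frac = 0.10, min_r_squared = 0.8,
                      force_tol = 0.02, max_resid_frac = 0.25,
                      n_candidates = 150) {
  curve <- deflection_to_force(curve)
  meta <- curve_meta(curve)
  if (is.null(baseline)) {
    baseline <- fit_baseline(curve, analysis_force = analysis_force,
                             max_resid_frac = max_resid_frac)
  }
  if (identical(baseline$status, "excluded")) {
    return(hertz_fit_obj(meta, analysis_force, "excluded", "baseline",
                         baseline = baseline))
  }
  z <- curve$z_um
  Fc <- curve$force_nN - (baseline$intercept + baseline$slope * z)
  n <- length(z)
  k <- meta$k_N_per_m
  pref <- hertz_prefactor(meta$R_um)
  fmax <- max(Fc)

  if (fmax < (1 - force_tol) * analysis_force) {
    return(hertz_fit_obj(meta, analysis_force, "excluded", "hertz_fit",
                         baseline = baseline, fmax = fmax))
  }

  dz <- median(diff(z))
  prov <- baseline$provisional_index
  i_end <- if (any(Fc >= analysis_force)) which(Fc >= analysis_force)[1] else n
  i0 <- max(1L, prov - ceiling(2 / dz))
  i1 <- which(Fc > 0.2 * analysis_force)[1]
  if (is.na(i1) || i1 <= i0 + 2L) i1 <- min(i0 + 10L, i_end - 1L)
  cand <- unique(round(seq(i0, i1, length.out = min(n_candidates, i1 - i0 + 1L))))

  region <- i0:i_end
  Fr <- Fc[region]; zr <- z[region]
  Fc_over_k <- Fr / (NM_PER_UM_FORCE * k)

  sse_at <- function(z_c) {
    contact <- zr > z_c
    if (!any(contact)) return(list(sse = sum(Fr^2), K = NA_real_))
    delta <- pmax((zr[contact] - z_c) - Fc_over_k[contact], 0)
    x <- pref * delta^1.5
    sxx <- sum(x * x)
    K <- if (sxx > 0) sum(Fr[contact] * x) / sxx else NA_real_
    resid <- if (is.na(K)) Fr[contact] else Fr[contact] - K * x
    list(sse = sum(Fr[!contact]^2) + sum(resid^2), K = K)
  }

  best <- list(sse = Inf, z_c = NA_real_, K = NA_real_)
  for (ci in seq_along(cand)) {
    res <- sse_at(z[cand[ci]])
    if (res$sse < best$sse) best <- list(sse = res$sse, z_c = z[cand[ci]],
                                         K = res$K, idx = ci)
  }
  # continuous refinement between neighbouring candidates
  lo <- z[cand[max(best$idx - 1L, 1L)]]
  hi <- z[cand[min(best$idx + 1L, length(cand))]]
  if (hi > lo) {
    opt <- optimize(function(zc) sse_at(zc)$sse, interval = c(lo, hi),
                    tol = 1e-9)
    if (opt$objective <= best$sse) {
      best$z_c <- opt$minimum
      fin <- sse_at(best$z_c)
      best$K <- fin$K; best$sse <- fin$sse
    }
  }

  contact <- zr > best$z_c
  n_contact <- sum(contact)
  if (is.na(best$K) || best$K <= 0 || n_contact < 5L) {
    return(hertz_fit_obj(meta, analysis_force, "excluded", "hertz_fit",
                         baseline = baseline, fmax = fmax))
  }
  delta <- pmax((zr[contact] - best$z_c) - Fc_over_k[contact], 0)
  pred <- pref * best$K * delta^1.5
  resid <- Fr[contact] - pred
  rms <- sqrt(mean(resid^2))
  ss_tot <- sum((Fr[contact] - mean(Fr[contact]))^2)
  r2 <- if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_
  bad <- rms > max_rms_frac * analysis_force ||
    (!is.na(r2) && r2 < min_r_squared)
  hertz_fit_obj(meta, analysis_force,
                status = if (bad) "excluded" else "accepted",
                reason = if (bad) "hertz_fit" else NA_character_,
                K = if (bad) NA_real_ else best$K,
                z_c = best$z_c, baseline = baseline,
                rms = rms, r2 = r2, fmax = fmax, n_contact = n_contact)
}

#' @export
print.hertz_fit <- function(x, ...) {
  if (identical(x$status, "accepted")) {
    cat(sprintf("<hertz_fit> K = %.4g Pa, z_c = %.4g um, RMS %.3g nN, R^2 %.4f\n",
                x$K_Pa, x$contact_z_um, x$rms_residual_nN, x$r_squared))
  } else {
    cat(sprintf("<hertz_fit> excluded (%s)\n", x$reason))
  }
  invisible(x)
}

#' Tidy a Hertz fit into parameter rows
#'
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @return Tibble with `term`/`estimate` rows for the modulus, contact
#'   point and baseline parameters.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(term = c("K_Pa", "contact_z_um", "baseline_slope_nN_per_um",
                  "baseline_intercept_nN"),
         estimate = c(x$K_Pa, x$contact_z_um, x$baseline_slope,
                      x$baseline_intercept))
}

#' One-row summary of a Hertz fit
#'
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @return One-row tibble with modulus, diagnostics, QC verdict and node
#'   identity.
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(K_Pa = x$K_Pa, contact_z_um = x$contact_z_um,
         rms_residual_nN = x$rms_residual_nN, r_squared = x$r_squared,
         max_force_reached_nN = x$max_force_reached_nN,
         n_contact = x$n_contact, i = x$i, j = x$j, t_min = x$t_min,
         status = x$status, reason = x$reason)
}
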