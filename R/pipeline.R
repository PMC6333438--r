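#' Default pipeline configuration
#'
#' Nested list mirroring the pipeline stages: scene (simulation), fit
#' (curve QC thresholds), smooth, roi, kinetics, density (nuclei-image
#' stage) and logging. [read_run_config()] validates user configs against
#' this schema; unknown keys are rejected.
#'
#' @param seed Integer seed for the whole run.
#' @return Named list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scene = list(
      field = unclass(field_params()),
      noise = unclass(curve_noise_params()),
      probe_radius = 18.64, spring_constant = 0.03, max_force = 10,
      approach_speed = 5, data_rate = 1000, baseline_length = 5,
      turn_delay = 18, turn_rate = 0.3, angle_noise_sd = 0.5,
      gradient_noise_sd = 0.035, n_repeats = 3L
    ),
    fit = list(analysis_force = 10, max_rms_frac = 0.10,
               min_r_squared = 0.8, force_tol = 0.02,
               max_resid_frac = 0.25),
    smooth = list(s = "auto", robust = FALSE),
    roi = list(standoff = 10, size = 50, replicate_offsets = c(-20, 0, 20)),
    kinetics = list(fit_window = "rise", rise_level = 0.1, crossing = 0),
    density = list(
      enabled = TRUE,
      stage_names = c("early", "mid", "late"),
      stage_windows = list(c(0, 90), c(90, 180), c(180, 280)),
      fractions_R = c(0.20, 0.28, 0.35),
      fractions_C = c(0.20, 0.21, 0.23),
      nucleus_radius = 4, pixel_size = 0.5, image_um = 100,
      threshold = 0.5
    ),
    log_level = "info"
  )
}

check_schema <- function(config, template, path = "") {
  extra <- setdiff(names(config), names(template))
  if (length(extra)) {
    stop_bad("unknown config key%s: %s", if (length(extra) > 1) "s" else "",
             paste0(path, extra, collapse = ", "))
  }
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]])) {
      check_schema(config[[nm]], template[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(config)
}

#' Read and validate a pipeline configuration
#'
#' Accepts YAML or JSON. Supplied keys override the defaults; keys not in
#' the schema are an error.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @param seed Default seed when the file does not set one.
#' @return Validated config list.
#' @export
read_run_config <- function(path, seed = 1L) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop_bad("config must be .yaml/.yml or .json: %s", path)
  }
  template <- default_run_config(seed)
  check_schema(user, template)
  modifyList(template, user)
}

scene_from_config <- function(config) {
  fp <- do.call(field_params, config$scene$field)
  np <- do.call(curve_noise_params, config$scene$noise)
  sc <- config$scene[setdiff(names(config$scene), c("field", "noise"))]
  do.call(afm_scene, c(list(field = fp, noise = np), sc))
}

pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[elastomap] ", fmt), ...))
  }
  invisible(NULL)
}

#' Run the full synthetic-to-report pipeline
#'
#' Orchestrates the analysis chain on a simulated scene: generate the
#' time-lapse force-curve grids, fit every curve (Hertz QC table), stack
#' and smooth the stiffness series, extract the ROI gradient series,
#' measure turn angles, fit onset kinetics and the gradient-to-turning
#' delay, compute fold-change maps, and (optionally) run the nuclei
#' density stage with its density-stiffness correlation. Every stage
#' artefact is written under `out_dir` with fixed numeric formatting, so
#' a rerun with the same seed is byte-identical; a machine-readable
#' manifest records parameters, versions and per-stage counts.
#'
#' @param config Configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory.
#' @param seed Overrides `config$seed` when given.
#' @return Invisibly, a list with the main results (series, gradient
#'   table, kinetics fits, delay row, density summary, manifest).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config <- check_schema(config, default_run_config())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  config$scene$noise$seed <- as.integer(derive_seed(seed, 1))

  scene <- scene_from_config(config)
  pipe_log(config, "simulating %dx%d grid, %d frames (seed %d)",
           scene$field$nx, scene$field$ny, scene$field$n_frames, seed)
  sim <- simulate_map_series(scene)

  fit_args <- config$fit
  maps <- lapply(sim$curves, function(frame_curves) {
    do.call(process_grid, c(list(frame_curves, spacing = scene$field$spacing),
                            fit_args))
  })
  qc <- list_rbind(lapply(maps, function(m) {
    as_tibble(m)[, c("i", "j", "K_Pa", "status", "reason",
                     "rms_residual_nN", "r_squared")]
  }))
  qc$frame <- rep(seq_along(maps), each = nrow(maps[[1]]))
  qc_out <- qc
  for (col in c("K_Pa", "rms_residual_nN", "r_squared")) {
    qc_out[[col]] <- fmt_num(qc_out[[col]], 12)
  }
  utils::write.csv(qc_out, file.path(out_dir, "curve_qc.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  n_excl <- table(factor(qc$reason[qc$status != "accepted"],
                         levels = c("baseline", "hertz_fit")))
  pipe_log(config, "fitted %d curves: %d accepted, %d baseline-, %d hertz-excluded",
           nrow(qc), sum(qc$status == "accepted"),
           n_excl[["baseline"]], n_excl[["hertz_fit"]])

  series <- assemble_series(maps)
  write_series(series, out_dir, prefix = "raw")
  smoothed <- smooth_stiffness_series(series, s = config$smooth$s,
                                      robust = config$smooth$robust)
  sm <- attr(smoothed, "smooth")
  write_series(smoothed, out_dir, prefix = "smoothed")
  pipe_log(config, "smoothed series: s = %.4g, %d nodes imputed",
           sm$s_selected, sm$n_imputed)

  pairs <- auto_roi_pairs(smoothed, standoff = config$roi$standoff,
                          size = config$roi$size,
                          replicate_offsets = config$roi$replicate_offsets)
  write_roi_json(pairs, file.path(out_dir, "rois.json"))
  grads <- gradient_series(smoothed, pairs)
  grads_out <- grads
  for (col in c("K_R_Pa", "K_C_Pa", "gradient_Pa_per_um")) {
    grads_out[[col]] <- fmt_num(grads_out[[col]], 12)
  }
  utils::write.csv(grads_out, file.path(out_dir, "gradient_series.csv"),
                   row.names = FALSE, quote = FALSE)

  turn <- simulate_turn_series(scene, seed = derive_seed(seed, 2))
  traces <- simulate_tract(scene)
  write_trace_json(traces, file.path(out_dir, "traces.json"))
  kin_grad <- fit_onset(grads, t_min, gradient_Pa_per_um,
                        kind = "gradient",
                        fit_window = config$kinetics$fit_window,
                        rise_level = config$kinetics$rise_level,
                        crossing = config$kinetics$crossing)
  kin_turn <- fit_onset(turn, t_min, turn_deg,
                        kind = "turn_angle",
                        fit_window = config$kinetics$fit_window,
                        rise_level = config$kinetics$rise_level,
                        crossing = config$kinetics$crossing)
  delay <- onset_delay(kin_grad, kin_turn)
  kin_tbl <- rbind(glance(kin_grad), glance(kin_turn))
  kin_out <- kin_tbl
  for (col in c("slope", "intercept", "r_squared", "onset_min")) {
    kin_out[[col]] <- fmt_num(kin_out[[col]], 12)
  }
  utils::write.csv(kin_out, file.path(out_dir, "kinetics_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  pipe_log(config, "onsets: gradient %.1f min, turning %.1f min (delay %.1f)",
           delay$onset_gradient_min, delay$onset_turn_min, delay$delay_min)

  fold <- fold_change_maps(smoothed, reference = "previous")
  write_series(fold, out_dir, prefix = "foldchange")

  density_summary <- NULL
  if (isTRUE(config$density$enabled)) {
    dc <- config$density
    rows <- lapply(seq_along(dc$stage_names), function(si) {
      img <- simulate_nuclei_image(
        dc$fractions_R[si], dc$fractions_C[si],
        nucleus_radius = dc$nucleus_radius, pixel_size = dc$pixel_size,
        width_um = dc$image_um, height_um = dc$image_um,
        seed = as.integer(derive_seed(seed, 10 + si))
      )
      half <- dc$image_um / 2
      d_r <- cell_density(img$image, roi_box(0, half - 25, 50),
                          pixel_size = dc$pixel_size,
                          threshold = dc$threshold)
      d_c <- cell_density(img$image, roi_box(dc$image_um - 50, half - 25, 50),
                          pixel_size = dc$pixel_size,
                          threshold = dc$threshold)
      w <- dc$stage_windows[[si]]
      inside <- grads$t_min >= w[1] & grads$t_min < w[2]
      tibble(stage = dc$stage_names[si],
             D_R = d_r, D_C = d_c,
             density_gradient_per_um = density_gradient(d_r, d_c),
             stiffness_gradient_Pa_per_um =
               mean(grads$gradient_Pa_per_um[inside]))
    })
    density_tbl <- list_rbind(rows)
    corr <- gradient_correlation(density_tbl,
                                 stiffness_gradient_Pa_per_um,
                                 density_gradient_per_um)
    density_summary <- list(stages = density_tbl, correlation = corr)
    dt_out <- density_tbl
    for (col in c("D_R", "D_C", "density_gradient_per_um",
                  "stiffness_gradient_Pa_per_um")) {
      dt_out[[col]] <- fmt_num(dt_out[[col]], 12)
    }
    utils::write.csv(dt_out, file.path(out_dir, "density_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    pipe_log(config, "density-stiffness correlation rho = %.3f",
             corr$pearson_rho)
  }

  manifest <- list(
    package = "elastomap",
    version = as.character(packageVersion("elastomap")),
    seed = seed,
    config = config,
    counts = list(
      n_curves = nrow(qc),
      n_accepted = sum(qc$status == "accepted"),
      n_excluded_baseline = unname(n_excl[["baseline"]]),
      n_excluded_hertz = unname(n_excl[["hertz_fit"]]),
      n_imputed = sm$n_imputed,
      n_frames = length(series$t_min)
    ),
    smoothing = list(s_selected = sm$s_selected, gcv = sm$gcv),
    kinetics = list(onset_gradient_min = delay$onset_gradient_min,
                    onset_turn_min = delay$onset_turn_min,
                    delay_min = delay$delay_min),
    density = if (!is.null(density_summary)) {
      list(pearson_rho = density_summary$correlation$pearson_rho)
    }
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(series = series, smoothed = smoothed, gradients = grads,
                 turn = turn, kinetics = list(gradient = kin_grad,
                                              turn = kin_turn),
                 delay = delay, density = density_summary,
                 manifest = manifest, qc = qc))
}
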