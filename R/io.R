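# Force-curve text dialect: UTF-8, '#'-prefixed "key: value" header lines
# (k_N_per_m, R_um, i, j, t_min, channel), then two tab-separated columns:
# z_um and the channel (force_nN or deflection_um).

#' Write a force curve to the text format
#'
#' @param curve A [force_curve()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  m <- curve_meta(curve)
  chan <- intersect(c("force_nN", "deflection_um"), names(curve))[1]
  header <- c(
    sprintf("# k_N_per_m: %s", fmt_num(m$k_N_per_m)),
    sprintf("# R_um: %s", fmt_num(m$R_um)),
    sprintf("# i: %d", m$i),
    sprintf("# j: %d", m$j),
    sprintf("# t_min: %s", fmt_num(m$t_min)),
    sprintf("# channel: %s", chan)
  )
  body <- paste(fmt_num(curve$z_um, 17), fmt_num(curve[[chan]], 17), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a force curve from the text format
#'
#' Tolerates CRLF line endings; errors name any missing header field.
#'
#' @param path Input file.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  is_head <- grepl("^#", lines)
  header <- lines[is_head]
  kv <- regmatches(header, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", header))
  keys <- vapply(kv, function(x) if (length(x) == 3) x[2] else NA_character_,
                 character(1))
  vals <- vapply(kv, function(x) if (length(x) == 3) x[3] else NA_character_,
                 character(1))
  meta <- setNames(as.list(vals), keys)
  for (need in c("k_N_per_m", "R_um", "channel")) {
    if (is.null(meta[[need]])) {
      stop_bad("force-curve file %s is missing header field `%s`", path, need)
    }
  }
  chan <- meta$channel
  if (!chan %in% c("force_nN", "deflection_um")) {
    stop_bad("unknown channel `%s` in %s", chan, path)
  }
  body <- lines[!is_head & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop_bad("malformed data line in %s", path)
  z <- as.numeric(vapply(parts, `[[`, character(1), 1))
  v <- as.numeric(vapply(parts, `[[`, character(1), 2))
  if (anyNA(z) || anyNA(v)) stop_bad("non-numeric data in %s", path)
  d <- tibble(z_um = z)
  d[[chan]] <- v
  force_curve(d,
              k_N_per_m = as.numeric(meta$k_N_per_m),
              R_um = as.numeric(meta$R_um),
              i = as.integer(meta$i %||% 1L),
              j = as.integer(meta$j %||% 1L),
              t_min = as.numeric(meta$t_min %||% 0))
}

#' Write a stiffness map as CSV
#'
#' Columns `i, j, x_um, y_um, K_Pa, status, reason`; geometry goes into a
#' JSON sidecar when written as part of a series.
#'
#' @param map A [stiffness_map].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  df <- as.data.frame(map)[, c("i", "j", "x_um", "y_um", "K_Pa",
                               "status", "reason")]
  df$K_Pa <- fmt_num(df$K_Pa, 12)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a stiffness series as per-frame CSV grids plus a JSON sidecar
#'
#' @param series A [stiffness_series].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The sidecar path, invisibly.
#' @export
write_series <- function(series, dir, prefix = "map") {
  stopifnot(inherits(series, "stiffness_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$K)
  files <- character(d[3])
  for (f in seq_len(d[3])) {
    files[f] <- sprintf("%s_frame%03d.csv", prefix, f)
    write_map_csv(series_frame(series, f), file.path(dir, files[f]))
  }
  sidecar <- file.path(dir, paste0(prefix, "_series.json"))
  jsonlite::write_json(list(
    shape = d, t_min = series$t_min, spacing = series$spacing,
    x_um = series$x_um, y_um = series$y_um, frames = files,
    n_missing = sum(!series$mask)
  ), sidecar, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}

#' Read a stiffness series written by [write_series()]
#'
#' @param sidecar Path to the `*_series.json` sidecar.
#' @return A [stiffness_series].
#' @export
read_series <- function(sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  dir <- dirname(sidecar)
  d <- as.integer(meta$shape)
  K <- array(NA_real_, d)
  for (f in seq_along(meta$frames)) {
    df <- utils::read.csv(file.path(dir, meta$frames[f]),
                          stringsAsFactors = FALSE)
    acc <- df$status == "accepted"
    K[cbind(df$i, df$j, f)] <- ifelse(acc, as.numeric(df$K_Pa), NA_real_)
  }
  new_stiffness_series(K, meta$x_um, meta$y_um, meta$t_min, meta$spacing)
}

#' Write and read ROI pairs as JSON
#'
#' @param pairs List of [roi_pair()]s.
#' @param path JSON file.
#' @return `path` / the list of pairs.
#' @export
write_roi_json <- function(pairs, path) {
  if (inherits(pairs, "roi_pair")) pairs <- list(pairs)
  payload <- lapply(pairs, function(p) {
    list(replicate = p$replicate,
         rostral = p$rostral[c("x0", "y0", "size")],
         caudal = p$caudal[c("x0", "y0", "size")])
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    roi_pair(roi_box(p$rostral$x0, p$rostral$y0, p$rostral$size),
             roi_box(p$caudal$x0, p$caudal$y0, p$caudal$size),
             replicate = p$replicate)
  })
}

#' Write and read tract landmark traces as JSON
#'
#' @param traces Tibble of landmarks (`t_min`, `landmark`, `x_um`, `y_um`).
#' @param path JSON file.
#' @return `path` / the landmark tibble.
#' @export
write_trace_json <- function(traces, path) {
  jsonlite::write_json(as.data.frame(traces), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace_json
#' @export
read_trace_json <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write and read single-channel grayscale TIFF images
#'
#' Thin wrappers storing matrices (rows = y, cols = x) as 16-bit
#' grayscale TIFF.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path TIFF file.
#' @return `path` / the image matrix.
#' @export
write_gray_tiff <- function(image, path) {
  stopifnot(is.matrix(image))
  tiff::writeTIFF(pmin(pmax(image, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_gray_tiff
#' @export
read_gray_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}
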