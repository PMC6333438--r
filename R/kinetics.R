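#' Rescale a series to the unit interval
#'
#' `(x - min) / (max - min)`: the per-embryo normalisation applied to
#' gradient and turn-angle series before cross-animal comparison. The
#' minimum maps to 0 and the maximum to 1; a constant series is an error.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return Rescaled vector in `[0, 1]`.
#' @export
#' @examples
#' rescale_series(c(2, 5, 8))
rescale_series <- function(x) {
  if (length(x) < 2) stop_bad("rescaling needs >= 2 values")
  rng <- range(x, na.rm = TRUE)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop_bad("constant series cannot be rescaled")
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

ols_line <- function(t, y) {
  if (length(unique(t)) < 2) stop_bad("degenerate time axis in linear fit")
  fit <- lm(y ~ t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' First-degree polynomial fit of a time series
#'
#' Ordinary least squares line through `(t, y)` with the R-squared that
#' estimates fit quality.
#'
#' @param data Data frame holding the series.
#' @param time,value Columns with the time axis (min) and response.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`.
#' @export
#' @examples
#' linear_fit(tibble::tibble(t = 0:5, y = 2 * (0:5) + 1), t, y)
linear_fit <- function(data, time, value) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  as_tibble(ols_line(t, y))
}

#' Fit onset kinetics of a rescaled time series
#'
#' Rescales the series to `[0, 1]`, fits a line, and extrapolates the
#' onset time as the crossing of a configurable level (default 0, the
#' natural level since per-series minima are mapped to 0). By default the
#' fit uses frames from the first clear rise onward (`fit_window =
#' "rise"`: from the first sample exceeding `rise_level` of the rescaled
#' range); for series that rise throughout -- the regime in which these
#' fits reach R-squared near 1 -- this coincides with the all-frames fit
#' (`fit_window = "all"`).
#'
#' @param data Data frame with the series.
#' @param time,value Columns holding time (min) and the measured quantity
#'   (gradient in Pa/um or turn angle in deg).
#' @param kind Series kind label (`"gradient"` or `"turn_angle"`).
#' @param fit_window `"rise"` (default) or `"all"`.
#' @param rise_level Rescaled level defining the first clear rise.
#' @param crossing Rescaled level whose crossing defines the onset.
#' @param rescale Rescale to `[0, 1]` first (the standard protocol).
#' @return A `kinetics_fit` object with `slope` (1/min), `intercept`,
#'   `r_squared`, `onset_min` and the rescaled data; `onset_min` is `NA`
#'   when the fitted slope is not positive.
#' @export
#' @examples
#' d <- tibble::tibble(t = seq(0, 245, 35), g = pmax(0, (seq(0, 245, 35) - 40) * 0.02))
#' fit <- fit_onset(d, t, g, kind = "gradient")
#' fit$onset_min
fit_onset <- function(data, time, value, kind = c("gradient", "turn_angle"),
                      fit_window = c("rise", "all"), rise_level = 0.1,
                      crossing = 0, rescale = TRUE) {
  kind <- match.arg(kind)
  fit_window <- match.arg(fit_window)
  t <- dplyr::pull(data, {{ time }})
  y_raw <- dplyr::pull(data, {{ value }})
  keep <- is.finite(t) & is.finite(y_raw)
  t <- t[keep]; y_raw <- y_raw[keep]
  if (length(t) < 3) stop_bad("onset fit needs >= 3 finite samples")
  y <- if (rescale) rescale_series(y_raw) else y_raw
  idx <- if (fit_window == "rise") {
    first <- which(y > rise_level)[1]
    if (is.na(first)) seq_along(t) else seq(first, length(t))
  } else seq_along(t)
  if (length(idx) < 2) idx <- seq_along(t)
  line <- ols_line(t[idx], y[idx])
  onset <- if (is.finite(line$slope) && line$slope > 0) {
    (crossing - line$intercept) / line$slope
  } else NA_real_
  structure(list(
    slope = line$slope, intercept = line$intercept,
    r_squared = line$r_squared, onset_min = onset, kind = kind,
    fit_window = fit_window, crossing = crossing,
    data = tibble(t_min = t, value = y_raw, rescaled = y,
                  in_fit = seq_along(t) %in% idx)
  ), class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit: %s> slope %.4g /min, R^2 %.4f, onset %.4g min\n",
              x$kind, x$slope, x$r_squared, x$onset_min))
  invisible(x)
}

#' Tidy a kinetics fit into parameter rows
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return Tibble of `term`/`estimate` rows.
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble(term = c("slope_per_min", "intercept", "onset_min"),
         estimate = c(x$slope, x$intercept, x$onset_min))
}

#' One-row summary of a kinetics fit
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return One-row tibble with slope, intercept, R-squared, onset and kind.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(kind = x$kind, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, onset_min = x$onset_min,
         fit_window = x$fit_window)
}

#' Rescaled series with fitted values
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return The rescaled series tibble with a `.fitted` column.
#' @export
augment.kinetics_fit <- function(x, ...) {
  x$data |> mutate(.fitted = x$intercept + x$slope * .data$t_min)
}

#' Delay between gradient onset and turning onset
#'
#' Subtracts the extrapolated gradient-onset time from the turning-onset
#' time for one animal or scene; positive delays mean the stiffness
#' gradient appeared first.
#'
#' @param gradient_fit,turn_fit `kinetics_fit`s of the two series.
#' @return One-row tibble: `onset_gradient_min`, `onset_turn_min`,
#'   `delay_min`.
#' @export
onset_delay <- function(gradient_fit, turn_fit) {
  stopifnot(inherits(gradient_fit, "kinetics_fit"),
            inherits(turn_fit, "kinetics_fit"))
  og <- gradient_fit$onset_min; ot <- turn_fit$onset_min
  if (!is.finite(og) || !is.finite(ot)) {
    stop_bad("onset undefined (non-positive fitted slope)")
  }
  tibble(onset_gradient_min = og, onset_turn_min = ot, delay_min = ot - og)
}

#' Cohort summary of per-scene onset delays
#'
#' @param delays Tibble of per-scene [onset_delay()] rows.
#' @return One-row tibble with the mean delay, its SEM and n.
#' @export
delay_summary <- function(delays) {
  stopifnot("delay_min" %in% names(delays))
  d <- delays$delay_min
  tibble(mean_delay_min = mean(d),
         sem_delay_min = sd(d) / sqrt(length(d)),
         n = length(d))
}

#' Bin gradient samples into stage windows
#'
#' Averages samples whose timestamps fall inside each stage window;
#' stage-to-minute mappings are experiment-specific and supplied by the
#' caller.
#'
#' @param data Data frame of samples.
#' @param windows Data frame with columns `stage`, `t_start`, `t_end`
#'   (min, half-open `[t_start, t_end)`).
#' @param time,value Columns of `data` holding time and the quantity.
#' @return Tibble with one row per stage: `stage`, `mean_value`, `n`.
#' @export
bin_by_stage <- function(data, windows, time, value) {
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  out <- lapply(seq_len(nrow(windows)), function(w) {
    inside <- t >= windows$t_start[w] & t < windows$t_end[w]
    tibble(stage = windows$stage[w],
           mean_value = if (any(inside)) mean(y[inside]) else NA_real_,
           n = sum(inside))
  })
  list_rbind(out)
}

#' Correlation between stiffness and cell-density gradients
#'
#' Pearson product-moment correlation plus a first-degree fit of paired
#' per-stage gradient values (stiffness gradient in Pa/um against mean
#' cell-density gradient).
#'
#' @param data Data frame of paired bins.
#' @param stiffness,density Columns holding the paired gradients.
#' @return One-row tibble: `pearson_rho`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
#' @examples
#' d <- tibble::tibble(sg = c(0.1, 0.9, 1.8), dg = c(0.0002, 0.0018, 0.0035))
#' gradient_correlation(d, sg, dg)
gradient_correlation <- function(data, stiffness, density) {
  x <- dplyr::pull(data, {{ stiffness }})
  y <- dplyr::pull(data, {{ density }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop_bad("correlation needs >= 3 paired bins")
  line <- ols_line(x, y)
  tibble(pearson_rho = cor(x, y), slope = line$slope,
         intercept = line$intercept, r_squared = line$r_squared,
         n = length(x))
}
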