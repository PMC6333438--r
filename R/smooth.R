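# Orthonormal DCT-II matrix; diagonalises the Neumann (reflective-boundary)
# second-difference operator with eigenvalues 2 - 2 cos((i-1) pi / n).
dct_matrix <- function(n) {
  if (n == 1L) return(matrix(1, 1, 1))
  k <- seq_len(n) - 1
  i <- seq_len(n) - 1
  M <- sqrt(2 / n) * cos(pi * outer(k, 2 * i + 1) / (2 * n))
  M[1, ] <- sqrt(1 / n)
  M
}

# apply matrix M along one axis of a 3-D array
tensor_apply <- function(a, M, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(a, perm)
  dm <- dim(a)
  a <- M %*% matrix(a, nrow = dm[1])
  dim(a) <- dm
  aperm(a, order(perm))
}

dct3 <- function(a, mats) {
  for (ax in seq_along(mats)) a <- tensor_apply(a, mats[[ax]], ax)
  a
}

idct3 <- function(a, mats) {
  for (ax in seq_along(mats)) a <- tensor_apply(a, t(mats[[ax]]), ax)
  a
}

# per-axis Laplacian eigenvalues, scaled by the axis grid step, summed into
# the full eigenvalue field
laplacian_eigenvalues <- function(d, spacing) {
  lam <- lapply(seq_along(d), function(ax) {
    n <- d[ax]
    (2 - 2 * cos((seq_len(n) - 1) * pi / n)) / spacing[ax]^2
  })
  plane <- outer(lam[[1]], rep(1, d[2])) + outer(rep(1, d[1]), lam[[2]])
  full <- array(plane, d)
  for (k in seq_len(d[3])) full[, , k] <- plane + lam[[3]][k]
  full
}

smooth_core <- function(y, w, gamma, mats, tol = 1e-12, maxit = 20000L) {
  full <- all(w == 1)
  if (full) {
    z <- idct3(gamma * dct3(y, mats), mats)
    return(list(z = z, iterations = 1L, converged = TRUE))
  }
  y0 <- y
  mu <- sum(w * y) / sum(w)
  y0[w == 0] <- mu
  z <- y0
  yw <- w * y
  for (it in seq_len(maxit)) {
    z_new <- idct3(gamma * dct3(yw + (1 - w) * z, mats), mats)
    delta <- max(abs(z_new - z))
    z <- z_new
    if (delta <= tol * max(abs(z), 1e-12)) {
      return(list(z = z, iterations = it, converged = TRUE))
    }
  }
  list(z = z, iterations = maxit, converged = FALSE)
}

prep_mask_weights <- function(y, mask, weights) {
  d <- dim(y)
  if (is.null(mask)) mask <- !is.na(y)
  stopifnot(identical(dim(mask), d))
  w <- if (is.null(weights)) array(1, d) else weights
  stopifnot(identical(dim(w), d), all(w >= 0))
  w[!mask] <- 0
  if (all(w == 0)) stop_bad("all entries missing: nothing to smooth")
  y[!mask] <- 0
  list(y = y, w = w, mask = mask)
}

#' Generalized cross-validation score of the DCT smoother
#'
#' GCV score of the penalized-least-squares smooth at parameter `s`:
#' `(RSS / n_obs) / (1 - tr(H)/n)^2`, with the residual sum of squares over
#' observed entries and the trace of the hat matrix summed in the DCT
#' eigenbasis. [select_smoothing_parameter()] minimises this score.
#'
#' @inheritParams dct_pls_smooth
#' @param s Smoothing parameter (single non-negative number).
#' @return The GCV score (single number).
#' @export
gcv_score <- function(y, s, mask = NULL, weights = NULL, spacing = c(1, 1, 1)) {
  y <- as_array3(y)
  p <- prep_mask_weights(y, mask, weights)
  d <- dim(y)
  mats <- lapply(d, dct_matrix)
  gamma <- 1 / (1 + s * laplacian_eigenvalues(d, spacing)^2)
  fit <- smooth_core(p$y, p$w, gamma, mats)
  obs <- p$w > 0
  rss <- sum(p$w[obs] * (p$y[obs] - fit$z[obs])^2)
  n <- prod(d)
  n_obs <- sum(obs)
  tr_h <- sum(gamma)
  (rss / n_obs) / (1 - tr_h / n)^2
}

#' Select the smoothing parameter by GCV
#'
#' Minimises the generalized cross-validation score over a log-spaced
#' search in `[1e-6, 1e6]`, refined by bounded scalar minimisation between
#' the bracketing grid points.
#'
#' @inheritParams dct_pls_smooth
#' @param weights Optional non-negative weight array (missing entries get
#'   weight 0 regardless).
#' @param n_coarse Number of points of the coarse log-spaced scan.
#' @param bounds Search bounds for `s`.
#' @return The selected `s` (single number).
#' @export
select_smoothing_parameter <- function(y, mask = NULL, weights = NULL,
                                       spacing = c(1, 1, 1),
                                       bounds = c(1e-6, 1e6),
                                       n_coarse = 31L) {
  y <- as_array3(y)
  lb <- log10(bounds[1]); ub <- log10(bounds[2])
  grid <- 10^seq(lb, ub, length.out = n_coarse)
  scores <- vapply(grid, function(s) {
    gcv_score(y, s, mask = mask, weights = weights, spacing = spacing)
  }, numeric(1))
  b <- which.min(scores)
  lo <- log10(grid[max(b - 1L, 1L)])
  hi <- log10(grid[min(b + 1L, n_coarse)])
  if (hi > lo) {
    opt <- optimize(function(ls) {
      gcv_score(y, 10^ls, mask = mask, weights = weights, spacing = spacing)
    }, interval = c(lo, hi), tol = 1e-4)
    if (opt$objective <= scores[b]) return(10^opt$minimum)
  }
  grid[b]
}

as_array3 <- function(y) {
  if (is.array(y) && length(dim(y)) == 3L) return(y)
  if (is.matrix(y)) return(array(y, dim = c(dim(y), 1L)))
  if (is.numeric(y)) return(array(y, dim = c(length(y), 1L, 1L)))
  stop_bad("`y` must be a numeric vector, matrix or 3-D array")
}

#' Penalized-least-squares smoothing in the discrete cosine basis
#'
#' Smooths (and imputes) an n-dimensional gridded array by minimising
#' `||W^(1/2)(y - z)||^2 + s ||D z||^2`, where `D` is the second-difference
#' (Laplacian) operator with reflective boundaries. The operator is
#' diagonal in the type-II DCT basis, so the smoother is a spectral filter
#' `1 / (1 + s L^2)`; entries with zero weight (missing nodes) are filled
#' by iterating the filter to its fixed point, which uses the entire array
#' rather than local neighbours. With `robust = TRUE` the fit is
#' iteratively reweighted with bisquare weights on studentised residuals,
#' down-weighting outliers and high-leverage points (intended for display
#' arrays).
#'
#' @param y Numeric 3-D array (vectors and matrices are promoted); `NA`
#'   entries are treated as missing.
#' @param mask Optional logical array, `TRUE` where observed.
#' @param s Smoothing parameter (>= 0) or `"auto"` for GCV selection.
#' @param spacing Grid step per axis; each axis's penalty eigenvalues are
#'   scaled by `1/spacing^2` so physical units are respected.
#' @param weights Optional non-negative weight array.
#' @param robust Iteratively reweight against outliers.
#' @param max_robust_iters Maximum robust reweighting passes.
#' @param tol Relative convergence tolerance of the robust loop.
#' @param bisquare_c Bisquare tuning constant (4.685 keeps ~95% Gaussian
#'   efficiency).
#' @return A `smoothed_series` list: `z` (smoothed array, no missing
#'   entries), `s_selected`, `gcv`, `robust_weights` (or `NULL`),
#'   `n_imputed`, `iterations`, `converged`.
#' @export
#' @examples
#' y <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
#' sm <- dct_pls_smooth(y, s = 1)
#' max(abs(sm$z))
dct_pls_smooth <- function(y, mask = NULL, s = "auto", spacing = c(1, 1, 1),
                           weights = NULL, robust = FALSE,
                           max_robust_iters = 5L, tol = 1e-5,
                           bisquare_c = 4.685) {
  y <- as_array3(y)
  d <- dim(y)
  if (sum(d > 1) < 1) stop_bad("need at least 2 entries along one axis")
  p <- prep_mask_weights(y, mask, weights)
  mats <- lapply(d, dct_matrix)
  lam2 <- laplacian_eigenvalues(d, spacing)^2

  auto <- identical(s, "auto")
  pick_s <- function(w) {
    if (!auto) return(s)
    select_smoothing_parameter(p$y, mask = p$mask & (w > 0),
                               weights = w, spacing = spacing)
  }

  w <- p$w
  s_now <- pick_s(w)
  check_number(s_now, "s", lower = 0)
  gamma <- 1 / (1 + s_now * lam2)
  fit <- smooth_core(p$y, w, gamma, mats)
  rob_w <- NULL
  rob_converged <- TRUE

  if (robust) {
    rob_converged <- FALSE
    z_prev <- fit$z
    for (it in seq_len(max_robust_iters)) {
      r <- p$y - fit$z
      obs <- p$mask
      med <- median(r[obs])
      mad_r <- median(abs(r[obs] - med))
      if (mad_r <= 0) { rob_converged <- TRUE; break }
      h <- min(mean(gamma), 1 - 1e-8)           # average leverage
      u <- abs(r / (1.4826 * mad_r) / sqrt(1 - h))
      bw <- (1 - (u / bisquare_c)^2)^2 * (u < bisquare_c)
      bw[!obs] <- 0
      w <- p$w * bw
      if (all(w == 0)) break
      s_now <- pick_s(w)
      gamma <- 1 / (1 + s_now * lam2)
      fit <- smooth_core(p$y, w, gamma, mats)
      rel <- max(abs(fit$z - z_prev)) / max(abs(fit$z), 1e-12)
      z_prev <- fit$z
      rob_w <- bw
      if (rel < tol) { rob_converged <- TRUE; break }
    }
  }

  obs <- w > 0
  rss <- sum(w[obs] * (p$y[obs] - fit$z[obs])^2)
  gcv <- (rss / sum(obs)) / (1 - sum(gamma) / prod(d))^2
  structure(list(
    z = fit$z, s_selected = s_now, gcv = gcv,
    robust_weights = rob_w, n_imputed = sum(!p$mask),
    iterations = fit$iterations,
    converged = fit$converged && rob_converged
  ), class = "smoothed_series")
}

#' Robust DCT smoothing
#'
#' Convenience wrapper for [dct_pls_smooth()] with `robust = TRUE`.
#'
#' @inheritParams dct_pls_smooth
#' @param ... Passed to [dct_pls_smooth()].
#' @return A `smoothed_series`; see [dct_pls_smooth()].
#' @export
robust_smooth <- function(y, mask = NULL, s = "auto", ...) {
  dct_pls_smooth(y, mask = mask, s = s, robust = TRUE, ...)
}

#' @export
print.smoothed_series <- function(x, ...) {
  cat(sprintf("<smoothed_series> s = %.4g, GCV = %.4g, %d imputed%s\n",
              x$s_selected, x$gcv, x$n_imputed,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' One-row summary of a smoothing fit
#'
#' @param x A `smoothed_series`.
#' @param ... Unused.
#' @return One-row tibble with the selected parameter, GCV score,
#'   imputation count and convergence flag.
#' @export
glance.smoothed_series <- function(x, ...) {
  tibble(s_selected = x$s_selected, gcv = x$gcv, n_imputed = x$n_imputed,
         iterations = x$iterations, converged = x$converged)
}
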