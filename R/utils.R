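# Unit bookkeeping used throughout:
#   force in nN, lengths in um, spring constant in N/m, moduli in Pa.
#   F[nN] = 1e3 * k[N/m] * d[um]               (Hooke)
#   F[nN] = (4/3) * K[Pa] * delta^{3/2} * sqrt(R) * 1e-3   (Hertz, sphere)
NM_PER_UM_FORCE <- 1e3   # nN per (N/m * um)
HERTZ_UNIT <- 1e-3       # nN per (Pa * um^2)

hertz_prefactor <- function(R_um) (4 / 3) * sqrt(R_um) * HERTZ_UNIT

# the 50 um that separates (and sizes) the flanking ROI boxes; also the
# denominator of the gradient statistic (K_R - K_C)/50
ROI_SEPARATION_UM <- 50

#' Hertz force for a spherical indenter
#'
#' Closed-form contact force \eqn{F = (4/3) K \delta^{3/2} \sqrt{R}} for a
#' sphere of radius `R_um` indenting an elastic half-space of reduced
#' apparent modulus `K_Pa` (that is, \eqn{E/(1-\nu^2)}).
#'
#' @param K_Pa Reduced apparent elastic modulus (Pa).
#' @param delta_um Indentation depth (um); negative values give zero force.
#' @param R_um Probe radius (um).
#' @return Force in nN.
#' @export
#' @examples
#' hertz_force(100, 10, 18.64)
hertz_force <- function(K_Pa, delta_um, R_um) {
  hertz_prefactor(R_um) * K_Pa * pmax(delta_um, 0)^1.5
}

stop_bad <- function(msg, ...) abort(sprintf(msg, ...), class = "elastomap_error")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    stop_bad("`%s` must be a finite number in %s%s, %s%s (got %s)",
             name, if (closed_lower) "[" else "(", format(lower),
             format(upper), if (closed_upper) "]" else ")",
             paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x != round(x)) {
    stop_bad("`%s` must be an integer >= %d", name, lower)
  }
  invisible(as.integer(x))
}

# deterministic child seeds below 2^31, derived from one integer seed
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

fmt_num <- function(x, digits = 10) {
  out <- formatC(x, format = "g", digits = digits)
  out[is.na(x)] <- "NA"
  out
}
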