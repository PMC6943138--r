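# Shared numerical helpers.

# Celsius <-> Kelvin
c_to_k <- function(t) t + .T0K
k_to_c <- function(t) t - .T0K

#' Convert folding enthalpy/entropy between kJ and kcal
#'
#' Thermodynamic results are reported in kJ/mol (dH) and kJ/(mol K) (dS) by
#' default; some of the literature uses kcal. 1 kcal = 4.184 kJ.
#'
#' @param x numeric value(s) in kJ-based units.
#' @param to `"kcal"` or `"kJ"` (identity).
#' @return numeric, converted.
#' @export
convert_energy <- function(x, to = c("kcal", "kJ")) {
  to <- match.arg(to)
  if (to == "kJ") x else x / 4.184
}

# Evaluate a linear baseline c(intercept, slope) at temperature t.
eval_baseline <- function(b, t) b[[1]] + b[[2]] * t

# Local least-squares quadratic smoothing / differentiation on a (possibly
# non-uniform) strictly monotone grid. Returns the fitted value or first
# derivative at every point; edge points reuse the nearest full window.
local_quad <- function(x, y, window, deriv = 0) {
  n <- length(x)
  stopifnot(window %% 2 == 1, window >= 3, window < n)
  h <- (window - 1L) %/% 2L
  centers <- pmin(pmax(seq_len(n), h + 1L), n - h)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ci <- centers[i]
    j <- (ci - h):(ci + h)
    xc <- x[j] - x[i]
    X <- cbind(1, xc, xc^2)
    b <- qr.coef(qr(X), y[j])
    out[i] <- if (deriv == 0) b[[1]] else b[[2]]
  }
  out
}

# Parabolic refinement of an extremum: fit a quadratic to (x, y) around index
# i0 (halfwidth hw points) and return the vertex abscissa, falling back to
# x[i0] when the curvature has the wrong sign or the vertex escapes the
# window.
refine_extremum <- function(x, y, i0, hw = 4L, maximum = FALSE) {
  n <- length(x)
  j <- max(1L, i0 - hw):min(n, i0 + hw)
  if (length(j) < 3L) return(x[i0])
  xc <- x[j] - x[i0]
  b <- qr.coef(qr(cbind(1, xc, xc^2)), y[j])
  a2 <- b[[3]]
  ok <- if (maximum) a2 < 0 else a2 > 0
  if (!ok || !is.finite(a2) || a2 == 0) return(x[i0])
  v <- -b[[2]] / (2 * a2)
  if (abs(v) > max(abs(xc))) return(x[i0])
  x[i0] + v
}

# Gaussian band evaluated on a wavelength grid.
gauss_band <- function(lambda, center, width, amplitude) {
  amplitude * exp(-(lambda - center)^2 / (2 * width^2))
}

# Sum a band table (data.frame center/width/amplitude) on a grid.
eval_bands <- function(lambda, bands) {
  out <- numeric(length(lambda))
  for (k in seq_len(nrow(bands))) {
    out <- out + gauss_band(lambda, bands$center[k], bands$width[k],
                            bands$amplitude[k])
  }
  out
}

# stop() with a condition class so callers can test errors by class.
stop_em <- function(class, msg, ...) {
  stop(structure(class = c(class, "epimotif_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

warn_em <- function(class, msg, ...) {
  warning(structure(class = c(class, "epimotif_warning", "warning", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1))))
}
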