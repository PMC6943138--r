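# Lightweight S3 containers for the measured data.

#' UV melting curve container
#'
#' One absorbance-vs-temperature ramp at 295 nm for one oligonucleotide
#' replicate. Temperatures must be strictly monotone within the ramp
#' (increasing for a melt, decreasing for an anneal) and at least 20 points
#' are required.
#'
#' @param temperature_C,absorbance_AU numeric vectors of equal length.
#' @param sequence_id,replicate_id metadata.
#' @param direction `"melt"` or `"anneal"`.
#' @return object of class `melt_curve`: a list with `sequence_id`,
#'   `replicate_id`, `direction` and `data` (data.frame `temperature_C`,
#'   `absorbance_AU`).
#' @export
melt_curve <- function(temperature_C, absorbance_AU, sequence_id = "seq",
                       replicate_id = 1L, direction = c("melt", "anneal")) {
  direction <- match.arg(direction)
  if (length(temperature_C) != length(absorbance_AU))
    stop_em("invalid_curve", "temperature and absorbance lengths differ")
  if (length(temperature_C) < 20)
    stop_em("invalid_curve", "a melting curve needs >= 20 points, got %d",
            length(temperature_C))
  dt <- diff(temperature_C)
  if (!(all(dt > 0) || all(dt < 0)))
    stop_em("invalid_curve", "temperature must be strictly monotone within a ramp")
  if (any(!is.finite(absorbance_AU)))
    stop_em("invalid_curve", "non-finite absorbance values")
  structure(list(sequence_id = sequence_id,
                 replicate_id = replicate_id,
                 direction = direction,
                 data = data.frame(temperature_C = temperature_C,
                                   absorbance_AU = absorbance_AU)),
            class = "melt_curve")
}

#' @export
print.melt_curve <- function(x, ...) {
  d <- x$data
  cat(sprintf("<melt_curve> %s rep %s (%s): %d points, %.1f-%.1f degC\n",
              x$sequence_id, x$replicate_id, x$direction, nrow(d),
              min(d$temperature_C), max(d$temperature_C)))
  invisible(x)
}

#' Spectrum container
#'
#' Ordered (wavelength, signal) pairs with optional temperature/pH metadata.
#' Wavelengths must be strictly increasing and at least 50 points are
#' required (instrument pitch is 0.5 nm over a >= 100 nm range).
#'
#' @param wavelength_nm,signal numeric vectors.
#' @param temperature_C,pH metadata (NA when not applicable).
#' @param blank_subtracted logical flag.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, signal, temperature_C = NA_real_,
                     pH = NA_real_, blank_subtracted = FALSE) {
  if (length(wavelength_nm) != length(signal))
    stop_em("invalid_spectrum", "wavelength and signal lengths differ")
  if (length(wavelength_nm) < 50)
    stop_em("invalid_spectrum", "a spectrum needs >= 50 points")
  if (any(diff(wavelength_nm) <= 0))
    stop_em("invalid_spectrum", "wavelengths must be strictly increasing")
  structure(list(data = data.frame(wavelength_nm = wavelength_nm,
                                   signal = signal),
                 temperature_C = temperature_C, pH = pH,
                 blank_subtracted = isTRUE(blank_subtracted)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  d <- x$data
  cat(sprintf("<spectrum> %d points, %.1f-%.1f nm%s%s%s\n", nrow(d),
              min(d$wavelength_nm), max(d$wavelength_nm),
              if (is.na(x$temperature_C)) "" else sprintf(", %g degC", x$temperature_C),
              if (is.na(x$pH)) "" else sprintf(", pH %.2f", x$pH),
              if (x$blank_subtracted) ", blank-subtracted" else ""))
  invisible(x)
}

#' Titration series container
#'
#' Ellipticity at a fixed wavelength (default 288 nm) across a pH series.
#' Requires at least 6 points spanning at least 1.5 pH units.
#'
#' @param pH,ellipticity_mdeg numeric vectors.
#' @param sequence_id metadata.
#' @param wavelength_nm monitored wavelength.
#' @return object of class `titration_series`.
#' @export
titration_series <- function(pH, ellipticity_mdeg, sequence_id = "seq",
                             wavelength_nm = 288) {
  if (length(pH) != length(ellipticity_mdeg))
    stop_em("invalid_series", "pH and ellipticity lengths differ")
  if (length(pH) < 6)
    stop_em("invalid_series", "a titration needs >= 6 pH points")
  if (diff(range(pH)) < 1.5)
    stop_em("invalid_series", "a titration must span >= 1.5 pH units")
  o <- order(pH)
  structure(list(sequence_id = sequence_id, wavelength_nm = wavelength_nm,
                 data = data.frame(pH = pH[o],
                                   ellipticity_mdeg = ellipticity_mdeg[o])),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  d <- x$data
  cat(sprintf("<titration_series> %s @ %g nm: %d points, pH %.2f-%.2f\n",
              x$sequence_id, x$wavelength_nm, nrow(d), min(d$pH), max(d$pH)))
  invisible(x)
}
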