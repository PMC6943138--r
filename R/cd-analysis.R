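# CD spectra and pH titrations: transitional pH fitting, structural
# classification, and thermal difference spectra.

#' Subtract a buffer blank from a spectrum
#'
#' Pointwise subtraction; the two spectra must be on identical wavelength
#' grids (no implicit interpolation).
#'
#' @param sample,blank [spectrum()] objects.
#' @return the sample spectrum with `blank_subtracted = TRUE`.
#' @export
blank_subtract <- function(sample, blank) {
  stopifnot(inherits(sample, "spectrum"), inherits(blank, "spectrum"))
  if (!isTRUE(all.equal(sample$data$wavelength_nm, blank$data$wavelength_nm)))
    stop_em("grid_mismatch", "sample and blank wavelength grids differ")
  out <- sample
  out$data$signal <- sample$data$signal - blank$data$signal
  out$blank_subtracted <- TRUE
  out
}

#' Extract an ellipticity-vs-pH series from a set of CD spectra
#'
#' Reads the signal at `wavelength_nm` (288 nm by default, the i-motif
#' positive band) from each spectrum, interpolating linearly when the
#' wavelength falls between grid points, and assembles a pH-sorted series.
#' Spectra recorded at duplicate pH values are averaged with a warning.
#'
#' @param spectra list of [spectrum()] objects, each with its `pH` set.
#' @param wavelength_nm monitored wavelength.
#' @param sequence_id label for the resulting series.
#' @return a [titration_series()].
#' @export
extract_titration <- function(spectra, wavelength_nm = 288,
                              sequence_id = "seq") {
  stopifnot(length(spectra) >= 1)
  ph <- vapply(spectra, function(s) s$pH, numeric(1))
  if (any(is.na(ph)))
    stop_em("invalid_params", "every spectrum needs a pH value")
  val <- vapply(spectra, function(s) {
    d <- s$data
    if (wavelength_nm < min(d$wavelength_nm) ||
        wavelength_nm > max(d$wavelength_nm))
      stop_em("insufficient_coverage",
              "spectrum does not cover %g nm", wavelength_nm)
    approx(d$wavelength_nm, d$signal, xout = wavelength_nm)$y
  }, numeric(1))
  if (anyDuplicated(ph)) {
    warn_em("duplicate_ph", "duplicate pH values averaged")
    agg <- tapply(val, ph, mean)
    ph <- as.numeric(names(agg))
    val <- as.numeric(agg)
  }
  titration_series(pH = ph, ellipticity_mdeg = val,
                   sequence_id = sequence_id, wavelength_nm = wavelength_nm)
}

#' Fit the transitional pH of an i-motif titration
#'
#' Fits the Hill-type sigmoid
#' `E(pH) = E_u + (E_f - E_u) / (1 + 10^(h * (pH - pHT)))`
#' by nonlinear least squares (Levenberg-Marquardt). The transitional pH is
#' the inflection point of this model, i.e. the `pHT` parameter itself.
#' Starting values come from the data extremes and the pH at
#' half-amplitude.
#'
#' Errors of class `no_transition` are raised when the fitted dynamic range
#' is below 3x the residual SD (flat or noise-only series). A fitted pHT
#' within half a pH step of the sampled boundary is flagged
#' `"boundary_pHT"` (unreliable extrapolation).
#'
#' @param series a [titration_series()].
#' @return object of class `titration_fit`: list with `pHT`, `hill`,
#'   `plateau_folded`, `plateau_unfolded`, `r2`, `resid_sd`, `flags`.
#' @export
fit_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  d <- series$data
  amp_raw <- diff(range(d$ellipticity_mdeg))
  # starting values: folded plateau at low pH, unfolded at high pH
  n <- nrow(d)
  ef0 <- mean(d$ellipticity_mdeg[seq_len(min(2, n))])
  eu0 <- mean(d$ellipticity_mdeg[seq(max(1, n - 1), n)])
  if (abs(ef0 - eu0) < 1e-12 || amp_raw < 1e-9)
    stop_em("no_transition", "no transition detected (flat series)")
  mid <- (ef0 + eu0) / 2
  pht0 <- d$pH[which.min(abs(d$ellipticity_mdeg - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ellipticity_mdeg ~ Eu + (Ef - Eu) / (1 + 10^(h * (pH - pHT))),
      data = d,
      start = list(Ef = ef0, Eu = eu0, h = 2, pHT = pht0),
      lower = c(Ef = -Inf, Eu = -Inf, h = 1e-3,
                pHT = min(d$pH) - 1),
      upper = c(Ef = Inf, Eu = Inf, h = 50, pHT = max(d$pH) + 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_em("no_transition",
                                "titration fit failed: %s", conditionMessage(e)))
  p <- as.list(coef(fit))
  res <- residuals(fit)
  resid_sd <- sqrt(mean(res^2))
  amplitude <- abs(p$Ef - p$Eu)
  if (amplitude < 3 * max(resid_sd, 1e-8))
    stop_em("no_transition",
            "dynamic range (%.3g) below 3x residual SD (%.3g)",
            amplitude, resid_sd)
  flags <- character()
  step <- median(diff(sort(unique(d$pH))))
  if (p$pHT <= min(d$pH) + step || p$pHT >= max(d$pH) - step)
    flags <- c(flags, "boundary_pHT")
  ss_tot <- sum((d$ellipticity_mdeg - mean(d$ellipticity_mdeg))^2)
  structure(list(pHT = p$pHT, hill = p$h,
                 plateau_folded = p$Ef, plateau_unfolded = p$Eu,
                 r2 = 1 - sum(res^2) / ss_tot,
                 resid_sd = resid_sd, flags = flags),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> pHT = %.3f, hill = %.2f, plateaus %.2f/%.2f mdeg, r2 = %.4f%s\n",
              x$pHT, x$hill, x$plateau_folded, x$plateau_unfolded, x$r2,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

# Default classifier thresholds. Peaks must exceed both 3x the noise SD
# (estimated from the 310-320 nm smoothing residuals) and 40% of the
# largest absolute smoothed signal; the relative term keeps weak residual
# features in partially folded mixtures from being called structure.
cd_thresholds <- function(noise_mult = 3, rel_frac = 0.4,
                          imotif_peak = c(283, 293), imotif_trough = c(250, 260),
                          coil_peak = c(271, 281)) {
  list(noise_mult = noise_mult, rel_frac = rel_frac,
       imotif_peak = imotif_peak, imotif_trough = imotif_trough,
       coil_peak = coil_peak)
}

#' Classify a CD spectrum as i-motif or random coil
#'
#' Applies the canonical CD signatures: an i-motif shows a large positive
#' peak near 288 nm with a negative band near 255 nm; a random coil shows a
#' smaller positive peak near 276 nm without the 255 nm trough. The
#' spectrum is smoothed with a 5-point local quadratic and the global
#' positive maximum located; amplitudes must exceed a threshold combining
#' 3x the 310-320 nm noise SD and 40% of the largest absolute signal.
#' Anything not matching either signature (including partially folded
#' mixtures and empty spectra) is `"indeterminate"`.
#'
#' @param s a blank-subtracted [spectrum()] covering at least 240-320 nm.
#' @param thresholds see `cd_thresholds()` defaults.
#' @return `"i-motif"`, `"unstructured"` or `"indeterminate"` (character),
#'   with attribute `detail`.
#' @export
classify_cd_spectrum <- function(s, thresholds = cd_thresholds()) {
  stopifnot(inherits(s, "spectrum"))
  if (!s$blank_subtracted)
    warn_em("not_blank_subtracted", "spectrum is not blank-subtracted")
  d <- s$data
  if (min(d$wavelength_nm) > 240 || max(d$wavelength_nm) < 320)
    stop_em("insufficient_coverage", "classification needs 240-320 nm coverage")
  sm <- local_quad(d$wavelength_nm, d$signal, 5L, deriv = 0)
  tail_idx <- d$wavelength_nm >= 310 & d$wavelength_nm <= 320
  noise_sd <- sd(d$signal[tail_idx] - sm[tail_idx])
  if (is.na(noise_sd)) noise_sd <- 0
  thr <- max(thresholds$noise_mult * noise_sd,
             thresholds$rel_frac * max(abs(sm)))
  imax <- which.max(sm)
  peak_lambda <- d$wavelength_nm[imax]
  peak_val <- sm[imax]
  tw <- thresholds$imotif_trough
  trough_val <- min(sm[d$wavelength_nm >= tw[1] & d$wavelength_nm <= tw[2]])
  in_win <- function(x, w) x >= w[1] & x <= w[2]
  label <-
    if (peak_val > thr && in_win(peak_lambda, thresholds$imotif_peak) &&
        trough_val < -thr) "i-motif"
    else if (peak_val > thr && in_win(peak_lambda, thresholds$coil_peak) &&
             !(trough_val < -thr)) "unstructured"
    else "indeterminate"
  structure(label, detail = list(peak_lambda = peak_lambda,
                                 peak_value = peak_val,
                                 trough_255 = trough_val,
                                 threshold = thr))
}

#' Compute a normalized thermal difference spectrum
#'
#' TDS = absorbance of the unfolded structure (95 degC) minus that of the
#' folded structure (4 degC) between 220 and 320 nm, normalized so the
#' maximum change in absorption equals +1 exactly.
#'
#' @param folded,unfolded [spectrum()] objects on identical 220-320 nm
#'   grids.
#' @return object of class `tds_spectrum`: list with `data` (data.frame
#'   `wavelength_nm`, `delta_A`) and `normalization_factor` (the raw
#'   maximum difference, AU).
#' @export
compute_tds <- function(folded, unfolded) {
  stopifnot(inherits(folded, "spectrum"), inherits(unfolded, "spectrum"))
  if (!isTRUE(all.equal(folded$data$wavelength_nm, unfolded$data$wavelength_nm)))
    stop_em("grid_mismatch", "folded and unfolded wavelength grids differ")
  wl <- folded$data$wavelength_nm
  if (min(wl) > 220 || max(wl) < 320)
    stop_em("insufficient_coverage", "TDS needs 220-320 nm coverage")
  delta <- unfolded$data$signal - folded$data$signal
  m <- max(delta)
  if (m <= 0)
    stop_em("null_tds", "inverted or null TDS (maximum difference <= 0)")
  structure(list(data = data.frame(wavelength_nm = wl, delta_A = delta / m),
                 normalization_factor = m),
            class = "tds_spectrum")
}

#' Test a TDS for the i-motif signature
#'
#' TRUE iff the normalized TDS has a positive peak in 235-245 nm reaching
#' `pos_min` and a negative trough in 290-300 nm reaching `-neg_min`
#' (thresholds on the normalized scale where the maximum is +1).
#'
#' @param t a [compute_tds()] result.
#' @param pos_min,neg_min amplitude thresholds (defaults 0.5 and 0.2).
#' @param pos_window,neg_window wavelength windows, nm.
#' @return logical, with attribute `detail`.
#' @export
classify_tds <- function(t, pos_min = 0.5, neg_min = 0.2,
                         pos_window = c(235, 245), neg_window = c(290, 300)) {
  stopifnot(inherits(t, "tds_spectrum"))
  d <- t$data
  pos <- max(d$delta_A[d$wavelength_nm >= pos_window[1] &
                         d$wavelength_nm <= pos_window[2]])
  neg <- min(d$delta_A[d$wavelength_nm >= neg_window[1] &
                         d$wavelength_nm <= neg_window[2]])
  structure(pos >= pos_min && neg <= -neg_min,
            detail = list(peak_240 = pos, trough_295 = neg))
}
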