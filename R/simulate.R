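# Synthetic-data generators: melting curves, pH titrations, CD and UV
# absorbance spectra with known ground truth. These emulate the measurement
# protocols (295 nm absorbance ramps recorded every 1 degC between 4 and
# 95 degC; CD titrations in 0.25 pH steps from 5.0 to 8.0) so that every
# downstream estimator can be validated against planted parameters.

#' Two-state melting parameters
#'
#' Parameter set for an intramolecular two-state folding equilibrium
#' monitored by absorbance at 295 nm. The convention is that `dH` (kJ/mol)
#' and the derived dS refer to the *folding* reaction, so `dH < 0` and
#' Ka = theta/(1 - theta) equals 1 at the midpoint: dS = dH / Tm(K).
#'
#' The folded state absorbs more at 295 nm than the unfolded state (the
#' thermal difference spectrum of an i-motif has a negative 295 nm trough),
#' so the folded baseline must lie above the unfolded baseline across the
#' whole ramp.
#'
#' @param dH folding enthalpy change, kJ/mol; must be negative.
#' @param Tm_true midpoint temperature, degC; must lie inside the ramp.
#' @param baseline_folded,baseline_unfolded numeric length-2
#'   `c(intercept_AU, slope_AU_per_degC)` linear baselines.
#' @param noise_sd additive Gaussian noise SD, AU.
#' @param t_min,t_max,t_step temperature grid, degC (default 4-95 every 1).
#' @param seed integer RNG seed used by [simulate_melt_curve()].
#' @return object of class `two_state_params`.
#' @export
two_state_params <- function(dH = -160, Tm_true = 39.7,
                             baseline_folded = c(0.70, -5e-4),
                             baseline_unfolded = c(0.54, -2e-4),
                             noise_sd = 0, t_min = 4, t_max = 95,
                             t_step = 1, seed = 1L) {
  if (!is.numeric(dH) || dH >= 0)
    stop_em("invalid_params", "dH must be negative (folding convention), got %s", dH)
  if (!(t_min < Tm_true && Tm_true < t_max))
    stop_em("invalid_params", "Tm_true must lie inside [t_min, t_max]")
  if (noise_sd < 0) stop_em("invalid_params", "noise_sd must be >= 0")
  if (isTRUE(all.equal(baseline_folded, baseline_unfolded)))
    stop_em("degenerate_baselines", "folded and unfolded baselines are identical")
  tt <- c(t_min, t_max)
  if (any(eval_baseline(baseline_folded, tt) <= eval_baseline(baseline_unfolded, tt)))
    stop_em("invalid_params",
            "folded baseline must lie above unfolded baseline throughout the ramp")
  structure(list(dH = dH, Tm_true = Tm_true,
                 dS = dH / c_to_k(Tm_true),   # kJ/(mol K), theta(Tm) = 1/2
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 noise_sd = noise_sd, t_min = t_min, t_max = t_max,
                 t_step = t_step, seed = as.integer(seed)),
            class = "two_state_params")
}

# Fraction folded of the generating two-state model at temperature t (degC).
two_state_theta <- function(params, t) {
  tk <- c_to_k(t)
  ln_ka <- (-params$dH * 1000 / .R_GAS) / tk + params$dS * 1000 / .R_GAS
  1 / (1 + exp(-ln_ka))   # Ka/(1+Ka), numerically stable
}

#' Simulate a UV melting (or annealing) curve
#'
#' Generates one absorbance-vs-temperature ramp at 295 nm from the two-state
#' model: theta(T) = Ka/(1+Ka) with ln Ka = -dH/(R T) + dS/R, and
#' A(T) = theta * B_folded(T) + (1 - theta) * B_unfolded(T) + noise.
#' Annealing curves only reverse the temperature order; the generator has no
#' kinetic hysteresis (hysteresis scenarios are built by offsetting
#' `Tm_true` between directions).
#'
#' @param params a [two_state_params()] object.
#' @param direction `"melt"` (increasing T) or `"anneal"` (decreasing T).
#' @param sequence_id,replicate_id metadata carried on the curve.
#' @return a [melt_curve()] object.
#' @export
simulate_melt_curve <- function(params, direction = c("melt", "anneal"),
                                sequence_id = "synthetic",
                                replicate_id = 1L) {
  direction <- match.arg(direction)
  stopifnot(inherits(params, "two_state_params"))
  t <- seq(params$t_min, params$t_max, by = params$t_step)
  theta <- two_state_theta(params, t)
  a <- theta * eval_baseline(params$baseline_folded, t) +
    (1 - theta) * eval_baseline(params$baseline_unfolded, t)
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    a <- a + rnorm(length(a), sd = params$noise_sd)
  }
  if (direction == "anneal") {
    t <- rev(t); a <- rev(a)
  }
  melt_curve(temperature_C = t, absorbance_AU = a,
             sequence_id = sequence_id, replicate_id = replicate_id,
             direction = direction)
}

#' pH titration parameters
#'
#' Parameters of the Hill-type sigmoid used to generate CD ellipticity at
#' 288 nm versus pH:
#' `E(pH) = E_u + (E_f - E_u) / (1 + 10^(hill * (pH - pHT_true)))`.
#' The default grid samples pH 5.0 to 8.0 in 0.25-unit increments, matching
#' the titration protocol.
#'
#' @param pHT_true transitional pH (inflection of the sigmoid).
#' @param hill transition steepness; must be positive (folding is
#'   cooperative through hemi-protonated C:C+ pairs).
#' @param plateau_folded,plateau_unfolded low-/high-pH plateaus, mdeg.
#' @param noise_sd additive Gaussian noise, mdeg.
#' @param pH_min,pH_max,pH_step sampling grid.
#' @param seed integer RNG seed.
#' @return object of class `titration_params`.
#' @export
titration_params <- function(pHT_true = 6.0, hill = 2,
                             plateau_folded = 10, plateau_unfolded = 2,
                             noise_sd = 0, pH_min = 5.0, pH_max = 8.0,
                             pH_step = 0.25, seed = 1L) {
  if (hill <= 0) stop_em("invalid_params", "hill must be > 0")
  if (!(pH_min < pHT_true && pHT_true < pH_max))
    stop_em("invalid_params", "pHT_true must lie inside [pH_min, pH_max]")
  if (noise_sd < 0) stop_em("invalid_params", "noise_sd must be >= 0")
  structure(list(pHT_true = pHT_true, hill = hill,
                 plateau_folded = plateau_folded,
                 plateau_unfolded = plateau_unfolded,
                 noise_sd = noise_sd, pH_min = pH_min, pH_max = pH_max,
                 pH_step = pH_step, seed = as.integer(seed)),
            class = "titration_params")
}

#' Simulate a CD pH titration
#'
#' @param params a [titration_params()] object.
#' @param sequence_id metadata label.
#' @param wavelength_nm monitored wavelength (default 288 nm).
#' @return a [titration_series()] object.
#' @export
simulate_titration <- function(params, sequence_id = "synthetic",
                               wavelength_nm = 288) {
  stopifnot(inherits(params, "titration_params"))
  ph <- seq(params$pH_min, params$pH_max, by = params$pH_step)
  e <- params$plateau_unfolded +
    (params$plateau_folded - params$plateau_unfolded) /
    (1 + 10^(params$hill * (ph - params$pHT_true)))
  if (params$noise_sd > 0) {
    set.seed(params$seed)
    e <- e + rnorm(length(e), sd = params$noise_sd)
  }
  titration_series(pH = ph, ellipticity_mdeg = e,
                   sequence_id = sequence_id, wavelength_nm = wavelength_nm)
}

#' Reference CD band bases
#'
#' Gaussian band sets describing the two reference CD states on the
#' 220-320 nm range: the i-motif state has a large positive band near
#' 288 nm and a negative band near 255 nm; the random-coil state has a
#' smaller positive band near 276 nm.
#'
#' @return list with elements `imotif` and `coil`, each a data.frame with
#'   columns `center`, `width`, `amplitude` (nm, nm, mdeg).
#' @export
cd_basis <- function() {
  list(
    imotif = data.frame(center = c(288, 255), width = c(8, 10),
                        amplitude = c(10, -5)),
    coil = data.frame(center = 276, width = 10, amplitude = 6)
  )
}

#' Simulate a CD spectrum as a two-state mixture
#'
#' Linear mixture of the i-motif and random-coil band bases plus additive
#' Gaussian noise, on a 220-320 nm grid (0.5 nm pitch).
#'
#' @param state_mix fraction of i-motif state, in `[0, 1]`.
#' @param basis band basis, see [cd_basis()].
#' @param noise_sd Gaussian noise SD, mdeg.
#' @param seed integer RNG seed (ignored when `noise_sd == 0`).
#' @param lambda wavelength grid, nm.
#' @param pH,temperature_C metadata carried on the spectrum.
#' @return a [spectrum()] object (blank-subtracted).
#' @export
simulate_cd_spectrum <- function(state_mix, basis = cd_basis(), noise_sd = 0,
                                 seed = 1L, lambda = seq(220, 320, by = 0.5),
                                 pH = NA_real_, temperature_C = 20) {
  if (!is.numeric(state_mix) || state_mix < 0 || state_mix > 1)
    stop_em("invalid_params", "state_mix must lie in [0, 1]")
  y <- state_mix * eval_bands(lambda, basis$imotif) +
    (1 - state_mix) * eval_bands(lambda, basis$coil)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  spectrum(wavelength_nm = lambda, signal = y, temperature_C = temperature_C,
           pH = pH, blank_subtracted = TRUE)
}

#' UV absorbance band bases for TDS generation
#'
#' Absorbance spectra (AU) of the folded i-motif and the unfolded coil on
#' 220-320 nm. Subtracting folded (4 degC) from unfolded (95 degC) yields a
#' thermal difference spectrum with the i-motif signature: positive peak
#' near 240 nm and negative trough near 295 nm (the folded structure
#' absorbs more at 295 nm).
#'
#' @return list with band data.frames `folded` and `unfolded`.
#' @export
uv_absorbance_basis <- function() {
  list(
    folded = data.frame(center = c(260, 295), width = c(24, 9),
                        amplitude = c(0.90, 0.13)),
    unfolded = data.frame(center = c(256, 238), width = c(24, 12),
                          amplitude = c(0.90, 0.28))
  )
}

#' Simulate a folded/unfolded absorbance spectrum pair
#'
#' @param basis see [uv_absorbance_basis()].
#' @param noise_sd Gaussian noise SD, AU.
#' @param seed integer RNG seed.
#' @param lambda wavelength grid, nm (220-320 for TDS work).
#' @return list of two [spectrum()] objects, `folded` (4 degC) and
#'   `unfolded` (95 degC).
#' @export
simulate_tds_pair <- function(basis = uv_absorbance_basis(), noise_sd = 0,
                              seed = 1L, lambda = seq(220, 320, by = 0.5)) {
  yf <- eval_bands(lambda, basis$folded)
  yu <- eval_bands(lambda, basis$unfolded)
  if (noise_sd > 0) {
    set.seed(seed)
    yf <- yf + rnorm(length(yf), sd = noise_sd)
    yu <- yu + rnorm(length(yu), sd = noise_sd)
  }
  list(folded = spectrum(lambda, yf, temperature_C = 4, blank_subtracted = TRUE),
       unfolded = spectrum(lambda, yu, temperature_C = 95, blank_subtracted = TRUE))
}
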