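# Van't Hoff analysis of UV melting curves recorded at 295 nm.
#
# Workflow: first-derivative Tm -> linear folded/unfolded baselines fitted on
# the ramp flanks -> fraction folded theta(T) -> ln Ka = ln(theta/(1-theta))
# regressed on 1/T(K) over theta in [0.15, 0.85], giving dH = -slope*R and
# dS = intercept*R for the intramolecular folding reaction (Ka = 1 at Tm, so
# Tm_vH = dH/dS identically).

sorted_curve_data <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  d <- curve$data
  d[order(d$temperature_C), , drop = FALSE]
}

#' Melting temperature by the first-derivative method
#'
#' Locates the extremum of the locally smoothed first derivative of the
#' melting signal. For an i-motif at 295 nm the absorbance falls on
#' unfolding, so the transition is the minimum of dA/dT (equivalently the
#' maximum of the derivative with respect to reciprocal temperature).
#'
#' Two refinements keep the estimate centred on the transition midpoint of
#' a two-state melt: when linear flank baselines can be fitted, the
#' derivative is taken on the fraction folded rather than the raw
#' absorbance (removing the baseline background), and the derivative is
#' taken with respect to 1/T(K), in which a van't Hoff two-state transition
#' is symmetric so its derivative extremum sits exactly at the midpoint
#' (against temperature itself the extremum is shifted low by the 1/T^2
#' factor). The grid extremum is refined by a parabolic vertex fit.
#'
#' A transition is only called when the dA/dT minimum stands out from the
#' flank derivative scatter by more than 5 robust SDs; otherwise (flat or
#' strictly linear ramps) an error of class `no_transition` is raised.
#' When several grid points tie for the extremum the lowest temperature is
#' returned and the result carries a `"multiple_extrema"` flag; if the
#' baseline correction is unavailable the raw-absorbance derivative is used
#' and flagged `"raw_derivative"`.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window odd integer >= 3, derivative smoothing window
#'   (default 7 points, i.e. +/- 3 degC on the standard 1 degC grid).
#' @return Tm in degC, with attribute `flags` (character vector).
#' @export
first_derivative_tm <- function(curve, smooth_window = 7L) {
  d <- sorted_curve_data(curve)
  n <- nrow(d)
  if (smooth_window %% 2 != 1 || smooth_window < 3 || smooth_window >= n)
    stop_em("invalid_params", "smooth_window must be odd, >= 3 and < n points")
  flags <- character()
  # baseline-corrected signal where possible
  th <- tryCatch({
    bl <- suppressWarnings(fit_baselines(curve))
    fraction_unclamped(d, bl)
  }, error = function(e) NULL)
  if (is.null(th)) flags <- c(flags, "raw_derivative")
  y <- if (is.null(th)) d$absorbance_AU else th
  # transition detection on dY/dT: constant for linear ramps, so the flank
  # scatter is a pure noise estimate
  dT <- local_quad(d$temperature_C, y, smooth_window, deriv = 1)
  h <- (smooth_window - 1L) %/% 2L
  interior <- (h + 1L):(n - h)
  di <- dT[interior]
  m <- length(di)
  q <- max(3L, m %/% 4L)
  flank <- c(di[seq_len(q)] - median(di[seq_len(q)]),
             di[(m - q + 1L):m] - median(di[(m - q + 1L):m]))
  scale <- max(mad(flank, center = 0), 1e-8)
  depth <- median(di) - min(di)
  if (!(depth > 5 * scale))
    stop_em("no_transition",
            "no transition detected (derivative has no interior extremum)")
  # location on the reciprocal-temperature derivative (maximum: theta and
  # the 295 nm absorbance both increase with 1/T)
  x <- 1 / c_to_k(d$temperature_C)
  dx <- local_quad(x, y, smooth_window, deriv = 1)
  dxi <- dx[interior]
  maxima <- which(dxi == max(dxi))
  if (length(maxima) > 1) flags <- c(flags, "multiple_extrema")
  i0 <- interior[maxima[1]]
  # vertex window ~ the transition half-width on the default 1 degC grid
  v <- refine_extremum(x, dx, i0, hw = 10L, maximum = TRUE)
  structure(k_to_c(1 / v), flags = flags)
}

# Unclamped fraction folded used internally by the derivative method.
fraction_unclamped <- function(d, baselines) {
  bf <- eval_baseline(baselines$folded, d$temperature_C)
  bu <- eval_baseline(baselines$unfolded, d$temperature_C)
  sep <- bf - bu
  if (any(sep <= 0) || mean(sep) < 5 * (baselines$resid_sd %||% 0))
    stop_em("insufficient_amplitude", "baseline separation too small")
  (d$absorbance_AU - bu) / sep
}

#' Fit linear folded/unfolded baselines
#'
#' Ordinary least-squares lines over the coolest `low_frac` and hottest
#' `high_frac` of the temperature *range*. The cool window is the folded
#' baseline (the folded i-motif absorbs more at 295 nm). A warning of class
#' `baseline_overlap` is raised when either window reaches into the
#' transition (|theta - 0.5| < 0.35 inside a window); identical lines are an
#' error.
#'
#' @param curve a [melt_curve()].
#' @param low_frac,high_frac window fractions of the temperature range
#'   (defaults 0.15/0.15; their sum must stay below 0.6 so the windows
#'   cannot meet across a mid-range transition).
#' @return object of class `baseline_pair`: list with `folded`, `unfolded`
#'   (each `c(intercept, slope)`), `ranges` and `resid_sd` (pooled residual
#'   SD, the curve's noise estimate).
#' @export
fit_baselines <- function(curve, low_frac = 0.15, high_frac = 0.15) {
  if (low_frac + high_frac >= 0.6)
    stop_em("invalid_params", "low_frac + high_frac must be < 0.6")
  d <- sorted_curve_data(curve)
  tr <- range(d$temperature_C)
  lo_max <- tr[1] + low_frac * diff(tr)
  hi_min <- tr[2] - high_frac * diff(tr)
  lo <- d$temperature_C <= lo_max
  hi <- d$temperature_C >= hi_min
  if (sum(lo) < 3 || sum(hi) < 3)
    stop_em("invalid_params", "baseline windows must contain >= 3 points each")
  f_lo <- lm(absorbance_AU ~ temperature_C, data = d[lo, ])
  f_hi <- lm(absorbance_AU ~ temperature_C, data = d[hi, ])
  folded <- unname(coef(f_lo))
  unfolded <- unname(coef(f_hi))
  if (isTRUE(all.equal(folded, unfolded, tolerance = 1e-10)))
    stop_em("degenerate_baselines", "folded and unfolded baselines are identical")
  bp <- structure(list(folded = folded, unfolded = unfolded,
                       ranges = list(folded = c(tr[1], lo_max),
                                     unfolded = c(hi_min, tr[2])),
                       resid_sd = sqrt(mean(c(residuals(f_lo)^2,
                                              residuals(f_hi)^2)))),
                  class = "baseline_pair")
  # transition-overlap check: provisional theta against reference baselines
  # from narrow (10%) outer flanks, which a wide window cannot contaminate
  ref_lo <- d$temperature_C <= tr[1] + min(low_frac, 0.10) * diff(tr)
  ref_hi <- d$temperature_C >= tr[2] - min(high_frac, 0.10) * diff(tr)
  rf <- unname(coef(lm(absorbance_AU ~ temperature_C, data = d[ref_lo, ])))
  ru <- unname(coef(lm(absorbance_AU ~ temperature_C, data = d[ref_hi, ])))
  sep <- eval_baseline(rf, d$temperature_C) - eval_baseline(ru, d$temperature_C)
  if (all(abs(sep) > .Machine$double.eps^0.5)) {
    th <- (d$absorbance_AU - eval_baseline(ru, d$temperature_C)) / sep
    if (any(abs(th[lo | hi] - 0.5) < 0.35))
      warn_em("baseline_overlap",
              "baseline window overlaps the transition region; consider smaller fractions")
  }
  bp
}

#' Convert a melting curve to fraction folded
#'
#' theta(T) = (A(T) - B_unfolded(T)) / (B_folded(T) - B_unfolded(T)),
#' clamped to `[0, 1]`. The number of clamped points is reported in the
#' `n_clamped` attribute. When the baseline separation is smaller than five
#' times the baseline residual SD the transition amplitude is considered
#' indistinguishable from noise and an error of class
#' `insufficient_amplitude` is raised.
#'
#' @param curve a [melt_curve()].
#' @param baselines a [fit_baselines()] result (or any list with `folded`,
#'   `unfolded` and optionally `resid_sd`).
#' @return data.frame with `temperature_C` and `theta`, attributes
#'   `n_clamped`.
#' @export
fraction_folded <- function(curve, baselines) {
  d <- sorted_curve_data(curve)
  bf <- eval_baseline(baselines$folded, d$temperature_C)
  bu <- eval_baseline(baselines$unfolded, d$temperature_C)
  sep <- bf - bu
  noise <- baselines$resid_sd %||% 0
  if (mean(sep) < 5 * noise || any(sep <= 0))
    stop_em("insufficient_amplitude",
            "baseline separation is below 5x the noise estimate")
  theta_raw <- (d$absorbance_AU - bu) / sep
  theta <- pmin(pmax(theta_raw, 0), 1)
  structure(data.frame(temperature_C = d$temperature_C, theta = theta),
            n_clamped = sum(theta_raw < 0 | theta_raw > 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Van't Hoff regression of a fraction-folded series
#'
#' Regresses ln Ka = ln(theta/(1-theta)) on 1/T(K), restricted to theta in
#' `theta_window` (default `[0.15, 0.85]`, where Ka values are most
#' precise). For the folding reaction dH = -slope * R and dS =
#' intercept * R; the van't Hoff melting temperature Tm_vH = dH/dS (in K)
#' is returned in degC and equals the temperature where Ka = 1.
#'
#' @param theta_series data.frame with `temperature_C` and `theta` (e.g.
#'   from [fraction_folded()]).
#' @param theta_window inclusive theta bounds for the regression.
#' @param units `"kJ"` (default) or `"kcal"` for dH/dS.
#' @return object of class `thermo_fit`: list with `dH` (kJ/mol or
#'   kcal/mol), `dS` (same energy unit per mol K), `Tm_vH` (degC), `r2`,
#'   `theta_window`, `n_points_used`, `units`, and `Tm_deriv` (NA here;
#'   filled by [analyze_melt()]).
#' @export
vant_hoff_fit <- function(theta_series, theta_window = c(0.15, 0.85),
                          units = c("kJ", "kcal")) {
  units <- match.arg(units)
  th <- theta_series$theta
  keep <- th >= theta_window[1] & th <= theta_window[2]
  if (sum(keep) < 5)
    stop_em("too_few_points",
            "fewer than 5 points with theta in [%.2f, %.2f]",
            theta_window[1], theta_window[2])
  tk <- c_to_k(theta_series$temperature_C[keep])
  ln_ka <- log(th[keep] / (1 - th[keep]))
  fit <- lm(ln_ka ~ I(1 / tk))
  sl <- unname(coef(fit)[2]); ic <- unname(coef(fit)[1])
  dH <- -sl * .R_GAS / 1000          # kJ/mol
  dS <- ic * .R_GAS / 1000           # kJ/(mol K)
  tm_vh <- k_to_c(dH / dS)
  r2 <- summary(fit)$r.squared
  if (tm_vh < min(theta_series$temperature_C) ||
      tm_vh > max(theta_series$temperature_C))
    warn_em("tm_outside_ramp", "Tm_vH (%.1f degC) falls outside the ramp", tm_vh)
  structure(list(Tm_deriv = NA_real_,
                 dH = convert_energy(dH, units),
                 dS = convert_energy(dS, units),
                 Tm_vH = tm_vh, r2 = r2,
                 theta_window = theta_window,
                 n_points_used = sum(keep),
                 units = units),
            class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf(
    "<thermo_fit> Tm_deriv = %.2f degC, Tm_vH = %.2f degC, dH = %.1f %s/mol, dS = %.4f %s/(mol K), r2 = %.4f (%d pts)\n",
    x$Tm_deriv, x$Tm_vH, x$dH, x$units, x$dS, x$units, x$r2, x$n_points_used))
  invisible(x)
}

#' Full thermodynamic analysis of one melting curve
#'
#' Convenience pipeline: [first_derivative_tm()], [fit_baselines()],
#' [fraction_folded()] and [vant_hoff_fit()].
#'
#' @inheritParams first_derivative_tm
#' @inheritParams fit_baselines
#' @inheritParams vant_hoff_fit
#' @return a `thermo_fit` with `Tm_deriv` filled in.
#' @export
analyze_melt <- function(curve, smooth_window = 7L, low_frac = 0.15,
                         high_frac = 0.15, theta_window = c(0.15, 0.85),
                         units = c("kJ", "kcal")) {
  tm <- first_derivative_tm(curve, smooth_window)
  bl <- fit_baselines(curve, low_frac, high_frac)
  th <- fraction_folded(curve, bl)
  fit <- vant_hoff_fit(th, theta_window, units)
  fit$Tm_deriv <- as.numeric(tm)
  fit
}

#' Replicate statistics for one oligonucleotide
#'
#' Runs [analyze_melt()] on each replicate curve (all curves must share
#' `sequence_id` and `direction`) and reports the arithmetic mean and
#' sample SD of Tm, dH and dS across replicates, the way triplicate melts
#' are reported.
#'
#' @param curves list of at least two [melt_curve()]s.
#' @param ... passed to [analyze_melt()].
#' @return list with `sequence_id`, `direction`, `n_replicates`,
#'   `replicates` (per-replicate data.frame of Tm_deriv, Tm_vH, dH, dS, r2)
#'   and `summary` (data.frame parameter/mean/sd).
#' @export
analyze_replicates <- function(curves, ...) {
  if (!is.list(curves) || length(curves) < 2)
    stop_em("too_few_replicates", "need >= 2 replicate curves")
  ids <- vapply(curves, function(x) x$sequence_id, character(1))
  dirs <- vapply(curves, function(x) x$direction, character(1))
  if (length(unique(ids)) != 1)
    stop_em("mixed_sequences", "curves come from different sequences: %s",
            paste(unique(ids), collapse = ", "))
  if (length(unique(dirs)) != 1)
    stop_em("mixed_directions", "melt and anneal curves cannot be pooled")
  fits <- lapply(curves, analyze_melt, ...)
  reps <- data.frame(
    replicate = vapply(curves, function(x) as.character(x$replicate_id), character(1)),
    Tm_deriv = vapply(fits, `[[`, numeric(1), "Tm_deriv"),
    Tm_vH = vapply(fits, `[[`, numeric(1), "Tm_vH"),
    dH = vapply(fits, `[[`, numeric(1), "dH"),
    dS = vapply(fits, `[[`, numeric(1), "dS"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"))
  pars <- c("Tm_deriv", "Tm_vH", "dH", "dS")
  summ <- data.frame(parameter = pars,
                     mean = vapply(pars, function(p) mean(reps[[p]]), numeric(1)),
                     sd = vapply(pars, function(p) sd(reps[[p]]), numeric(1)),
                     row.names = NULL)
  list(sequence_id = ids[1], direction = dirs[1],
       n_replicates = length(curves), replicates = reps, summary = summ)
}

# Welch two-sided t-test on two replicate vectors, with the degenerate
# zero-variance cases handled explicitly.
welch_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_em("too_few_replicates", "need >= 2 replicates per group")
  flags <- character()
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      flags <- "zero_variance_equal_means"
      return(list(delta = 0, t = 0, df = length(x) + length(y) - 2,
                  p = 1, flags = flags))
    }
    flags <- "zero_variance"
    return(list(delta = mean(x) - mean(y), t = Inf,
                df = length(x) + length(y) - 2, p = NA_real_, flags = flags))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(delta = mean(x) - mean(y), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, flags = flags)
}

#' Compare a modified oligonucleotide to the unmodified control
#'
#' Independent two-sample Welch t-tests (two-sided) on the melting
#' temperature and thermodynamic parameters collected from replicate melts.
#' When both groups have zero variance with equal means the comparison is
#' degenerate and p = 1 is returned with a flag; with unequal means p is NA
#' (flagged `zero_variance`).
#'
#' @param test,control either numeric vectors of one per-replicate
#'   parameter, or per-replicate data.frames as returned in
#'   `analyze_replicates()$replicates` (columns `Tm_deriv`, `dH`, `dS`,
#'   optionally `Tm_vH`).
#' @return object of class `melt_comparison`: data.frame with one row per
#'   parameter and columns `parameter`, `delta` (test mean - control mean),
#'   `t_statistic`, `df`, `p_value`, `flags`.
#' @export
compare_to_control <- function(test, control) {
  if (is.numeric(test) && is.numeric(control)) {
    test <- data.frame(value = test)
    control <- data.frame(value = control)
  }
  pars <- intersect(c("value", "Tm_deriv", "Tm_vH", "dH", "dS"),
                    intersect(names(test), names(control)))
  if (length(pars) == 0)
    stop_em("invalid_params", "no shared parameter columns to compare")
  rows <- lapply(pars, function(p) {
    w <- welch_compare(test[[p]], control[[p]])
    data.frame(parameter = p, delta = w$delta, t_statistic = w$t,
               df = w$df, p_value = w$p,
               flags = paste(w$flags, collapse = ";"))
  })
  structure(do.call(rbind, rows), class = c("melt_comparison", "data.frame"))
}

#' Check for melting/annealing hysteresis
#'
#' Compares the melting temperatures obtained in the heating and cooling
#' directions; a difference beyond `tolerance` indicates the transition is
#' not at equilibrium at the scan rate used.
#'
#' @param melt,anneal `thermo_fit` objects or numeric Tm values (degC).
#' @param tolerance degC (default 1.0).
#' @return list with `delta_Tm` (melt - anneal, degC), `hysteresis`
#'   (logical) and `tolerance`.
#' @export
hysteresis_check <- function(melt, anneal, tolerance = 1.0) {
  tm_of <- function(x) {
    if (inherits(x, "thermo_fit"))
      (if (is.na(x$Tm_deriv)) x$Tm_vH else x$Tm_deriv)
    else as.numeric(x)
  }
  d <- tm_of(melt) - tm_of(anneal)
  list(delta_Tm = d, hysteresis = abs(d) > tolerance, tolerance = tolerance)
}
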