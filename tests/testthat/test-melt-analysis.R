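# Van't Hoff melting analysis: derivative Tm, baselines, fraction folded,
# regression, replicate statistics and control comparisons.

test_that("first-derivative Tm recovers the midpoint of noiseless two-state melts", {
  for (p in list(flat_params(), control_params(),
                 control_params(dH = -200, Tm_true = 50))) {
    tm <- first_derivative_tm(simulate_melt_curve(p))
    expect_lt(abs(as.numeric(tm) - p$Tm_true), 0.5)
  }
})

test_that("strictly linear and flat ramps raise no_transition", {
  lin <- melt_curve(4:95, 0.7 - 5e-4 * (4:95))
  expect_error(first_derivative_tm(lin), class = "no_transition")
  set.seed(301)
  noisy_flat <- melt_curve(4:95, 0.6 + rnorm(92, sd = 0.002))
  expect_error(first_derivative_tm(noisy_flat), class = "no_transition")
  expect_error(first_derivative_tm(simulate_melt_curve(flat_params()),
                                   smooth_window = 4),
               class = "invalid_params")
})

test_that("Tm recovery over noisy replicates is accurate and unbiased", {
  errs <- vapply(1:100, function(s) {
    p <- control_params(noise_sd = 0.002, seed = s)
    as.numeric(first_derivative_tm(simulate_melt_curve(p))) - p$Tm_true
  }, numeric(1))
  expect_lte(mean(abs(errs)), 0.5)
  expect_lte(abs(mean(errs)), 0.2)
})

test_that("baseline fitting recovers the generating lines on noiseless data", {
  p <- control_params()
  bl <- fit_baselines(simulate_melt_curve(p))
  expect_equal(bl$folded[2], -5e-4, tolerance = 0.01)
  expect_equal(bl$unfolded[2], -2e-4, tolerance = 0.01)
  expect_equal(bl$folded[1], 0.70, tolerance = 0.01)
  expect_equal(bl$unfolded[1], 0.54, tolerance = 0.01)
  # flat baselines come back flat
  blf <- fit_baselines(simulate_melt_curve(flat_params()))
  expect_lt(abs(blf$folded[2]), 1e-4)
  expect_lt(abs(blf$unfolded[2]), 1e-4)
})

test_that("wide baseline windows that reach the transition are flagged", {
  cv <- simulate_melt_curve(control_params(Tm_true = 45))
  expect_warning(fit_baselines(cv, 0.37, 0.15), class = "baseline_overlap")
  expect_error(fit_baselines(cv, 0.4, 0.4), class = "invalid_params")
})

test_that("fraction folded maps baselines to 1/0.5 and clamps noise excursions", {
  p <- control_params()
  cv <- simulate_melt_curve(p)
  th <- true_theta(p, cv)
  # coolest point sits on the folded baseline (theta -> 1)
  expect_equal(th$theta[1], 1, tolerance = 1e-3)
  # the transition passes theta = 0.5 at Tm
  expect_equal(approx(th$temperature_C, th$theta, xout = p$Tm_true)$y, 0.5,
               tolerance = 1e-3)
  expect_true(all(th$theta >= 0 & th$theta <= 1))
  # noise pushes points above the folded baseline; they are clamped and counted
  pn <- control_params(noise_sd = 0.002, seed = 5)
  thn <- true_theta(pn, simulate_melt_curve(pn))
  expect_gt(attr(thn, "n_clamped"), 0)
  expect_true(all(thn$theta <= 1))
  # vanishing amplitude is refused
  tiny <- list(folded = c(0.6001, 0), unfolded = c(0.6, 0), resid_sd = 0.01)
  expect_error(fraction_folded(cv, tiny), class = "insufficient_amplitude")
})

test_that("van't Hoff regression inverts the generating model exactly", {
  p <- control_params()
  vf <- vant_hoff_fit(true_theta(p))
  expect_equal(vf$dH, -160, tolerance = 1e-3 / 160)        # 0.1%
  expect_equal(vf$dS, -160 / (39.7 + 273.15), tolerance = 1e-6)
  expect_equal(vf$Tm_vH, 39.7, tolerance = 0.1)
  expect_gt(vf$r2, 0.999999)
  # identity Tm_vH = dH/dS holds by construction
  expect_equal(vf$Tm_vH, vf$dH / vf$dS - 273.15, tolerance = 1e-12)
  # kcal output is a pure unit change
  vk <- vant_hoff_fit(true_theta(p), units = "kcal")
  expect_equal(vk$dH * 4.184, vf$dH, tolerance = 1e-9)
})

test_that("theta window restricts the regression and a theta=0.5 point gives ln Ka = 0", {
  p <- control_params()
  th <- true_theta(p)
  vf <- vant_hoff_fit(th)
  expect_identical(vf$n_points_used,
                   sum(th$theta >= 0.15 & th$theta <= 0.85))
  # ln Ka at theta = 0.5 is exactly 0
  expect_identical(log(0.5 / (1 - 0.5)), 0)
  # too few in-window points raises an informative error
  sparse <- th[seq(1, nrow(th), by = 30), ]
  expect_error(vant_hoff_fit(sparse), class = "too_few_points")
  expect_error(vant_hoff_fit(sparse), "0.15")
})

test_that("window exclusion does not shift noiseless estimates", {
  p <- control_params()
  th <- true_theta(p)
  narrow <- vant_hoff_fit(th, theta_window = c(0.15, 0.85))
  wide <- vant_hoff_fit(th, theta_window = c(0.02, 0.98))
  expect_equal(narrow$dH, wide$dH, tolerance = 1e-9)
  expect_equal(narrow$Tm_vH, wide$Tm_vH, tolerance = 1e-9)
})

test_that("estimates are invariant to adding a common linear ramp", {
  p <- control_params()
  cv <- simulate_melt_curve(p)
  shift <- function(curve, a, b) {
    melt_curve(curve$data$temperature_C,
               curve$data$absorbance_AU + a + b * curve$data$temperature_C,
               sequence_id = curve$sequence_id, direction = curve$direction)
  }
  f1 <- analyze_melt(cv)
  f2 <- analyze_melt(shift(cv, 0.2, 1e-4))
  expect_equal(f1$Tm_deriv, f2$Tm_deriv, tolerance = 1e-6)
  expect_equal(f1$dH, f2$dH, tolerance = 1e-6)
  expect_equal(f1$dS, f2$dS, tolerance = 1e-6)
})

test_that("noisy dH recovery stays within 10% median relative error", {
  rel <- vapply(1:100, function(s) {
    p <- control_params(noise_sd = 0.002, seed = s)
    f <- analyze_melt(simulate_melt_curve(p))
    abs((f$dH + 160) / 160)
  }, numeric(1))
  expect_lte(median(rel), 0.10)
})

test_that("derivative and van't Hoff Tm agree on noiseless two-state data", {
  f <- analyze_melt(simulate_melt_curve(control_params()))
  expect_lt(abs(f$Tm_vH - f$Tm_deriv), 1)
})

test_that("replicate statistics are arithmetic mean and sample SD", {
  p <- control_params()
  curves <- lapply(1:3, function(r)
    simulate_melt_curve(control_params(noise_sd = 0.002, seed = r),
                        replicate_id = r))
  res <- analyze_replicates(curves)
  expect_identical(res$n_replicates, 3L)
  tm_row <- res$summary[res$summary$parameter == "Tm_deriv", ]
  expect_equal(tm_row$mean, mean(res$replicates$Tm_deriv))
  expect_equal(tm_row$sd, sd(res$replicates$Tm_deriv))
  # identical replicates have zero SD
  same <- lapply(1:2, function(r) simulate_melt_curve(p, replicate_id = r))
  expect_equal(analyze_replicates(same)$summary$sd, rep(0, 4))
  # contract violations
  expect_error(analyze_replicates(curves[1]), class = "too_few_replicates")
  mixed <- list(simulate_melt_curve(p, "melt"), simulate_melt_curve(p, "anneal"))
  expect_error(analyze_replicates(mixed), class = "mixed_directions")
  diffid <- list(simulate_melt_curve(p, sequence_id = "a"),
                 simulate_melt_curve(p, sequence_id = "b"))
  expect_error(analyze_replicates(diffid), class = "mixed_sequences")
})

test_that("control comparison matches the Welch t computed from first principles", {
  x <- c(39.6, 39.7, 39.8); y <- c(35.0, 35.2, 34.8)
  # independent oracle: Welch's statistic written out by hand
  se2 <- var(x) / 3 + var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  cmp <- compare_to_control(x, y)
  expect_equal(cmp$delta, 4.7, tolerance = 1e-12)
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-9)
  expect_equal(cmp$df, df_hand, tolerance = 1e-9)
  expect_equal(cmp$p_value, p_hand, tolerance = 1e-9)
  expect_lt(cmp$p_value, 0.001)
})

test_that("degenerate control comparisons are flagged", {
  same <- c(39.7, 39.7, 39.7)
  cmp <- compare_to_control(same, same)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
  expect_match(cmp$flags, "zero_variance")
  # identical groups with variance: delta 0, p = 1
  g <- c(39.6, 39.7, 39.8)
  cmp2 <- compare_to_control(g, g)
  expect_equal(cmp2$delta, 0)
  expect_equal(cmp2$p_value, 1, tolerance = 1e-12)
  # data.frame interface compares each parameter
  reps <- data.frame(Tm_deriv = g, dH = c(-160, -161, -159))
  cmp3 <- compare_to_control(reps, reps)
  expect_setequal(cmp3$parameter, c("Tm_deriv", "dH"))
})

test_that("hysteresis check responds to a planted Tm offset", {
  tm_m <- first_derivative_tm(simulate_melt_curve(control_params()))
  tm_a <- first_derivative_tm(
    simulate_melt_curve(control_params(Tm_true = 36.7), "anneal"))
  h0 <- hysteresis_check(tm_m, tm_m)
  expect_false(h0$hysteresis)
  expect_equal(h0$delta_Tm, 0)
  h3 <- hysteresis_check(tm_m, tm_a)
  expect_true(h3$hysteresis)
  expect_equal(h3$delta_Tm, 3, tolerance = 0.5)
  expect_false(hysteresis_check(tm_m, tm_a, tolerance = 5)$hysteresis)
})
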