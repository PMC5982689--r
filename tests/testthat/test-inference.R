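# inverse stage: stiffness from shift, modulus estimation, classification

test_that("stiffness-from-shift inverts the lumped frequency relation", {
  expect_equal(estimate_stiffness_from_shift(463, 463, ref_J_b), 0)
  k <- estimate_stiffness_from_shift(600, 463, ref_J_b)
  expect_equal(k, (2 * pi * 600)^2 * ref_J_b - (2 * pi * 463)^2 * ref_J_b)
  # quadratic in frequency: doubling both frequencies quadruples it
  expect_rel_equal(estimate_stiffness_from_shift(1200, 926, ref_J_b),
                   4 * k, 1e-12)
  expect_error(estimate_stiffness_from_shift(400, 463, ref_J_b), "soften")
  # round trip through the forward frequency relation
  f_loaded <- resonant_frequency(49557e-12 + 6e-8, ref_J_b)
  f_free <- resonant_frequency(49557e-12, ref_J_b)
  expect_rel_equal(estimate_stiffness_from_shift(f_loaded, f_free, ref_J_b),
                   6e-8, 1e-10)
})

test_that("noiseless round trips recover each reference cell within 5%", {
  for (nm in c("cell_BHP", "cell_PC3", "cell_LNCaP")) {
    scn <- scenario_preset(nm)
    m <- make_synthetic_measurement(scn, noise_sd = 0)
    fit <- estimate_modulus(m, scn, bootstrap = 0)
    for (method in c("frequency_shift", "torque_balance")) {
      E_hat <- fit$estimates[[method]]$E_hat
      expect_lt(abs(E_hat / scn$cell$E_c - 1), 0.05)
    }
    # forward alpha_a is recovered as the cell stiffness
    alpha_a <- assemble_motion_equation(scn)$fit$alpha_a
    expect_lt(abs(fit$k_zc_hat / alpha_a - 1), 0.05)
    # classification of self-simulated presets is exact
    expect_identical(fit$classification$label, scn$cell$label)
    expect_false(fit$flagged)
  }
})

test_that("recovery holds across the full modulus working range", {
  scn <- scenario_preset("cell_BHP")
  scn$solver <- solver_settings(freq_min = 350, freq_max = 1200,
                               freq_points = 1701)
  for (E in c(100, 500, 2000, 10000)) {
    scn$cell <- cell_model(E_c = E, v = 0.5, R = 10e-6, label = "sweep")
    m <- make_synthetic_measurement(scn, noise_sd = 0)
    fit <- estimate_modulus(m, scn, bootstrap = 0)
    expect_lt(abs(fit$E_hat / E - 1), 0.05)
    expect_lt(abs(fit$estimates$torque_balance$E_hat / E - 1), 0.05)
  }
})

test_that("estimator bias vanishes as measurement noise shrinks", {
  scn <- scenario_preset("cell_PC3")
  scn$solver <- solver_settings(freq_min = 450, freq_max = 720,
                               freq_points = 801)
  clean <- make_synthetic_measurement(scn, noise_sd = 0)
  bias <- vapply(c(0.02, 0.01, 0.002), function(ns) {
    E_hat <- vapply(1:25, function(i) {
      set.seed(7000 + i)
      m <- clean
      m$amplitude_rad <- m$amplitude_rad * (1 + rnorm(nrow(m), 0, ns))
      estimate_modulus(m, scn, bootstrap = 0)$E_hat
    }, numeric(1))
    abs(mean(E_hat) / scn$cell$E_c - 1)
  }, numeric(1))
  expect_lt(bias[3], 0.01)          # near-noiseless: sub-percent bias
  expect_true(all(bias < 0.03))     # bounded at the noisiest level
})

test_that("bootstrap intervals cover the true modulus", {
  scn <- scenario_preset("cell_BHP")
  scn$solver <- solver_settings(freq_min = 550, freq_max = 800,
                               freq_points = 601)
  clean <- make_synthetic_measurement(scn, noise_sd = 0)
  n_trials <- 200L
  covered <- 0L
  for (i in seq_len(n_trials)) {
    set.seed(20000 + i)
    m <- clean
    m$amplitude_rad <- m$amplitude_rad * (1 + rnorm(nrow(m), 0, 0.01))
    fit <- estimate_modulus(m, scn, bootstrap = 50L, seed = i)
    if (!is.null(fit$ci) && fit$ci[1] <= 2797 && 2797 <= fit$ci[2]) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / n_trials, 0.90)
})

test_that("a cell-free response is flagged below resolution", {
  scn <- scenario_preset("paper_default")
  scn$solver <- solver_settings(freq_min = 380, freq_max = 560,
                               freq_points = 601)
  m <- make_synthetic_measurement(scn, noise_sd = 0)
  fit <- estimate_modulus(m, scn, bootstrap = 0)
  expect_true(fit$flagged)
  expect_null(fit$classification)
  expect_lt(fit$E_hat, 1)
})

test_that("classification assigns reference moduli to their own class", {
  cl <- classify_cell(2797)
  expect_identical(cl$label, "BHP")
  expect_equal(unname(cl$z_scores["BHP"]), 0)
  expect_identical(classify_cell(287)$label, "LNCaP")
  expect_identical(classify_cell(1401)$label, "PC-3")
  # equidistant tie breaks towards the stiffer class, with a warning
  refs <- data.frame(label = c("soft", "stiff"),
                     E_mean = c(1000, 3000), E_sd = c(100, 100))
  expect_warning(cl <- classify_cell(2000, refs), "stiffer")
  expect_identical(cl$label, "stiff")
})

test_that("modulus_fit behaves like a fitted-model object", {
  scn <- scenario_preset("cell_LNCaP")
  scn$solver <- solver_settings(freq_min = 400, freq_max = 600,
                               freq_points = 601)
  m <- make_synthetic_measurement(scn, noise_sd = 0.005, seed = 3)
  fit <- estimate_modulus(m, scn, bootstrap = 30L, seed = 3)
  expect_s3_class(fit, "modulus_fit")
  expect_named(coef(fit), c("E_hat", "k_zc_hat"))
  ci <- confint(fit, level = 0.9)
  expect_true(ci[1] < fit$E_hat && fit$E_hat < ci[2])
  expect_output(print(fit), "E_hat")
  expect_output(summary(fit), "frequency_shift")
  pred <- predict(fit)
  expect_identical(nrow(pred), nrow(m))
  # the model curve at the estimate tracks the measurement near the peak
  i <- which.max(m$amplitude_rad)
  win <- max(1, i - 20):min(nrow(m), i + 20)
  expect_lt(median(abs(pred$amplitude_rad[win] / m$amplitude_rad[win] - 1)),
            0.05)
})
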