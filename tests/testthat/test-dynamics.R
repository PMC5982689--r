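# Duffing dynamics: Ritz response, resonant frequency, quality factor,
# time-domain oracle

test_that("lumped resonant frequency reproduces the reference device value", {
  f <- resonant_frequency(49557e-12, ref_J_b)
  expect_lt(abs(f / 463.8 - 1), 0.005)       # printed device frequency
  expect_rel_equal(resonant_frequency(4 * 49557e-12, ref_J_b), 2 * f, 1e-12)
  # with a gripped cell the linearized cell stiffness adds to the suspension
  kzc <- 5e-8
  expect_equal(resonant_frequency(49557e-12 + kzc, ref_J_b),
               sqrt((49557e-12 + kzc) / ref_J_b) / (2 * pi))
})

test_that("the linear-limit Ritz response equals the closed form to 12 digits", {
  p <- make_params(alpha_b = 0)
  w <- 2 * pi * seq(300, 700, length.out = 401)
  resp <- ritz_response(p, w)
  expect_equal(nrow(resp), length(w))
  closed <- p$B / sqrt((p$k_lin - p$J_b * w^2)^2 + (p$c_amT * w)^2)
  expect_rel_equal(resp$c1, closed, 1e-12)
  expect_true(all(resp$stable))
  # phase runs 0 -> pi through resonance
  expect_true(all(diff(resp$psi) > 0))
  expect_lt(resp$psi[1], pi / 2)
  expect_gt(resp$psi[length(w)], pi / 2)
})

test_that("hardening shifts the peak up with drive and folds the branch", {
  f <- seq(400, 900, length.out = 2001)
  peaks <- vapply(c(0.5, 1, 2, 4) * 2e-13, function(B) {
    p <- make_params(alpha_b = 0.05, B = B)
    response_peak(ritz_response(p, 2 * pi * f))$f_peak
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))

  # strong nonlinearity: branch counts go 1 -> 3 -> 1 across the fold
  p <- make_params(alpha_b = 0.5, B = 4e-13)
  resp <- ritz_response(p, 2 * pi * f)
  counts <- tapply(resp$branch, resp$omega, length)
  expect_identical(sort(unique(as.integer(counts))), c(1L, 3L))
  r <- rle(as.integer(counts))
  expect_identical(r$values, c(1L, 3L, 1L))
  # intermediate branch flagged unstable
  triple <- resp[resp$omega == resp$omega[which(resp$branch == 3)[1]], ]
  expect_identical(triple$stable, c(TRUE, FALSE, TRUE))
})

test_that("peak amplitude respects the damping-limited resonance bound", {
  for (alpha_b in c(0, 0.02)) {
    p <- make_params(alpha_b = alpha_b, B = 3e-13)
    resp <- ritz_response(p, 2 * pi * seq(380, 620, length.out = 2001))
    pk <- response_peak(resp)
    bound <- p$B / (p$c_amT * 2 * pi * pk$f_peak)
    expect_lt(pk$c_peak, bound * 1.01)
    expect_gt(pk$c_peak, bound * 0.9)
  }
})

test_that("quality factor matches the closed-form linear value", {
  p <- make_params()
  f <- seq(380, 560, length.out = 2001)
  Q <- quality_factor(ritz_response(p, 2 * pi * f))
  expect_lt(abs(Q / (sqrt(p$J_b * p$k_lin) / p$c_amT) - 1), 0.01)
  # peak at the grid edge is refused, not silently extrapolated
  expect_error(response_peak(ritz_response(p, 2 * pi * seq(480, 560, 10))),
               "grid")
})

test_that("Ritz steady state matches time integration for weak nonlinearity", {
  scn <- scenario_preset("cell_BHP")
  p <- assemble_motion_equation(scn)
  f_n <- p$f_n
  for (f in c(0.97, 1.0, 1.01) * f_n) {
    ritz <- ritz_response(p, 2 * pi * f)
    c_ritz <- max(ritz$c1[ritz$stable])
    sim <- time_integrate(p, 2 * pi * f, periods = 220L,
                          samples_per_period = 48L)
    expect_lt(abs(sim$amplitude / c_ritz - 1), 0.02)
  }
})

test_that("free ringdown decays at c/(2J) and rings at the lumped frequency", {
  p <- make_params(B = 0)
  w_n <- 2 * pi * p$f_n
  sim <- time_integrate(p, w_n, periods = 60L, samples_per_period = 64L,
                        theta0 = 1e-4)
  traj <- sim$trajectory
  Tp <- 2 * pi / w_n
  # rms amplitude per period decays as exp(-lambda t), lambda = c/(2J)
  per <- floor(traj$t / Tp)
  keep <- per >= 2 & per <= 50
  rms <- tapply(traj$theta[keep], per[keep], function(x) sqrt(mean(x^2)))
  tmid <- tapply(traj$t[keep], per[keep], mean)
  lambda_hat <- -coef(lm(log(rms) ~ tmid))[2]
  expect_lt(abs(lambda_hat / (p$c_amT / (2 * p$J_b)) - 1), 0.01)
  # ringdown frequency vs the lumped formula, from zero crossings
  s <- sign(traj$theta[keep])
  n_cross <- sum(abs(diff(s)) == 2)
  f_hat <- n_cross / 2 / (max(traj$t[keep]) - min(traj$t[keep]))
  expect_lt(abs(f_hat / p$f_n - 1), 0.005)
})

test_that("undriven undamped motion conserves energy", {
  p <- make_params(B = 0, c_amT = 0, alpha_b = 0.05)
  sim <- time_integrate(p, 2 * pi * p$f_n, periods = 30L,
                        samples_per_period = 64L, theta0 = 5e-4)
  traj <- sim$trajectory
  En <- 0.5 * p$J_b * traj$theta_dot^2 + 0.5 * p$k_lin * traj$theta^2 +
    0.25 * p$alpha_b * traj$theta^4
  expect_lt(diff(range(En)) / En[1], 1e-6)
})

test_that("drive work equals dissipation per steady cycle in the oracle", {
  p <- make_params(alpha_b = 0.01, B = 2e-13)
  w <- 2 * pi * p$f_n
  sim <- time_integrate(p, w, periods = 240L, samples_per_period = 64L)
  traj <- sim$trajectory
  Tp <- 2 * pi / w
  last <- traj$t >= 239 * Tp - 1e-12
  tt <- traj$t[last]; td <- traj$theta_dot[last]
  dt <- tt[2] - tt[1]
  trap <- function(x) (sum(x) - (x[1] + x[length(x)]) / 2) * dt
  W_drive <- trap(p$B * sin(w * tt) * td)
  W_diss <- trap(p$c_amT * td^2)
  expect_lt(abs(W_drive / W_diss - 1), 0.005)
})

test_that("peak frequency and quality factor rise with the gripped modulus", {
  stats <- lapply(c("cell_LNCaP", "cell_PC3", "cell_BHP"), function(nm) {
    resp <- sweep_response(scenario_preset(nm))
    c(f = response_peak(resp)$f_peak, Q = quality_factor(resp))
  })
  f <- vapply(stats, `[[`, numeric(1), "f")
  Q <- vapply(stats, `[[`, numeric(1), "Q")
  expect_true(all(diff(f) > 0))
  expect_true(all(diff(Q) > 0))
})
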