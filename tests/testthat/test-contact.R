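# Hertzian large-deformation cell contact and the cubic torque reduction

bhp <- function() cell_model(E_c = 2797, v = 0.5, R = 10e-6, label = "BHP")
kin <- function() kinematics_model()

test_that("contact radius follows the chord geometry", {
  cell <- bhp()
  expect_equal(contact_radius(cell, 0), 0)
  expect_equal(contact_radius(cell, cell$R), cell$R)   # hemispherical limit
  # 20% radial compression of a 10 um cell: a = sqrt(40 - 4) = 6 um
  expect_equal(contact_radius(cell, 2e-6), 6e-6)
  expect_error(contact_radius(cell, 11e-6), "delta_r")
  # concave increasing, bounded by R
  d <- seq(0, cell$R, length.out = 200)
  a <- contact_radius(cell, d)
  expect_true(all(a <= cell$R + 1e-18))
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(diff(a)) < 1e-12))
})

test_that("resistive force is zero at contact, increasing, linear in modulus", {
  cell <- bhp()
  expect_equal(resistive_force(cell, 0), 0)
  d <- seq(1e-9, 0.5 * cell$R, length.out = 500)
  F <- resistive_force(cell, d)
  expect_true(all(F > 0))
  expect_true(all(diff(F) > 0))   # monotone on (0, 0.5R)
  stiff <- cell_model(E_c = 2 * cell$E_c, v = cell$v, R = cell$R)
  expect_equal(resistive_force(stiff, d), 2 * F)
  expect_error(resistive_force(cell, 0.7 * cell$R), "validity cap")
})

test_that("the small-compression limit recovers the Hertz power law", {
  # frozen regression of the documented contact normalisation: for
  # delta < 0.05 R the force follows E sqrt(R) delta^(3/2) / (1 - v^2)
  cell <- bhp()
  d <- cell$R * 10^seq(-3, log10(0.05), length.out = 40)
  F <- resistive_force(cell, d)
  slope <- coef(lm(log(F) ~ log(d)))[2]
  expect_lt(abs(slope - 1.5), 0.02)
  # prefactor: (4 sqrt(2) / 3) E sqrt(R) / (1 - v^2), the chord-radius
  # analogue of the Hertz coefficient
  pref <- F / (cell$E_c / (1 - cell$v^2) * sqrt(cell$R) * d^1.5)
  expect_lt(max(abs(pref - 4 * sqrt(2) / 3)), 0.06)
  # the collapse F (1 - v^2) / E is invariant across cells
  soft <- cell_model(E_c = 287, v = 0.5, R = cell$R)
  expect_equal(resistive_force(soft, d) / 287,
               F / 2797, tolerance = 1e-12)
})

test_that("resistive torque is superlinear over the squeezing range", {
  cell <- bhp()
  expect_equal(resistive_torque(cell, 0, kin()), 0)
  th <- seq(0, 0.0016, length.out = 100)   # 20% compression at the default lever
  Tc <- resistive_torque(cell, th, kin())
  expect_true(all(diff(Tc) > 0))
  expect_true(all(diff(diff(Tc)) > 0))  # convex over the squeezing range
  # superlinear: secant slope grows
  sec <- Tc[-1] / th[-1]
  expect_true(all(diff(sec) > 0))
  # pointwise linear in the modulus
  soft <- cell_model(E_c = 287, v = 0.5, R = cell$R)
  expect_equal(resistive_torque(soft, th, kin()),
               Tc * 287 / 2797, tolerance = 1e-12)
  expect_error(resistive_torque(cell, 0.01, kin()), "validity cap")
})

test_that("cubic reduction recovers an exact odd cubic to 10 digits", {
  fit <- fit_cubic_torque(bhp(), kin(), theta_max = 0.0016,
                          torque_fn = function(th) 3 * th + 5 * th^3)
  expect_rel_equal(fit$alpha_a, 3, 1e-10)
  expect_rel_equal(fit$alpha_b, 5, 1e-10)
  expect_lt(fit$residual, 1e-12)
})

test_that("cubic fit of the contact torque behaves as a local approximation", {
  cell <- bhp()
  fit <- fit_cubic_torque(cell, kin())
  expect_equal(fit$theta_max, 0.0016)
  expect_gt(fit$alpha_a, 0)
  expect_gt(fit$alpha_b, 0)
  # relative misfit shrinks (weakly) with the fit range
  fit_half <- fit_cubic_torque(cell, kin(), theta_max = 0.0008)
  rel <- function(f) f$residual /
    max(abs(resistive_torque(cell, f$theta_max, kin())))
  expect_lte(rel(fit_half), rel(fit) * 1.0001)
})

test_that("linearized cell stiffness is ordered by modulus and linear in it", {
  fits <- lapply(c(2797, 1401, 287), function(E) {
    fit_cubic_torque(cell_model(E_c = E, v = 0.5, R = 10e-6), kin())
  })
  k <- vapply(fits, linearized_cell_stiffness, numeric(1))
  expect_true(all(diff(k) < 0))         # BHP > PC-3 > LNCaP
  expect_rel_equal(k[1] / k[3], 2797 / 287, 1e-8)  # exactly linear in E_c
  # loaded resonant frequency rises monotonically with modulus
  f <- vapply(rev(k), function(kz)
    resonant_frequency(49557e-12 + kz, ref_J_b), numeric(1))
  expect_true(all(diff(f) > 0))
})
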