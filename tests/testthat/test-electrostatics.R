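# comb capacitance, torque, push-pull drive, stability limit

# independent term-by-term oracle: the 2(n-1) inverse-log terms summed one
# by one, radii spelled out explicitly
cap_oracle <- function(geom, theta) {
  tot <- 0
  for (i in seq_len(geom$n - 1L)) {
    outer1 <- geom$R0 + 2 * i * (geom$Wf + geom$g)
    inner1 <- outer1 - geom$g
    tot <- tot + 1 / log(outer1 / inner1)
    outer2 <- geom$R0 + (2 * i + 1) * (geom$Wf + geom$g)
    inner2 <- geom$R0 + 2 * i * (geom$Wf + geom$g) + geom$Wf
    tot <- tot + 1 / log(outer2 / inner2)
  }
  8.854e-12 * theta * geom$h * tot * geom$layers
}

test_that("capacitance matches the term-by-term oracle and is linear in theta", {
  geom <- table1_comb()
  theta <- 6 * pi / 180
  expect_equal(comb_capacitance(geom, 0), 0)
  expect_rel_equal(comb_capacitance(geom, theta), cap_oracle(geom, theta),
                   1e-10)
  expect_equal(comb_capacitance(geom, 2 * theta),
               2 * comb_capacitance(geom, theta))
  g3 <- table1_comb(layers = 3L)
  expect_equal(comb_capacitance(g3, theta), 3 * comb_capacitance(geom, theta))
  expect_error(comb_capacitance(geom, -0.1), "theta")
})

test_that("torque coefficient is half the angular derivative of capacitance", {
  geom <- table1_comb(layers = 3L)
  tau0 <- torque_coefficient(geom)
  dth <- 1e-6
  for (theta in c(0.02, 0.1, 0.4)) {
    dC <- (comb_capacitance(geom, theta + dth) -
             comb_capacitance(geom, theta - dth)) / (2 * dth)
    expect_rel_equal(2 * tau0, dC, 1e-8)
  }
  # linear in thickness, matches the oracle-based coefficient
  g2 <- table1_comb(layers = 3L)
  g2$h <- 2 * g2$h
  expect_rel_equal(torque_coefficient(g2), 2 * tau0, 1e-12)
  expect_rel_equal(tau0, 0.5 * cap_oracle(geom, 1), 1e-10)
})

test_that("capacitance scales by s under uniform in-plane similarity", {
  geom <- table1_comb()
  s <- 2.5
  scaled <- comb_geometry(R0 = s * geom$R0, Wf = s * geom$Wf, g = s * geom$g,
                          h = s * geom$h, n = geom$n, layers = geom$layers,
                          theta0 = geom$theta0)
  # log-ratio terms are scale-invariant; C is proportional to h
  expect_rel_equal(comb_capacitance(scaled, 0.1),
                   s * comb_capacitance(geom, 0.1), 1e-12)
})

test_that("push-pull voltages obey the differential drive identities", {
  sig <- drive_signal(V0 = 3, V1 = 1.5, omega = 2 * pi * 100)
  t <- seq(0, 0.05, length.out = 400)
  v <- pushpull_voltages(sig, t)
  expect_equal(v$VL[1], sig$V0)
  expect_equal(v$VR[1], sig$V0)
  expect_equal(v$VL^2 - v$VR^2, 4 * sig$V0 * sig$V1 * sin(sig$omega * t))
  v0 <- pushpull_voltages(drive_signal(V0 = 3, V1 = 0, omega = 10), t)
  expect_equal(v0$VL, v0$VR)
})

test_that("alternating torque amplitude is 4 tau0 V0 V1", {
  tau0 <- torque_coefficient(table1_comb(layers = 3L))
  expect_equal(actuation_torque_amplitude(tau0, drive_signal(V0 = 0, V1 = 5)),
               0)
  sig <- drive_signal(V0 = 64.58, V1 = 64.58)
  expect_equal(actuation_torque_amplitude(tau0, sig), tau0 * 4 * 64.58^2)
  swap <- drive_signal(V0 = 2, V1 = 7)
  expect_equal(actuation_torque_amplitude(tau0, swap),
               actuation_torque_amplitude(tau0, drive_signal(V0 = 7, V1 = 2)))
})

test_that("critical voltage matches the two-plate energy-balance oracle", {
  k <- 90.76; g <- 2e-6; C <- 1e-12
  vc <- critical_voltage(k, g, C)
  expect_equal(vc, g * sqrt(k / (2 * C)))
  # energy oracle: two opposing plates of capacitance C at gap g each; the
  # lateral electrostatic stiffness at a given V is the numerical second
  # derivative of the co-energy; instability when it reaches k
  Cy <- function(y) C * g / (g - y) + C * g / (g + y)
  k_elec <- function(V) {
    hh <- 1e-10
    0.5 * V^2 * (Cy(hh) - 2 * Cy(0) + Cy(-hh)) / hh^2
  }
  v_oracle <- uniroot(function(V) k_elec(V) - k, c(1, 1e5), tol = 1e-9)$root
  expect_rel_equal(vc, v_oracle, 1e-4)
  # scalings
  expect_rel_equal(critical_voltage(k, g, 4 * C), vc / 2, 1e-12)
  expect_rel_equal(critical_voltage(k, 3 * g, C), 3 * vc, 1e-12)
  expect_error(critical_voltage(k, g, 0), "C")
})

test_that("static rotation is quadratic in voltage and maps to tip travel", {
  k_tz <- 49557e-12
  tau0 <- 1e-11
  expect_equal(static_rotation(tau0, 0, k_tz)$theta_z, 0)
  r1 <- static_rotation(tau0, 10, k_tz)
  r2 <- static_rotation(tau0, 10 * sqrt(2), k_tz)
  expect_rel_equal(r2$theta_z, 2 * r1$theta_z, 1e-12)
  # a 0.382 rad rotation reaches 95.5 um of tip travel at the default lever
  vdc <- sqrt(0.382 * k_tz / tau0)
  r <- static_rotation(tau0, vdc, k_tz, r_tip = 250e-6)
  expect_rel_equal(r$theta_z, 0.382, 1e-10)
  expect_rel_equal(r$tip_displacement * 1e6, 95.5, 1e-3)
})

test_that("gripping force reserve decreases as the tips close", {
  k_tz <- 49557e-12
  tau0 <- 1e-11
  theta <- seq(0, 0.3, length.out = 50)
  Fg <- gripping_force(tau0, 23.4, k_tz, 250e-6, theta)
  expect_true(all(diff(Fg) < 0))
  expect_equal(Fg[1], tau0 * 23.4^2 / 250e-6)
})
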