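# Dynamics of the mobile arm: lumped resonant frequency, Duffing equation
# of motion, Ritz-averaging steady-state frequency response, quality
# factor, and a time-domain integration oracle.

#' Lumped rotational resonant frequency
#'
#' `f = sqrt(k / J) / (2 pi)` of the arm's working rotational mode; with a
#' gripped cell, `k` is the suspension stiffness plus the cell's linearized
#' rotational stiffness.
#'
#' @param k_Tz_total total rotational stiffness (N m rad^-1).
#' @param J_b polar mass moment of inertia (kg m^2).
#' @return frequency (Hz).
#' @export
resonant_frequency <- function(k_Tz_total, J_b) {
  .check_positive(k_Tz_total, "k_Tz_total"); .check_positive(J_b, "J_b")
  sqrt(k_Tz_total / J_b) / (2 * pi)
}

#' Assemble the Duffing equation of motion from a scenario
#'
#' Collects the lumped coefficients of
#' `J_b theta'' + c_amT theta' + k_lin theta + alpha_b theta^3 = B sin(w t)`:
#' inertia from the scenario, damping from the slide-film model, linear
#' stiffness from the suspension (plus the cell's linear torque coefficient
#' when a cell is gripped), the cubic coefficient from the cell-torque fit,
#' and the drive amplitude from the electrodynamic comb and push-pull drive.
#'
#' @param scn a `grip_scenario`.
#' @return object of class `duffing_params` with fields `J_b`, `c_amT`,
#'   `k_lin`, `alpha_b`, `B`, `f_n` (undamped linear natural frequency, Hz)
#'   and, when a cell is present, the `cubic_torque_fit`.
#' @export
assemble_motion_equation <- function(scn) {
  stopifnot(inherits(scn, "grip_scenario"))
  ks <- scenario_stiffness(scn)
  coefs <- slide_film_coefficients(scn$damping)
  tau0 <- torque_coefficient(scn$comb_electrodynamic)
  B <- actuation_torque_amplitude(tau0, scn$drive)
  k_lin <- ks$k_tz
  alpha_b <- 0
  fit <- NULL
  if (!is.null(scn$cell)) {
    fit <- fit_cubic_torque(scn$cell, scn$kinematics)
    k_lin <- k_lin + fit$alpha_a
    alpha_b <- fit$alpha_b
  }
  structure(list(J_b = scn$inertia$J_b, c_amT = coefs$c_amT,
                 k_lin = k_lin, alpha_b = alpha_b, B = B,
                 f_n = resonant_frequency(k_lin, scn$inertia$J_b),
                 fit = fit),
            class = "duffing_params")
}

#' @export
print.duffing_params <- function(x, ...) {
  cat("Duffing oscillator parameters\n")
  cat(sprintf("  J_b     = %.4g kg m^2\n", x$J_b))
  cat(sprintf("  c_amT   = %.4g N m s/rad\n", x$c_amT))
  cat(sprintf("  k_lin   = %.4g N m/rad\n", x$k_lin))
  cat(sprintf("  alpha_b = %.4g N m/rad^3\n", x$alpha_b))
  cat(sprintf("  B       = %.4g N m\n", x$B))
  cat(sprintf("  f_n     = %.2f Hz\n", x$f_n))
  invisible(x)
}

#' Steady-state frequency response by Ritz averaging
#'
#' Single-harmonic ansatz `theta = c1 sin(w t - psi)` (lagging the drive
#' `B sin(w t)` by the phase `psi`) balanced at the drive frequency gives,
#' per frequency, the amplitude equation
#' \deqn{[(k - J w^2) c_1 + (3/4) \alpha_b c_1^3]^2 + (c w c_1)^2 = B^2,}
#' a cubic in `c1^2` with one or three positive roots, and the phase
#' `psi = atan2(c w, k + (3/4) alpha_b c1^2 - J w^2)`.  On triple-root
#' (hardening) intervals the intermediate amplitude branch is unstable.
#'
#' @param p a `duffing_params`.
#' @param omega angular frequency grid (rad s^-1).
#' @return a data.frame of class `frequency_response` with columns
#'   `omega`, `frequency_hz`, `c1` (rad), `psi` (rad), `branch`
#'   (1 = lowest amplitude), `stable`.
#' @export
ritz_response <- function(p, omega) {
  stopifnot(inherits(p, "duffing_params"))
  if (any(omega <= 0)) stop("omega must be > 0", call. = FALSE)
  rows <- vector("list", length(omega))
  for (i in seq_along(omega)) {
    w <- omega[i]
    dk <- p$k_lin - p$J_b * w^2
    cw <- p$c_amT * w
    if (p$B == 0) {
      u <- 0
    } else if (p$alpha_b == 0) {
      u <- p$B^2 / (dk^2 + cw^2)
    } else {
      q <- 0.75 * p$alpha_b
      # q^2 u^3 + 2 q dk u^2 + (dk^2 + cw^2) u - B^2 = 0
      rt <- polyroot(c(-p$B^2, dk^2 + cw^2, 2 * q * dk, q^2))
      u <- sort(Re(rt)[abs(Im(rt)) < 1e-8 * Mod(rt) & Re(rt) > 0])
      if (!length(u)) {
        stop("no real positive amplitude root (internal error)",
             call. = FALSE)
      }
    }
    c1 <- sqrt(u)
    nb <- length(c1)
    stable <- rep(TRUE, nb)
    if (nb == 3L) stable[2L] <- FALSE
    psi <- atan2(cw, p$k_lin + 0.75 * p$alpha_b * c1^2 - p$J_b * w^2)
    rows[[i]] <- data.frame(omega = w, frequency_hz = w / (2 * pi),
                            c1 = c1, psi = psi, branch = seq_len(nb),
                            stable = stable)
  }
  out <- do.call(rbind, rows)
  attr(out, "params") <- p
  class(out) <- c("frequency_response", "data.frame")
  out
}

# amplitude the device settles on in a slow low->high sweep: the largest
# stable amplitude at each frequency
.upper_stable <- function(resp) {
  st <- resp[resp$stable, , drop = FALSE]
  idx <- tapply(seq_len(nrow(st)), st$omega, function(ii) ii[which.max(st$c1[ii])])
  st <- st[unlist(idx), , drop = FALSE]
  st[order(st$omega), , drop = FALSE]
}

#' Locate the response peak
#'
#' Peak of the upper stable branch, refined off-grid by a quadratic fit
#' through the grid maximum and its neighbours.
#'
#' @param resp a `frequency_response`.
#' @return list with `f_peak` (Hz), `c_peak` (rad).
#' @export
response_peak <- function(resp) {
  stopifnot(inherits(resp, "frequency_response"))
  up <- .upper_stable(resp)
  i <- which.max(up$c1)
  if (i == 1L || i == nrow(up)) {
    stop("response peak at grid edge; widen the frequency grid",
         call. = FALSE)
  }
  f <- up$frequency_hz[(i - 1):(i + 1)]
  a <- up$c1[(i - 1):(i + 1)]
  # vertex of the interpolating parabola through the three points
  cf <- solve(cbind(1, f - f[2], (f - f[2])^2), a)
  if (cf[3] >= 0) {
    return(list(f_peak = f[2], c_peak = a[2]))
  }
  t0 <- -cf[2] / (2 * cf[3])
  list(f_peak = f[2] + t0,
       c_peak = cf[1] + cf[2] * t0 + cf[3] * t0^2)
}

#' Quality factor from a frequency response
#'
#' Half-power definition on the upper stable branch: `Q = f_peak / df`,
#' where `df` is the bandwidth between the two crossings of
#' `c_peak / sqrt(2)`.  For bent (hardening) peaks whose upper branch ends
#' at a fold before recrossing, the fold frequency closes the band.
#'
#' @param resp a `frequency_response`.
#' @return quality factor (dimensionless).
#' @export
quality_factor <- function(resp) {
  stopifnot(inherits(resp, "frequency_response"))
  up <- .upper_stable(resp)
  pk <- response_peak(resp)
  hp <- pk$c_peak / sqrt(2)
  i <- which.max(up$c1)
  # lower crossing
  lo <- NULL
  for (j in seq(i, 2L)) {
    if (up$c1[j - 1] < hp && up$c1[j] >= hp) {
      lo <- up$frequency_hz[j - 1] +
        (hp - up$c1[j - 1]) / (up$c1[j] - up$c1[j - 1]) *
        (up$frequency_hz[j] - up$frequency_hz[j - 1])
      break
    }
  }
  # upper crossing (or fold: discontinuous drop of the upper branch)
  hi <- NULL
  for (j in seq(i, nrow(up) - 1L)) {
    if (up$c1[j] >= hp && up$c1[j + 1] < hp) {
      drop <- (up$c1[j] - up$c1[j + 1]) > 0.25 * up$c1[j]
      hi <- if (drop) up$frequency_hz[j] else
        up$frequency_hz[j] +
          (up$c1[j] - hp) / (up$c1[j] - up$c1[j + 1]) *
          (up$frequency_hz[j + 1] - up$frequency_hz[j])
      break
    }
  }
  if (is.null(lo) || is.null(hi)) {
    stop("half-power band not resolved on the grid; widen the grid",
         call. = FALSE)
  }
  pk$f_peak / (hi - lo)
}

#' Time-domain integration oracle for the Duffing equation
#'
#' Adaptive integration of the full equation of motion from rest, used as
#' the independent check of the Ritz steady-state amplitudes.
#'
#' @param p a `duffing_params`.
#' @param omega drive angular frequency (rad s^-1).
#' @param periods number of forcing periods to integrate (>= 50 for
#'   steady-state extraction).
#' @param samples_per_period output sampling density.
#' @param rtol,atol integrator tolerances.
#' @param theta0,theta_dot0 initial rotation (rad) and angular velocity
#'   (rad s^-1); the default starts from rest.
#' @return list with `trajectory` (data.frame `t`, `theta`, `theta_dot`)
#'   and `amplitude`, the half peak-to-peak displacement over the last 10
#'   periods.
#' @export
time_integrate <- function(p, omega, periods = 120L,
                           samples_per_period = 40L,
                           rtol = 1e-9, atol = 1e-14,
                           theta0 = 0, theta_dot0 = 0) {
  stopifnot(inherits(p, "duffing_params"))
  .check_positive(omega, "omega")
  Tp <- 2 * pi / omega
  times <- seq(0, periods * Tp, by = Tp / samples_per_period)
  deriv <- function(t, y, parms) {
    list(c(y[2],
           (p$B * sin(omega * t) - p$c_amT * y[2] - p$k_lin * y[1] -
              p$alpha_b * y[1]^3) / p$J_b))
  }
  sol <- deSolve::ode(y = c(theta = theta0, theta_dot = theta_dot0),
                      times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  traj <- as.data.frame(sol)
  names(traj) <- c("t", "theta", "theta_dot")
  tail10 <- traj$t >= (periods - 10L) * Tp
  amp <- (max(traj$theta[tail10]) - min(traj$theta[tail10])) / 2
  list(trajectory = traj, amplitude = amp)
}

#' Frequency sweep of a scenario
#'
#' Assembles the equation of motion and evaluates the Ritz response on the
#' scenario's solver frequency grid, filtered by the solver's branch
#' policy: `"all"` keeps every solution branch, `"stable"` drops the
#' unstable middle branch, `"lowest"` keeps only the lowest-amplitude
#' branch (what a slow high-to-low sweep settles on).
#'
#' @param scn a `grip_scenario`.
#' @return a `frequency_response`.
#' @export
sweep_response <- function(scn) {
  stopifnot(inherits(scn, "grip_scenario"))
  p <- assemble_motion_equation(scn)
  f <- seq(scn$solver$freq_min, scn$solver$freq_max,
           length.out = scn$solver$freq_points)
  resp <- ritz_response(p, 2 * pi * f)
  keep <- switch(scn$solver$branch_policy,
                 all = rep(TRUE, nrow(resp)),
                 stable = resp$stable,
                 lowest = resp$branch == 1L)
  out <- resp[keep, , drop = FALSE]
  attr(out, "params") <- p
  class(out) <- class(resp)
  out
}

#' @export
plot.frequency_response <- function(x, ...) {
  up <- .upper_stable(x)
  graphics::plot(up$frequency_hz, up$c1, type = "l",
                 xlab = "frequency (Hz)", ylab = "amplitude c1 (rad)", ...)
  un <- x[!x$stable, , drop = FALSE]
  if (nrow(un)) graphics::points(un$frequency_hz, un$c1, pch = ".",
                                 col = "grey50")
  invisible(x)
}
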