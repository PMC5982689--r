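# Hertzian large-deformation contact of the gripped cell and its cubic
# torque reduction.
#
# The contact law extends Hertz sphere contact to compressions that are a
# substantial fraction of the cell radius, with a lateral-extension
# correction f(a).  The bracket is evaluated as (4a - f(a) a^2 / pi): the
# correction carries an a^2 length normalisation so both terms are lengths,
# and in the small-compression limit the force reduces to the classical
# sphere-plate power law F proportional to E sqrt(R) delta^{3/2} / (1-v^2)
# (with the geometric chord contact radius a = sqrt(2 R delta - delta^2),
# whose leading coefficient is sqrt(2) times the Hertz elastic one; see the
# methods vignette).  The law is exposed through these functions only, so a
# different contact model can be swapped in at this surface.

#' Geometric contact radius of the compressed cell
#'
#' Chord radius of the flattened cap after a radial compression `delta_r`:
#' `a = sqrt(2 R delta_r - delta_r^2)`.
#'
#' @param cell a [cell_model()].
#' @param delta_r radial compression (m), `0 <= delta_r <= R`.
#' @return contact radius (m).
#' @export
contact_radius <- function(cell, delta_r) {
  stopifnot(inherits(cell, "cell_model"))
  if (any(delta_r < 0) || any(delta_r > cell$R)) {
    stop("delta_r must lie in [0, R]", call. = FALSE)
  }
  sqrt(2 * cell$R * delta_r - delta_r^2)
}

# lateral-extension correction, units 1/length
.contact_f <- function(cell, a) {
  v <- cell$v; R <- cell$R
  2 * (1 + v) * R^2 / (a^2 + 4 * R^2)^(3 / 2) +
    (1 - v^2) / sqrt(a^2 + 4 * R^2)
}

#' Resistive contact force of the compressed cell
#'
#' Large-deformation contact force
#' `F = delta_r * E_c / (3 (1 - v^2)) * (4a - f(a) a^2 / pi)`.
#'
#' @param cell a [cell_model()].
#' @param delta_r radial compression (m).
#' @param cap model-validity cap on `delta_r` as a fraction of `R`.
#' @return compression force (N), 0 at `delta_r = 0`, linear in `E_c`.
#' @export
resistive_force <- function(cell, delta_r, cap = 0.6) {
  stopifnot(inherits(cell, "cell_model"))
  if (cell$v >= 1) stop("cell Poisson ratio must be < 1", call. = FALSE)
  if (any(delta_r < 0)) stop("delta_r must be >= 0", call. = FALSE)
  if (any(delta_r > cap * cell$R)) {
    stop(sprintf("delta_r exceeds the contact-model validity cap %.2f R",
                 cap), call. = FALSE)
  }
  a <- contact_radius(cell, delta_r)
  bracket <- 4 * a - .contact_f(cell, a) * a^2 / pi
  delta_r * cell$E_c / (3 * (1 - cell$v^2)) * bracket
}

#' Resistive torque of the gripped cell about the pivot
#'
#' The arm rotation splits the compression equally between the two tips,
#' `delta_r = r_c * theta_z / 2`, and the contact force acts at the lever
#' arm `r_c`: `T_c = F(delta_r) * r_c`.
#'
#' @param cell a [cell_model()].
#' @param theta_z closing rotation (rad), `>= 0`.
#' @param kin a [kinematics_model()] providing `r_c`.
#' @param cap validity cap passed to [resistive_force()].
#' @return resistive torque (N m).
#' @export
resistive_torque <- function(cell, theta_z, kin, cap = 0.6) {
  stopifnot(inherits(kin, "kinematics_model"))
  if (any(theta_z < 0)) stop("theta_z must be >= 0", call. = FALSE)
  delta_r <- kin$r_c * theta_z / 2
  bad <- delta_r > cap * cell$R
  if (any(bad)) {
    stop(sprintf(paste0("theta_z = %.3g rad implies compression beyond the ",
                        "validity cap %.2f R"),
                 max(theta_z[bad]), cap), call. = FALSE)
  }
  resistive_force(cell, delta_r, cap = cap) * kin$r_c
}

#' Cubic polynomial reduction of the cell torque
#'
#' Least-squares fit of the resistive torque curve on `[0, theta_max]` to
#' the odd cubic `alpha_a * theta + alpha_b * theta^3` through the origin —
#' the form the gripped-cell term takes in the Duffing equation of motion.
#'
#' @param cell a [cell_model()].
#' @param kin a [kinematics_model()].
#' @param theta_max fit range (rad); default corresponds to compressing the
#'   cell by 20% of its radius.
#' @param n_grid number of sample points (>= 10).
#' @param torque_fn torque curve to reduce, a function of `theta`; defaults
#'   to the cell's [resistive_torque()].  Overriding it lets a different
#'   contact law reuse the same reduction.
#' @return object of class `cubic_torque_fit` with fields `alpha_a`
#'   (N m rad^-1), `alpha_b` (N m rad^-3), `theta_max`, `residual`
#'   (rms, N m).
#' @export
fit_cubic_torque <- function(cell, kin, theta_max = 0.4 * cell$R / kin$r_c,
                             n_grid = 200L, torque_fn = NULL) {
  stopifnot(inherits(cell, "cell_model"), inherits(kin, "kinematics_model"))
  .check_positive(theta_max, "theta_max")
  if (n_grid < 10) stop("n_grid must be >= 10", call. = FALSE)
  theta <- seq(0, theta_max, length.out = n_grid)
  Tc <- if (is.null(torque_fn)) resistive_torque(cell, theta, kin) else
    torque_fn(theta)
  X <- cbind(theta, theta^3)
  cf <- stats::lm.fit(X, Tc)$coefficients
  resid <- Tc - X %*% cf
  structure(list(alpha_a = unname(cf[1]), alpha_b = unname(cf[2]),
                 theta_max = theta_max,
                 residual = sqrt(mean(resid^2)),
                 cell = cell),
            class = "cubic_torque_fit")
}

#' @export
print.cubic_torque_fit <- function(x, ...) {
  cat(sprintf("Cubic cell-torque fit (%s): Tc = alpha_a*theta + alpha_b*theta^3\n",
              x$cell$label))
  cat(sprintf("  alpha_a = %.4g N m/rad\n", x$alpha_a))
  cat(sprintf("  alpha_b = %.4g N m/rad^3\n", x$alpha_b))
  cat(sprintf("  fit range [0, %.4g] rad, rms residual %.3g N m\n",
              x$theta_max, x$residual))
  invisible(x)
}

#' Linearized rotational stiffness of the gripped cell
#'
#' The linear coefficient of the cubic torque fit: the contribution the cell
#' adds to the suspension stiffness in the loaded resonant frequency.
#'
#' @param fit a `cubic_torque_fit`.
#' @return cell rotational stiffness `k_zc` (N m rad^-1).
#' @export
linearized_cell_stiffness <- function(fit) {
  stopifnot(inherits(fit, "cubic_torque_fit"))
  fit$alpha_a
}
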