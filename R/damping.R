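# Slide-film air damping of the mobile arm.
#
# Every coefficient returned here is a rotational damping coefficient,
# torque per unit angular velocity (N m s rad^-1): the local Couette drag of
# each surface is weighted by the square of its lever arm about the pivot.

#' Slide-film damping coefficients
#'
#' Partial and total rotational damping coefficients of the mobile arm:
#' * `c_am1` — substrate film under the first mobile layer, summed over the
#'   bodies that sit above the substrate (`mu A_p r^2 / d_p` each);
#' * `c_am2` — drag of an upper mobile layer, summed over all bodies
#'   (`(32/3) mu l_am r^2` each); the second and third mobile layers are
#'   identical, so `c_am2` enters the total twice;
#' * `c_am4` — comb sidewall films (`mu A_s r^2 / g` per face);
#' * `c_amT = c_am1 + 2 c_am2 + c_am4`.
#'
#' @param geom a [damping_geometry()].
#' @return list of class `damping_coefficients` with `c_am1`, `c_am2`,
#'   `c_am4`, `c_amT` (N m s rad^-1).
#' @export
slide_film_coefficients <- function(geom) {
  stopifnot(inherits(geom, "damping_geometry"))
  if (geom$d_p <= 0 || geom$g <= 0) {
    stop("gaps d_p and g must be > 0", call. = FALSE)
  }
  c1 <- 0; c2 <- 0
  for (b in geom$bodies) {
    if (isTRUE(b$above_substrate)) {
      c1 <- c1 + geom$mu * b$A_p * b$r_am^2 / geom$d_p
    }
    c2 <- c2 + (32 / 3) * geom$mu * b$l_am * b$r_am^2
  }
  c4 <- 0
  for (s in geom$sidewalls) {
    c4 <- c4 + geom$mu * s$A_s * s$r^2 / geom$g
  }
  structure(list(c_am1 = c1, c_am2 = c2, c_am4 = c4,
                 c_amT = c1 + 2 * c2 + c4),
            class = "damping_coefficients")
}

#' Damping torque
#'
#' Total viscous torque opposing the arm's angular velocity,
#' `Td = c_amT * theta_dot`.
#'
#' @param coefs a `damping_coefficients` object.
#' @param theta_dot angular velocity (rad s^-1).
#' @return damping torque (N m), same sign as `theta_dot`.
#' @export
damping_torque <- function(coefs, theta_dot) {
  stopifnot(inherits(coefs, "damping_coefficients"))
  coefs$c_amT * theta_dot
}

#' @export
print.damping_coefficients <- function(x, ...) {
  cat("Slide-film rotational damping coefficients (N m s/rad)\n")
  cat(sprintf("  c_am1 (substrate film) : %.4g\n", x$c_am1))
  cat(sprintf("  c_am2 (per upper layer): %.4g\n", x$c_am2))
  cat(sprintf("  c_am4 (comb sidewalls) : %.4g\n", x$c_am4))
  cat(sprintf("  c_amT (total)          : %.4g\n", x$c_amT))
  invisible(x)
}
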