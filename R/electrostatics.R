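# Electrostatics of the rotary comb actuators: capacitance, torque
# coefficient, push-pull drive, side-instability voltage limit, static
# rotation.

.eps0 <- 8.854e-12  # vacuum/air permittivity, F/m

# The two bracketed sums over the n-1 inner finger interfaces: the inverse
# logs of the radius ratios across the gap on either side of each mobile
# finger.  Kept as a single helper so capacitance and torque use literally
# the same series.
.comb_log_sums <- function(geom) {
  i <- seq_len(geom$n - 1L)
  p <- geom$Wf + geom$g
  s1 <- 1 / log((geom$R0 + 2 * i * p) / (geom$R0 + 2 * i * p - geom$g))
  s2 <- 1 / log((geom$R0 + (2 * i + 1) * p) / (geom$R0 + 2 * i * p + geom$Wf))
  sum(s1) + sum(s2)
}

#' Comb-drive capacitance
#'
#' Total capacitance of a rotary comb actuator at overlap angle `theta`,
#' summed over all mobile layers.  The capacitance is exactly linear in the
#' overlap angle, which is what makes the actuation torque independent of
#' rotation.
#'
#' @param geom a [comb_geometry()].
#' @param theta overlap angle (rad), `0 <= theta <= pi/2 - small`.
#' @return capacitance (F).
#' @export
comb_capacitance <- function(geom, theta) {
  stopifnot(inherits(geom, "comb_geometry"))
  if (any(theta < 0)) stop("theta must be >= 0", call. = FALSE)
  .eps0 * theta * geom$h * .comb_log_sums(geom) * geom$layers
}

#' Electrostatic torque coefficient
#'
#' Coefficient `tau0` such that the actuation torque is `tau0 * V^2`:
#' half the (constant) angular derivative of the comb capacitance.
#'
#' @param geom a [comb_geometry()].
#' @return torque coefficient (N m V^-2).
#' @export
torque_coefficient <- function(geom) {
  stopifnot(inherits(geom, "comb_geometry"))
  0.5 * .eps0 * geom$h * .comb_log_sums(geom) * geom$layers
}

#' Push-pull drive voltages
#'
#' Left and right electrode voltages of the differential (push-pull) ac
#' drive: `VL = V0 + V1 sin(wt)`, `VR = V0 - V1 sin(wt)`.  The net squared
#' voltage `VL^2 - VR^2 = 4 V0 V1 sin(wt)` makes the torque purely
#' alternating at the drive frequency.
#'
#' @param sig a [drive_signal()].
#' @param t time (s), scalar or vector.
#' @return data.frame with columns `t`, `VL`, `VR`.
#' @export
pushpull_voltages <- function(sig, t) {
  stopifnot(inherits(sig, "drive_signal"))
  s <- sig$V1 * sin(sig$omega * t)
  data.frame(t = t, VL = sig$V0 + s, VR = sig$V0 - s)
}

#' Alternating actuation torque amplitude
#'
#' Amplitude `B = 4 tau0 V0 V1` of the net push-pull torque
#' `B sin(wt)`.
#'
#' @param tau0 torque coefficient (N m V^-2).
#' @param sig a [drive_signal()].
#' @return torque amplitude (N m).
#' @export
actuation_torque_amplitude <- function(tau0, sig) {
  stopifnot(inherits(sig, "drive_signal"))
  .check_nonneg(tau0, "tau0")
  4 * tau0 * sig$V0 * sig$V1
}

#' Side-instability (critical) actuation voltage
#'
#' Voltage above which the lateral electrostatic attraction between finger
#' sidewalls overcomes the suspension's lateral stiffness and the fingers
#' snap sideways: `Vc = g * sqrt(k / (2 C))`.
#'
#' @param k lateral suspension stiffness normal to the finger sidewalls
#'   (N m^-1); conventionally the in-plane stiffness `k_Fy`.
#' @param g finger gap (m).
#' @param C total comb capacitance at the operating overlap (F).
#' @return critical voltage (V).
#' @export
critical_voltage <- function(k, g, C) {
  .check_positive(k, "k"); .check_positive(g, "g")
  if (!is.numeric(C) || C <= 0) stop("C must be > 0", call. = FALSE)
  g * sqrt(k / (2 * C))
}

#' Static rotation under dc actuation
#'
#' Quasi-static torque balance of the mobile arm without gripped cell:
#' actuation torque `tau0 Vdc^2` against the suspension reaction
#' `k_tz theta_z`.
#'
#' @param tau0 torque coefficient of the dc actuator (N m V^-2).
#' @param Vdc dc voltage (V).
#' @param k_tz rotational suspension stiffness (N m rad^-1).
#' @param r_tip optional tip lever arm (m) for the tip displacement.
#' @return list with `theta_z` (rad) and, when `r_tip` is given,
#'   `tip_displacement` (m).
#' @export
static_rotation <- function(tau0, Vdc, k_tz, r_tip = NULL) {
  .check_nonneg(tau0, "tau0"); .check_nonneg(Vdc, "Vdc")
  .check_positive(k_tz, "k_tz")
  theta <- tau0 * Vdc^2 / k_tz
  out <- list(theta_z = theta)
  if (!is.null(r_tip)) out$tip_displacement <- theta * r_tip
  out
}

#' Optimal push-pull voltage split
#'
#' Maximises the alternating torque amplitude `B = 4 tau0 V0 V1` subject to
#' the peak electrode voltage `V0 + V1` not exceeding `V_peak`.  The
#' optimum is the equal split, found here numerically.
#'
#' @param V_peak peak voltage cap (V).
#' @return list with `V0`, `V1` (V) and the maximised product `V0V1` (V^2).
#' @export
optimal_pushpull <- function(V_peak) {
  .check_positive(V_peak, "V_peak")
  opt <- stats::optimize(function(v0) v0 * (V_peak - v0),
                         interval = c(0, V_peak), maximum = TRUE,
                         tol = 1e-12)
  list(V0 = opt$maximum, V1 = V_peak - opt$maximum, V0V1 = opt$objective)
}

#' Maximum tip opening
#'
#' Initial tip separation plus the controlled opening-direction travel.
#'
#' @param kin a [kinematics_model()].
#' @return maximum opening (m).
#' @export
max_opening <- function(kin) {
  stopifnot(inherits(kin, "kinematics_model"))
  kin$gap0 + kin$max_travel
}

#' Available gripping force at a closing rotation
#'
#' Force reserve at the gripper tip while closing under dc actuation: the
#' actuation torque minus the suspension reaction, divided by the tip lever
#' arm, `F = (tau0 Vdc^2 - k_tz theta_z) / r_tip`.  The reserve shrinks as
#' the arm rotates further because an increasing share of the electrostatic
#' torque is spent deflecting the springs.
#'
#' @param tau0 torque coefficient of the dc actuator (N m V^-2).
#' @param Vdc dc voltage (V).
#' @param k_tz rotational suspension stiffness (N m rad^-1).
#' @param r_tip tip lever arm (m).
#' @param theta_z closing rotation (rad), scalar or vector.
#' @return gripping force (N); negative values mean the actuator cannot
#'   reach that rotation.
#' @export
gripping_force <- function(tau0, Vdc, k_tz, r_tip, theta_z) {
  .check_nonneg(tau0, "tau0"); .check_nonneg(Vdc, "Vdc")
  .check_positive(k_tz, "k_tz"); .check_positive(r_tip, "r_tip")
  (tau0 * Vdc^2 - k_tz * theta_z) / r_tip
}
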