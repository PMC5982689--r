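# Domain-type constructors.  All arguments and stored fields are SI.

#' Rotary comb-drive geometry
#'
#' Geometry of one rotary comb-drive actuator: concentric arc-shaped finger
#' pairs between an inner radius `R0` and the outer edge of the finger array,
#' with a constant finger width and gap, repeated on each mobile structural
#' layer.
#'
#' @param R0 inner radius of the first finger (m).
#' @param Wf finger width (m).
#' @param g gap between fingers (m).
#' @param h finger (layer) thickness (m).
#' @param n number of finger pairs per layer.
#' @param layers number of mobile structural layers carrying fingers.
#' @param theta0 initial overlap angle (rad), in (0, pi/2).
#' @return an object of class `comb_geometry`.
#' @examples
#' geom <- comb_geometry(R0 = 400e-6, Wf = 2e-6, g = 2e-6, h = 7e-6,
#'                       n = 20, layers = 3, theta0 = 6 * pi / 180)
#' comb_capacitance(geom, geom$theta0)
#' @export
comb_geometry <- function(R0, Wf, g, h, n, layers = 1L, theta0 = 6 * pi / 180) {
  .check_positive(R0, "R0"); .check_positive(Wf, "Wf")
  .check_positive(g, "g");   .check_positive(h, "h")
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop("field 'n' must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(layers) || layers < 1 || layers != round(layers)) {
    stop("field 'layers' must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(theta0) || theta0 <= 0 || theta0 >= pi / 2) {
    stop("field 'theta0' must lie in (0, pi/2)", call. = FALSE)
  }
  structure(list(R0 = R0, Wf = Wf, g = g, h = h, n = as.integer(n),
                 layers = as.integer(layers), theta0 = theta0),
            class = "comb_geometry")
}

#' Suspension stiffness set
#'
#' The five lumped stiffnesses of the two-spring serpentine suspension
#' assembly: rotations about z (the working mode) and x, and translations
#' along x, y, z.
#'
#' @param k_tz,k_tx rotational stiffnesses (N m rad^-1).
#' @param k_Fx,k_Fy,k_Fz translational stiffnesses (N m^-1).
#' @return an object of class `stiffness_set`.
#' @export
stiffness_set <- function(k_tz, k_tx, k_Fx, k_Fy, k_Fz) {
  for (nm in c("k_tz", "k_tx", "k_Fx", "k_Fy", "k_Fz")) {
    .check_positive(get(nm), nm)
  }
  structure(list(k_tz = k_tz, k_tx = k_tx,
                 k_Fx = k_Fx, k_Fy = k_Fy, k_Fz = k_Fz),
            class = "stiffness_set")
}

#' Straight beam segment of a serpentine spring
#'
#' One straight constant-section beam in the serpentine chain, described by
#' its length, rectangular cross-section and in-plane direction.  Segments
#' are chained tip-to-tail from the anchor towards the connection point with
#' the mobile arm.
#'
#' @param L length (m).
#' @param b in-plane width (m).
#' @param h out-of-plane height/thickness (m).
#' @param axis length-2 or length-3 direction vector (normalised internally);
#'   must lie in the device plane (zero z-component).
#' @return an object of class `beam_segment`.
#' @export
beam_segment <- function(L, b, h, axis = c(1, 0)) {
  .check_positive(L, "L"); .check_positive(b, "b"); .check_positive(h, "h")
  if (length(axis) == 2L) axis <- c(axis, 0)
  if (length(axis) != 3L || !is.numeric(axis) || sum(axis^2) == 0) {
    stop("field 'axis' must be a non-zero 2- or 3-vector", call. = FALSE)
  }
  if (abs(axis[3]) > 1e-12 * sqrt(sum(axis^2))) {
    stop("field 'axis' must lie in the device plane (z component 0)",
         call. = FALSE)
  }
  axis <- axis / sqrt(sum(axis^2))
  structure(list(L = L, b = b, h = h, axis = axis), class = "beam_segment")
}

#' Suspension model
#'
#' Either a directly specified [stiffness_set()] (`mode = "direct"`) or a
#' serpentine beam chain from which the stiffnesses are computed by the
#' Castigliano energy method (`mode = "castigliano"`).
#'
#' @param mode `"direct"` or `"castigliano"`.
#' @param stiffness a [stiffness_set()] (direct mode).
#' @param beams list of [beam_segment()] (castigliano mode), anchor to tip.
#' @param E polysilicon Young modulus (Pa).
#' @param nu_poly polysilicon Poisson ratio, in (0, 0.5).
#' @param rho polysilicon density (kg m^-3).
#' @return an object of class `suspension_model`.
#' @export
suspension_model <- function(mode = c("direct", "castigliano"),
                             stiffness = NULL, beams = NULL,
                             E = 160e9, nu_poly = 0.23, rho = 2330) {
  mode <- match.arg(mode)
  .check_positive(E, "E"); .check_positive(rho, "rho")
  if (!is.numeric(nu_poly) || nu_poly <= 0 || nu_poly >= 0.5) {
    stop("field 'nu_poly' must lie in (0, 0.5)", call. = FALSE)
  }
  if (mode == "direct") {
    if (is.null(stiffness) || !inherits(stiffness, "stiffness_set")) {
      stop("direct mode requires a 'stiffness' set", call. = FALSE)
    }
    if (!is.null(beams)) {
      stop("exactly one of 'stiffness'/'beams' may be given", call. = FALSE)
    }
  } else {
    if (is.null(beams) || !length(beams) ||
        !all(vapply(beams, inherits, logical(1), "beam_segment"))) {
      stop("castigliano mode requires a non-empty list of beam segments",
           call. = FALSE)
    }
    if (!is.null(stiffness)) {
      stop("exactly one of 'stiffness'/'beams' may be given", call. = FALSE)
    }
  }
  structure(list(mode = mode, stiffness = stiffness, beams = beams,
                 E = E, nu_poly = nu_poly, rho = rho),
            class = "suspension_model")
}

#' Gripped-cell model
#'
#' Linear-elastic sphere model of the gripped cell.
#'
#' @param E_c elastic modulus (Pa).
#' @param v Poisson ratio, in `[0, 0.5]`; 0.5 is the incompressible default
#'   conventional for cells.
#' @param R cell radius (m).
#' @param label cell-type name.
#' @return an object of class `cell_model`.
#' @export
cell_model <- function(E_c, v = 0.5, R = 10e-6, label = "cell") {
  .check_positive(E_c, "E_c"); .check_positive(R, "R")
  if (!is.numeric(v) || v < 0 || v > 0.5) {
    stop("field 'v' must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(E_c = E_c, v = v, R = R, label = as.character(label)),
            class = "cell_model")
}

#' Damping geometry
#'
#' Partition of the mobile arm into slide-film damping bodies plus the comb
#' sidewall faces.  Each body carries the plate area facing the substrate
#' (`A_p`), the lever arm of its damping-force resultant (`r_am`), its
#' half-length (`l_am`) and whether it sits above the substrate (only those
#' bodies contribute substrate slide film; all bodies contribute the
#' upper-layer terms).
#'
#' @param bodies list of lists with fields `A_p` (m^2), `r_am` (m), `l_am`
#'   (m), `above_substrate` (logical).
#' @param d_p gap between the first mobile layer and the substrate (m).
#' @param sidewalls list of lists with fields `A_s` (m^2) and `r` (m), one
#'   per mobile finger sidewall face.
#' @param g sidewall gap (m).
#' @param mu air dynamic viscosity (Pa s).
#' @return an object of class `damping_geometry`.
#' @export
damping_geometry <- function(bodies, d_p, sidewalls, g, mu = 1.81e-5) {
  .check_positive(d_p, "d_p"); .check_positive(g, "g")
  .check_positive(mu, "mu")
  for (b in bodies) {
    .check_nonneg(b$A_p, "A_p"); .check_nonneg(b$r_am, "r_am")
    .check_nonneg(b$l_am, "l_am")
    if (!is.logical(b$above_substrate)) {
      stop("each body needs a logical 'above_substrate' flag", call. = FALSE)
    }
  }
  for (s in sidewalls) {
    .check_nonneg(s$A_s, "A_s"); .check_nonneg(s$r, "r")
  }
  structure(list(bodies = bodies, d_p = d_p, sidewalls = sidewalls,
                 g = g, mu = mu),
            class = "damping_geometry")
}

#' Generate the default sidewall list from a comb geometry
#'
#' One entry per sidewall face of each mobile finger: two faces per finger
#' per layer, area approximated by arc length times thickness at the finger
#' radius, lever arm equal to the finger radius.
#'
#' @param geom a [comb_geometry()].
#' @param arc_angle angular extent of each finger arc (rad); defaults to
#'   twice the initial overlap angle.
#' @return list of sidewall descriptors suitable for [damping_geometry()].
#' @export
comb_sidewalls <- function(geom, arc_angle = 2 * geom$theta0) {
  pitch <- 2 * (geom$Wf + geom$g)
  out <- vector("list", 2L * geom$n * geom$layers)
  k <- 0L
  for (layer in seq_len(geom$layers)) {
    for (i in seq_len(geom$n)) {
      r <- geom$R0 + (i - 1) * pitch + geom$Wf / 2
      A <- r * arc_angle * geom$h
      for (face in 1:2) {
        k <- k + 1L
        out[[k]] <- list(A_s = A, r = r)
      }
    }
  }
  out
}

#' Kinematics of the gripper tips
#'
#' @param r_tip lever arm from the pivot to the gripper tip (m).
#' @param gap0 initial tip separation (m).
#' @param r_c lever arm of the cell-contact force (m).
#' @param max_travel maximum controlled tip displacement in either the
#'   opening or closing direction (m).
#' @return an object of class `kinematics_model`.
#' @export
kinematics_model <- function(r_tip = 250e-6, gap0 = 40e-6, r_c = 2500e-6,
                             max_travel = 40e-6) {
  .check_positive(r_tip, "r_tip"); .check_positive(gap0, "gap0")
  .check_positive(r_c, "r_c");     .check_positive(max_travel, "max_travel")
  structure(list(r_tip = r_tip, gap0 = gap0, r_c = r_c,
                 max_travel = max_travel),
            class = "kinematics_model")
}

#' Drive signal
#'
#' Push-pull ac drive of the electrodynamic actuator (`V0`, `V1`, `omega`)
#' plus the dc-only voltage of the electrostatic actuator (`Vdc`).
#'
#' @param V0 dc offset of the push-pull pair (V).
#' @param V1 ac amplitude (V).
#' @param omega angular drive frequency (rad s^-1).
#' @param Vdc dc actuation voltage of the electrostatic actuator (V).
#' @return an object of class `drive_signal`.
#' @export
drive_signal <- function(V0 = 0, V1 = 0, omega = 0, Vdc = 0) {
  .check_nonneg(V0, "V0"); .check_nonneg(V1, "V1")
  .check_nonneg(omega, "omega"); .check_nonneg(Vdc, "Vdc")
  structure(list(V0 = V0, V1 = V1, omega = omega, Vdc = Vdc),
            class = "drive_signal")
}

#' Solver settings
#'
#' @param freq_min,freq_max,freq_points frequency grid for sweeps (Hz).
#' @param branch_policy which Duffing solution branches to report.
#' @param ode_rtol,ode_atol tolerances of the time-domain integrator.
#' @param seed integer seed for stochastic fixtures.
#' @param series_terms truncation of the torsion-constant tanh series.
#' @return an object of class `solver_settings`.
#' @export
solver_settings <- function(freq_min = 300, freq_max = 900,
                            freq_points = 1201,
                            branch_policy = c("stable", "lowest", "all"),
                            ode_rtol = 1e-8, ode_atol = 1e-12,
                            seed = 1L, series_terms = 16L) {
  branch_policy <- match.arg(branch_policy)
  if (!(freq_min < freq_max)) stop("freq_min must be < freq_max", call. = FALSE)
  if (freq_points < 2) stop("freq_points must be >= 2", call. = FALSE)
  .check_positive(ode_rtol, "ode_rtol"); .check_positive(ode_atol, "ode_atol")
  if (series_terms < 1) stop("series_terms must be >= 1", call. = FALSE)
  structure(list(freq_min = freq_min, freq_max = freq_max,
                 freq_points = as.integer(freq_points),
                 branch_policy = branch_policy,
                 ode_rtol = ode_rtol, ode_atol = ode_atol,
                 seed = as.integer(seed),
                 series_terms = as.integer(series_terms)),
            class = "solver_settings")
}

#' Tip load case at the suspension connection point
#'
#' @param Fx,Fy,Fz forces (N).
#' @param Mx,My,Mz moments (N m).
#' @return an object of class `load_case`.
#' @export
load_case <- function(Fx = 0, Fy = 0, Fz = 0, Mx = 0, My = 0, Mz = 0) {
  v <- c(Fx = Fx, Fy = Fy, Fz = Fz, Mx = Mx, My = My, Mz = Mz)
  if (any(!is.finite(v))) stop("load components must be finite", call. = FALSE)
  structure(as.list(v), class = "load_case")
}
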