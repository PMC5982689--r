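# Serpentine-spring stiffness by the Castigliano energy method.
#
# The suspension is a chain of straight constant-section beams, clamped at
# the anchor, loaded at the connection point with the mobile arm.  Internal
# loads follow from rigid statics of the tip load; the strain energy keeps
# tension, torsion and bending (Euler-Bernoulli, shear deformation
# neglected); deflections are exact derivatives of the quadratic energy.

#' Rectangular-section properties
#'
#' Area, bending second moment and Saint-Venant torsion constant of a
#' `b x h` rectangle.  The torsion constant uses the classical tanh series
#' \deqn{J = \frac{bh^3}{3}\left(1 - \frac{192h}{\pi^5 b}\sum_{m=0}^{M}
#'   \frac{\tanh[(2m+1)\pi b/(2h)]}{(2m+1)^5}\right),}
#' evaluated with the longer side in the `b` slot so the series converges
#' from either argument order.
#'
#' @param b section width (m).
#' @param h section height (m).
#' @param series_terms number of series terms (M + 1).
#' @return list with `A` (m^2), `I` = b h^3/12 (m^4), `J` (m^4).
#' @export
section_properties <- function(b, h, series_terms = 16L) {
  .check_positive(b, "b"); .check_positive(h, "h")
  if (series_terms < 1) stop("series_terms must be >= 1", call. = FALSE)
  I <- b * h^3 / 12
  # torsion constant is symmetric in the two sides; series form wants the
  # long side multiplying the sum argument
  bb <- max(b, h); hh <- min(b, h)
  m <- seq_len(series_terms) - 1L
  S <- sum(tanh((2 * m + 1) * pi * bb / (2 * hh)) / (2 * m + 1)^5)
  J <- (bb * hh^3 / 3) * (1 - (192 * hh) / (pi^5 * bb) * S)
  list(A = b * h, I = I, J = J)
}

# node positions of the chain (anchor at origin), one row per node
.chain_nodes <- function(beams) {
  p <- matrix(0, nrow = length(beams) + 1L, ncol = 3L)
  for (i in seq_along(beams)) {
    p[i + 1L, ] <- p[i, ] + beams[[i]]$L * beams[[i]]$axis
  }
  p
}

# strain energy of the chain under a 6-component tip load
# load6 = c(Fx, Fy, Fz, Mx, My, Mz)
.chain_energy <- function(beams, load6, E, G, series_terms) {
  p <- .chain_nodes(beams)
  tip <- p[nrow(p), ]
  Fv <- load6[1:3]
  Mv <- load6[4:6]
  U <- 0
  zhat <- c(0, 0, 1)
  for (i in seq_along(beams)) {
    bm <- beams[[i]]
    t <- bm$axis
    n <- c(-t[2], t[1], 0)                      # z x t, in-plane normal
    sp <- section_properties(bm$b, bm$h, series_terms)
    In <- bm$b * bm$h^3 / 12                    # out-of-plane bending
    Iz <- bm$h * bm$b^3 / 12                    # in-plane bending
    # internal moment at arc length s from the segment start:
    # M(s) = Mv + (tip - r(s)) x Fv, linear in s
    r0 <- p[i, ]
    d0 <- tip - r0
    M0 <- Mv + c(d0[2] * Fv[3] - d0[3] * Fv[2],
                 d0[3] * Fv[1] - d0[1] * Fv[3],
                 d0[1] * Fv[2] - d0[2] * Fv[1])
    # dM/ds = -t x Fv
    M1 <- -c(t[2] * Fv[3] - t[3] * Fv[2],
             t[3] * Fv[1] - t[1] * Fv[3],
             t[1] * Fv[2] - t[2] * Fv[1])
    L <- bm$L
    int_sq <- function(a0, a1) L * (a0^2 + a0 * a1 * L + a1^2 * L^2 / 3)
    N_ax <- sum(Fv * t)                          # constant axial force
    U <- U +
      N_ax^2 * L / (2 * E * sp$A) +
      int_sq(sum(M0 * t), sum(M1 * t)) / (2 * G * sp$J) +
      int_sq(sum(M0 * n), sum(M1 * n)) / (2 * E * In) +
      int_sq(sum(M0 * zhat), sum(M1 * zhat)) / (2 * E * Iz)
  }
  U
}

#' Strain energy of a serpentine chain under a tip load
#'
#' Total elastic strain energy (tension + torsion + two-plane bending) of
#' the beam chain, with internal force and moment diagrams obtained by
#' rigid statics from the load applied at the free (connection) end.
#'
#' @param beams list of [beam_segment()], anchor to connection point.
#' @param load a [load_case()].
#' @param E Young modulus (Pa).
#' @param nu_poly Poisson ratio (shear modulus `G = E / (2(1+nu))`).
#' @param series_terms torsion-series truncation.
#' @return strain energy (J).
#' @export
strain_energy <- function(beams, load, E = 160e9, nu_poly = 0.23,
                          series_terms = 16L) {
  if (!length(beams) ||
      !all(vapply(beams, inherits, logical(1), "beam_segment"))) {
    stop("'beams' must be a non-empty list of beam segments", call. = FALSE)
  }
  stopifnot(inherits(load, "load_case"))
  G <- E / (2 * (1 + nu_poly))
  .chain_energy(beams, unlist(load[c("Fx", "Fy", "Fz", "Mx", "My", "Mz")]),
                E, G, series_terms)
}

# 6x6 tip compliance matrix of a single chain (exact Hessian of the
# quadratic energy, assembled from unit-load energies)
.chain_compliance <- function(beams, E, G, series_terms) {
  Cm <- matrix(0, 6, 6)
  Ue <- numeric(6)
  for (i in 1:6) {
    e <- numeric(6); e[i] <- 1
    Ue[i] <- .chain_energy(beams, e, E, G, series_terms)
    Cm[i, i] <- 2 * Ue[i]
  }
  for (i in 1:5) {
    for (j in (i + 1):6) {
      e <- numeric(6); e[i] <- 1; e[j] <- 1
      Cij <- .chain_energy(beams, e, E, G, series_terms) - Ue[i] - Ue[j]
      Cm[i, j] <- Cij
      Cm[j, i] <- Cij
    }
  }
  dimnames(Cm) <- rep(list(c("Fx", "Fy", "Fz", "Mx", "My", "Mz")), 2)
  Cm
}

#' Castigliano stiffness of the serpentine suspension
#'
#' Tip stiffnesses of the two-spring assembly from the energy method: each
#' generalized deflection is the derivative of the strain energy with
#' respect to its conjugate load (evaluated exactly from the quadratic
#' form), and the two mirrored springs act in parallel, doubling every
#' stiffness.
#'
#' @param suspension a [suspension_model()] in `castigliano` mode.
#' @param series_terms torsion-series truncation.
#' @return a [stiffness_set()] (assembly totals).
#' @export
castigliano_stiffness <- function(suspension, series_terms = 16L) {
  stopifnot(inherits(suspension, "suspension_model"))
  if (suspension$mode != "castigliano") {
    stop("suspension is not in castigliano mode", call. = FALSE)
  }
  E <- suspension$E
  G <- E / (2 * (1 + suspension$nu_poly))
  Cm <- .chain_compliance(suspension$beams, E, G, series_terms)
  # single-spring stiffness = 1 / direct compliance; assembly = 2x
  stiffness_set(k_tz = 2 / Cm["Mz", "Mz"],
                k_tx = 2 / Cm["Mx", "Mx"],
                k_Fx = 2 / Cm["Fx", "Fx"],
                k_Fy = 2 / Cm["Fy", "Fy"],
                k_Fz = 2 / Cm["Fz", "Fz"])
}

#' Suspension reaction torque
#'
#' Linear restoring torque of the serpentine assembly, `Ts = k_tz * theta_z`.
#'
#' @param k_tz rotational stiffness (N m rad^-1).
#' @param theta_z rotation (rad).
#' @return reaction torque (N m).
#' @export
reaction_torque <- function(k_tz, theta_z) {
  .check_positive(k_tz, "k_tz")
  k_tz * theta_z
}
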