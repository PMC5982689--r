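# Space-frame finite-element oracle for the serpentine suspension.
#
# Independent numerical cross-check of the Castigliano closed form: the
# chain is meshed into standard 12-dof Euler-Bernoulli space-frame elements
# (axial, Saint-Venant torsion, two-plane cubic bending, no shear area),
# clamped at the anchor, loaded at the connection point, and solved as a
# linear system.  Used by the test-suite; exact for point tip loads, so the
# mesh density only matters for the convergence study itself.

# 12x12 local stiffness of one element (local x along the beam)
.frame_element_k <- function(E, G, A, Iy, Iz, J, L) {
  k <- matrix(0, 12, 12)
  ax <- E * A / L
  to <- G * J / L
  # bending about local z (displacement v along y): dofs v1, rz1, v2, rz2
  bz <- E * Iz / L^3 * matrix(c(12, 6 * L, -12, 6 * L,
                                6 * L, 4 * L^2, -6 * L, 2 * L^2,
                                -12, -6 * L, 12, -6 * L,
                                6 * L, 2 * L^2, -6 * L, 4 * L^2), 4, 4)
  # bending about local y (displacement w along z): dofs w1, ry1, w2, ry2
  by <- E * Iy / L^3 * matrix(c(12, -6 * L, -12, -6 * L,
                                -6 * L, 4 * L^2, 6 * L, 2 * L^2,
                                -12, 6 * L, 12, 6 * L,
                                -6 * L, 2 * L^2, 6 * L, 4 * L^2), 4, 4)
  # dof order per node: ux, uy, uz, rx, ry, rz
  k[c(1, 7), c(1, 7)] <- ax * matrix(c(1, -1, -1, 1), 2, 2)
  k[c(4, 10), c(4, 10)] <- to * matrix(c(1, -1, -1, 1), 2, 2)
  iz <- c(2, 6, 8, 12); k[iz, iz] <- bz
  iy <- c(3, 5, 9, 11); k[iy, iy] <- by
  k
}

#' Space-frame beam-matrix oracle
#'
#' Assembles and solves the clamped beam chain as a space frame and returns
#' the tip deflections and rotations under the given load.  This is a
#' numerical stand-in for a beam-element FEM model and serves as the
#' independent oracle for [castigliano_stiffness()].
#'
#' @param beams list of [beam_segment()], anchor to connection point.
#' @param load a [load_case()] applied at the connection point.
#' @param E Young modulus (Pa).
#' @param nu_poly Poisson ratio.
#' @param n_elem elements per beam segment.
#' @param series_terms torsion-series truncation.
#' @return named numeric vector `c(ux, uy, uz, rx, ry, rz)` at the tip
#'   (m and rad).
#' @export
beam_matrix_oracle <- function(beams, load, E = 160e9, nu_poly = 0.23,
                               n_elem = 4L, series_terms = 16L) {
  if (!length(beams) ||
      !all(vapply(beams, inherits, logical(1), "beam_segment"))) {
    stop("'beams' must be a non-empty list of beam segments", call. = FALSE)
  }
  stopifnot(inherits(load, "load_case"))
  G <- E / (2 * (1 + nu_poly))
  # assemble in micrometre-Newton units: SI at micrometre scale mixes
  # translational and rotational stiffness entries across ~12 orders of
  # magnitude and the system becomes numerically singular
  s <- 1e6                                   # m -> um
  n_nodes <- length(beams) * n_elem + 1L
  ndof <- 6L * n_nodes
  K <- matrix(0, ndof, ndof)
  node <- 1L
  for (bm in beams) {
    t <- bm$axis
    n <- c(-t[2], t[1], 0)
    z <- c(0, 0, 1)
    R <- rbind(t, n, z)                      # local = R %*% global
    Tm <- matrix(0, 12, 12)
    for (blk in 0:3) Tm[blk * 3 + 1:3, blk * 3 + 1:3] <- R
    sp <- section_properties(bm$b, bm$h, series_terms)
    Iz <- bm$h * bm$b^3 / 12                 # in-plane bending (local z)
    Iy <- bm$b * bm$h^3 / 12                 # out-of-plane bending (local y)
    Le <- bm$L / n_elem
    ke <- t(Tm) %*% .frame_element_k(E / s^2, G / s^2, sp$A * s^2,
                                     Iy * s^4, Iz * s^4, sp$J * s^4,
                                     Le * s) %*% Tm
    for (e in seq_len(n_elem)) {
      i1 <- (node - 1L) * 6L
      i2 <- node * 6L
      idx <- c(i1 + 1:6, i2 + 1:6)
      K[idx, idx] <- K[idx, idx] + ke
      node <- node + 1L
    }
  }
  f <- numeric(ndof)
  f[(n_nodes - 1L) * 6L + 1:6] <-
    unlist(load[c("Fx", "Fy", "Fz", "Mx", "My", "Mz")]) *
    c(1, 1, 1, s, s, s)                      # moments N m -> N um
  free <- 7:ndof                             # clamp node 1
  u <- numeric(ndof)
  sol <- tryCatch(solve(K[free, free], f[free]),
                  error = function(e) stop("singular frame system: ",
                                           conditionMessage(e), call. = FALSE))
  u[free] <- sol
  out <- u[(n_nodes - 1L) * 6L + 1:6] / c(s, s, s, 1, 1, 1)  # um -> m
  names(out) <- c("ux", "uy", "uz", "rx", "ry", "rz")
  out
}
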