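# shared fixtures, all built in code

# electrodynamic comb with the published electrode dimensions, one layer
table1_comb <- function(layers = 1L, n = 20L) {
  comb_geometry(R0 = 400e-6, Wf = 2e-6, g = 2e-6, h = 7e-6,
                n = n, layers = layers, theta0 = 6 * pi / 180)
}

# reference suspension stiffness assembly (SI)
ref_stiffness <- function() {
  stiffness_set(k_tz = 49557e-12, k_tx = 11982e-12,
                k_Fx = 25.74, k_Fy = 90.76, k_Fz = 10.14)
}

ref_J_b <- 5.86e-15  # kg m^2

# directly assembled Duffing parameter sets for dynamics tests
make_params <- function(J_b = ref_J_b, c_amT = 2.7e-13,
                        k_lin = 49557e-12, alpha_b = 0, B = 1e-13) {
  structure(list(J_b = J_b, c_amT = c_amT, k_lin = k_lin,
                 alpha_b = alpha_b, B = B,
                 f_n = sqrt(k_lin / J_b) / (2 * pi), fit = NULL),
            class = "duffing_params")
}

# random slender serpentine chains for property-based spring tests
random_serpentine <- function(seed) {
  set.seed(seed)
  n_seg <- sample(3:7, 1)
  b <- runif(1, 2e-6, 4e-6)
  h <- runif(1, 5e-6, 8e-6)
  dirs <- list(c(0, 1), c(1, 0), c(0, -1), c(1, 0))
  lapply(seq_len(n_seg), function(i) {
    beam_segment(L = runif(1, 80e-6, 200e-6), b = b, h = h,
                 axis = dirs[[(i - 1) %% 4 + 1]])
  })
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(max(abs(actual / expected - 1)), rel)
}
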