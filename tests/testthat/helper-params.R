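# Reference parameter sets used across tests: the fitted corpus callosum
# histology statistics and the identified Ogden constants.

cc_gev <- function() gev_params(0.426, 0.200, -0.305)
cc_beta <- function() beta_params(9.155, 1.275)
cc_sp <- function() cc_structural_params()
cc_mp <- function() matrix_params(353.5, -21.5)
cc_fp <- function() fiber_params(80.8, 62.3)

# a deterministic single-fiber network: straight axial fiber spanning the
# cube, off the mesh gridlines
single_axial_fiber_net <- function(La = 5, d = 0.6, Ps = 1, y = 2.6, z = 2.6) {
  fiber_network(La, data.frame(anchor_x = 0, anchor_y = y, anchor_z = z,
                               Nx = 1, Ny = 0, Nz = 0, L0 = La, d = d, Ps = Ps))
}

# an oblique fiber that recruits under 10% axial stretch (Ps = 0.93)
oblique_fiber_net <- function(La = 5) {
  N <- c(0.95, 0.2, sqrt(1 - 0.95^2 - 0.2^2))
  fiber_network(La, data.frame(anchor_x = 0.1, anchor_y = 0.5, anchor_z = 0.3,
                               Nx = N[1], Ny = N[2], Nz = N[3],
                               L0 = 3, d = 0.8, Ps = 0.93))
}

conj <- function(P, mode, amount) sum(P * wmrve:::macro_F_dot(mode, amount))

random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
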