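# Affine homogenization: loading-mode kinematics, rule-of-mixtures
# assembly, energy consistency and objectivity.

test_that("macroscopic deformation gradients of the seven modes", {
  F <- macro_F("tension_FF", 1.2)
  expect_equal(F, diag(c(1.2, 1.2^-0.5, 1.2^-0.5)))
  expect_equal(det(F), 1, tolerance = 1e-12)
  expect_equal(det(macro_F("compression_FF", 0.8)), 1, tolerance = 1e-12)
  # TT modes stretch the transverse axis
  expect_equal(macro_F("tension_TT", 1.1)[2, 2], 1.1)
  # zero shear is the identity; shear dyad convention
  expect_equal(macro_F("shear_FT", 0), diag(3))
  expect_equal(macro_F("shear_FT", 0.2)[1, 2], 0.2)
  expect_equal(macro_F("shear_TF", 0.2)[2, 1], 0.2)
  expect_equal(macro_F("shear_TT", 0.2)[2, 3], 0.2)
  expect_error(macro_F("tension_XX", 1.1), class = "wmrve_invalid")
})

test_that("fiber stretch is the norm of the pushed-forward direction", {
  expect_equal(fiber_stretch(diag(3), c(1, 0, 0)), 1)
  F <- macro_F("tension_FF", 1.2)
  expect_equal(fiber_stretch(F, c(1, 0, 0)), 1.2, tolerance = 1e-14)
  set.seed(3)
  Fr <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
  N <- c(0.3, -0.5, sqrt(1 - 0.09 - 0.25))
  C <- t(Fr) %*% Fr
  expect_equal(fiber_stretch(Fr, N), sqrt(drop(t(N) %*% C %*% N)),
               tolerance = 1e-12)
})

test_that("homogenize assembles the rule of mixtures correctly", {
  net <- generate_rve(cc_sp(), 10, seed = 11)
  mp <- cc_mp(); fp <- cc_fp()
  # identity: everything zero
  h0 <- homogenize(net, diag(3), mp, fp)
  expect_equal(h0$P_total, matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(h0$recruited_fraction, 0)
  # P_total = P_matrix + v_f P_fiber componentwise
  F <- macro_F("tension_FF", 1.15)
  h <- homogenize(net, F, mp, fp)
  expect_equal(h$P_total, h$P_matrix + net$achieved_vf * h$P_fiber,
               tolerance = 1e-12)
  # aligned fibers: zero fiber stress in compression FF and tension TT
  hc <- homogenize(net, macro_F("compression_FF", 0.8), mp, fp)
  expect_equal(hc$P_fiber, matrix(0, 3, 3))
  ht <- homogenize(net, macro_F("tension_TT", 1.2), mp, fp)
  expect_equal(ht$P_fiber, matrix(0, 3, 3))
  # fiber-free limit: P_total equals the matrix stress exactly
  empty <- fiber_network(10, net$fibers[0, ])
  he <- homogenize(empty, F, mp, fp)
  expect_identical(he$P_total, matrix_pk1(F, mp))
})

test_that("response curves rise monotonically with growing recruitment", {
  net <- generate_rve(cc_sp(), 15, seed = 12)
  mp <- cc_mp(); fp <- cc_fp()
  cv <- response_curve(net, "tension_FF", max_amount = 1.2, mp = mp, fp = fp,
                       n_steps = 9)
  expect_equal(cv$P_total[1], 0, tolerance = 1e-10)
  expect_true(all(diff(cv$P_total) > 0))
  expect_true(all(diff(cv$recruited_fraction) >= 0))
  # work-conjugate decomposition holds on the reported components
  expect_equal(cv$P_total, cv$P_matrix + net$achieved_vf * cv$P_fiber,
               tolerance = 1e-10)
  # matrix conjugate component equals the analytic incompressible curve
  expect_equal(cv$P_matrix,
               uniaxial_incompressible_nominal(cv$amount, mp$mu, mp$alpha),
               tolerance = 1e-9)
  # anisotropy: tension along fibers stiffer than transverse at 15%
  cvtt <- response_curve(net, "tension_TT", max_amount = 1.15, mp = mp,
                         fp = fp, n_steps = 4)
  cvff <- response_curve(net, "tension_FF", max_amount = 1.15, mp = mp,
                         fp = fp, n_steps = 4)
  expect_gte(cvff$P_total[4], cvtt$P_total[4])
})

test_that("affine stress is work-conjugate to the homogenized energy", {
  net <- generate_rve(cc_sp(), 8, seed = 13)
  mp <- cc_mp(); fp <- cc_fp()
  lams <- seq(1, 1.12, length.out = 241)
  conj_vals <- numeric(length(lams)); energies <- numeric(length(lams))
  for (i in seq_along(lams)) {
    h <- homogenize(net, macro_F("tension_FF", lams[i]), mp, fp)
    conj_vals[i] <- conj(h$P_total, "tension_FF", lams[i])
    energies[i] <- h$energy
  }
  # trapezoid integral of the conjugate stress equals the energy change
  W_int <- cumsum(c(0, diff(lams) * (head(conj_vals, -1) + tail(conj_vals, -1)) / 2))
  expect_equal(W_int[length(lams)], energies[length(lams)] - energies[1],
               tolerance = 1e-4 * abs(energies[length(lams)]))
})

test_that("homogenization is objective under joint rotation", {
  net <- generate_rve(cc_sp(), 8, seed = 14)
  mp <- cc_mp(); fp <- cc_fp()
  R <- random_rotation(15)
  F <- macro_F("tension_FF", 1.12)
  h <- homogenize(net, F, mp, fp)
  # rotate every fiber direction and the loading by the same R
  fib_r <- net$fibers
  Nr <- as.matrix(net$fibers[, c("Nx", "Ny", "Nz")]) %*% t(R)
  fib_r$Nx <- Nr[, 1]; fib_r$Ny <- Nr[, 2]; fib_r$Nz <- Nr[, 3]
  net_r <- net; net_r$fibers <- fib_r
  hr <- homogenize(net_r, R %*% F %*% t(R), mp, fp)
  expect_equal(hr$P_total, R %*% h$P_total %*% t(R), tolerance = 1e-10)
  expect_equal(hr$recruited_fraction, h$recruited_fraction)
})

test_that("zero-lateral-stress kinematics reproduces true uniaxial response", {
  empty <- fiber_network(10, data.frame(anchor_x = numeric(0), anchor_y = numeric(0),
                                        anchor_z = numeric(0), Nx = numeric(0),
                                        Ny = numeric(0), Nz = numeric(0),
                                        L0 = numeric(0), d = numeric(0),
                                        Ps = numeric(0)))
  mp <- cc_mp(); fp <- cc_fp()
  cv <- response_curve(empty, "tension_FF", max_amount = 1.1, mp = mp, fp = fp,
                       n_steps = 5, lateral = "zero_stress")
  ref <- uniaxial_incompressible_nominal(cv$amount, mp$mu, mp$alpha)
  # matches the incompressible closed form up to the nu = 0.49 compressibility
  expect_lt(max(abs(cv$P_total[-1] - ref[-1]) / ref[-1]), 0.01)
  # only defined for affine uniaxial sweeps
  expect_error(response_curve(empty, "shear_TF", max_amount = 0.2, mp = mp,
                              fp = fp, lateral = "zero_stress"),
               class = "wmrve_invalid")
})

test_that("curve files round-trip with their metadata", {
  net <- generate_rve(cc_sp(), 6, seed = 16)
  cv <- response_curve(net, "shear_TF", max_amount = 0.2, mp = cc_mp(),
                       fp = cc_fp(), n_steps = 5)
  path <- tempfile(fileext = ".csv")
  write_curve(cv, path, metadata = list(seed = 16))
  back <- read_curve(path)
  expect_equal(as.data.frame(back), as.data.frame(cv), tolerance = 1e-12)
  expect_equal(attr(back, "mode"), "shear_TF")
  expect_equal(attr(back, "engine"), "affine")
})
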