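# Constitutive laws: recruitment kinematics, fiber and matrix energies and
# their stress derivatives, the incompressible uniaxial closed form.

test_that("recruitment split follows the piecewise rule", {
  r <- recruitment_split(1, 0.9)
  expect_equal(c(r$lambda_r, r$lambda_t), c(1, 1))
  # exactly at the recruitment point
  r2 <- recruitment_split(1 / 0.9, 0.9)
  expect_equal(r2$lambda_r, 1 / 0.9, tolerance = 1e-15)
  expect_equal(r2$lambda_t, 1, tolerance = 1e-15)
  # beyond recruitment: lambda_t = lambda * Ps
  r3 <- recruitment_split(1.2, 0.9)
  expect_equal(r3$lambda_t, 1.08, tolerance = 1e-12)
  expect_equal(r3$lambda_r * r3$lambda_t, 1.2, tolerance = 1e-12)
  # compression treated as unrecruited
  r4 <- recruitment_split(0.8, 0.9)
  expect_equal(r4$lambda_t, 1)
  expect_error(recruitment_split(1, 1.1), class = "wmrve_invalid")
  expect_error(recruitment_split(-0.1, 0.9), class = "wmrve_invalid")
})

test_that("fiber energy is zero before recruitment and continuous at it", {
  fp <- cc_fp()
  Ps <- 0.878
  expect_equal(fiber_energy(seq(0.5, 1 / Ps, length.out = 9), Ps, fp),
               rep(0, 9))
  eps <- 1e-9
  expect_lt(abs(fiber_energy(1 / Ps + eps, Ps, fp) -
                  fiber_energy(1 / Ps - eps, Ps, fp)), 1e-12)
  # frozen value checked against an independent symbolic evaluation
  expect_equal(fiber_energy(1.15, 0.878, fp), 0.012710068590224,
               tolerance = 1e-12)
})

test_that("fiber stress is the energy derivative, zero then increasing", {
  fp <- cc_fp()
  Ps <- 0.878
  expect_equal(fiber_nominal_stress(c(0.9, 1, 1 / Ps), Ps, fp), rep(0, 3))
  lams <- seq(1 / Ps + 0.005, 1.2, length.out = 20)
  s <- fiber_nominal_stress(lams, Ps, fp)
  expect_true(all(s > 0))
  expect_true(all(diff(s) > 0))
  # central finite difference of the energy
  h <- 1e-6
  fd <- (fiber_energy(lams + h, Ps, fp) - fiber_energy(lams - h, Ps, fp)) / (2 * h)
  expect_equal(s, fd, tolerance = 1e-6)
  # tangent stiffness consistent with the stress derivative
  kfd <- (fiber_nominal_stress(lams + h, Ps, fp) -
            fiber_nominal_stress(lams - h, Ps, fp)) / (2 * h)
  expect_equal(fiber_stiffness(lams, Ps, fp), kfd, tolerance = 1e-5)
})

test_that("matrix energy matches closed forms and is objective", {
  mp_inc <- matrix_params(353.5, -21.5, incompressible = TRUE)
  expect_equal(matrix_energy(diag(3), mp_inc), 0, tolerance = 1e-14)
  # isochoric uniaxial 1.1, frozen symbolic value
  F <- diag(c(1.1, 1.1^-0.5, 1.1^-0.5))
  expect_equal(matrix_energy(F, mp_inc), 4.130680033556686, tolerance = 1e-12)
  # objectivity: invariant under rotation from the left
  R <- random_rotation(11)
  mp <- cc_mp()
  Fr <- diag(3) + matrix(c(0.05, 0.02, 0, -0.01, -0.03, 0.02, 0, 0.01, 0.04), 3)
  expect_equal(matrix_energy(R %*% Fr, mp), matrix_energy(Fr, mp),
               tolerance = 1e-10)
  # isotropy: invariant under rotation from the right
  expect_equal(matrix_energy(Fr %*% R, mp), matrix_energy(Fr, mp),
               tolerance = 1e-10)
  expect_error(matrix_energy(diag(c(-1, 1, 1)), mp), class = "wmrve_invalid")
})

test_that("matrix nominal stress is the energy gradient (incl. repeated stretches)", {
  mp <- cc_mp()
  expect_equal(matrix_pk1(diag(3), mp), matrix(0, 3, 3), tolerance = 1e-12)
  fd_pk1 <- function(F) {
    h <- 1e-7
    P <- matrix(0, 3, 3)
    for (i in 1:3) for (J in 1:3) {
      Fp <- F; Fp[i, J] <- Fp[i, J] + h
      Fm <- F; Fm[i, J] <- Fm[i, J] - h
      P[i, J] <- (matrix_energy(Fp, mp) - matrix_energy(Fm, mp)) / (2 * h)
    }
    P
  }
  set.seed(21)
  for (k in 1:5) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.06), 3)
    expect_equal(matrix_pk1(F, mp), fd_pk1(F), tolerance = 1e-6)
  }
  # equal-biaxial state: two coincident principal stretches, no NaN
  Feb <- diag(c(1.08, 1.08, 1 / 1.08^2))
  Peb <- matrix_pk1(Feb, mp)
  expect_false(any(is.na(Peb)))
  expect_equal(Peb, fd_pk1(Feb), tolerance = 1e-6)
})

test_that("initial Poisson's ratio follows from the initial moduli", {
  # default compliance D = 0.04/mu gives the nearly incompressible 0.49
  expect_equal(round(initial_poisson(cc_mp()), 2), 0.49)
  expect_equal(initial_poisson(cc_mp()), 0.49006622516556,
               tolerance = 1e-10)
  # K = mu: nu = 0.125
  expect_equal(initial_poisson(matrix_params(100, 2, D = 0.02)), 0.125,
               tolerance = 1e-12)
  # incompressible flag and the D -> 0 limit
  expect_identical(initial_poisson(matrix_params(100, 2, incompressible = TRUE)), 0.5)
  expect_equal(initial_poisson(matrix_params(100, 2, D = 1e-12)), 0.5,
               tolerance = 1e-9)
})

test_that("incompressible uniaxial closed form has the Ogden small-strain limit", {
  mu <- 353.5; al <- -21.5
  expect_equal(uniaxial_incompressible_nominal(1, mu, al), 0, tolerance = 1e-12)
  # slope at identity equals 3 mu (incompressible Young's modulus)
  h <- 1e-6
  slope <- (uniaxial_incompressible_nominal(1 + h, mu, al) -
              uniaxial_incompressible_nominal(1 - h, mu, al)) / (2 * h)
  expect_equal(slope, 3 * mu, tolerance = 1e-3)
  # compression gives negative nominal stress for mu > 0
  expect_lt(uniaxial_incompressible_nominal(0.95, mu, al), 0)
  expect_lt(uniaxial_incompressible_nominal(0.95, mu, 8), 0)
})

test_that("material parameter JSON round-trips", {
  path <- tempfile(fileext = ".json")
  write_material_params(cc_mp(), cc_fp(), path)
  back <- read_material_params(path)
  expect_equal(unclass(back$matrix), unclass(cc_mp()))
  expect_equal(unclass(back$fiber), unclass(cc_fp()))
})
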