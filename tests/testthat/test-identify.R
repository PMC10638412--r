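# Two-step inverse identification: objective function, per-step recovery
# on noiseless synthetic data, invariances and failure modes.

analytic_matrix_curves <- function(mu, alpha, n = 21) {
  lamc <- seq(0.90, 1.0, length.out = n)
  lamt <- seq(1.0, 1.10, length.out = n)
  experiment_curves(list(
    compression_FF = data.frame(amount = lamc,
                                stress = uniaxial_incompressible_nominal(lamc, mu, alpha)),
    tension_TT = data.frame(amount = lamt,
                            stress = uniaxial_incompressible_nominal(lamt, mu, alpha))))
}

test_that("chi2 is the plain sum of squared residuals", {
  a <- experiment_curves(list(tension_FF = data.frame(amount = c(1, 1.1),
                                                      stress = c(0, 10))))
  expect_equal(chi2(a, a), 0)
  b <- experiment_curves(list(tension_FF = data.frame(amount = c(1, 1.1),
                                                      stress = c(0, 12))))
  expect_equal(chi2(a, b), 4)
  # permutation invariance over points (sum over modes and points)
  c1 <- experiment_curves(list(
    tension_FF = data.frame(amount = c(1, 1.05, 1.1), stress = c(0, 5, 10)),
    shear_TF = data.frame(amount = c(0, 0.2), stress = c(0, 3))))
  c2 <- experiment_curves(list(
    shear_TF = data.frame(amount = c(0, 0.2), stress = c(1, 2)),
    tension_FF = data.frame(amount = c(1, 1.05, 1.1), stress = c(1, 4, 12))))
  expect_equal(chi2(c1, c2), 1 + 1 + 4 + 1 + 1)
  d <- experiment_curves(list(shear_TT = data.frame(amount = c(0, 1),
                                                    stress = c(0, 1))))
  expect_error(chi2(a, d), class = "wmrve_invalid")
})

test_that("step 1 recovers the matrix parameters from noiseless curves", {
  exp1 <- analytic_matrix_curves(353.5, -21.5)
  fit <- fit_matrix(exp1)
  expect_lt(abs(fit$mu - 353.5) / 353.5, 0.01)
  expect_lt(abs(fit$alpha - (-21.5)) / 21.5, 0.01)
  expect_lt(fit$chi2, 1e-10 * sum(sapply(exp1, function(cv) sum(cv$stress^2))))
  # all interior starts agree on the optimum (multistart invariance)
  pars <- t(sapply(fit$starts, `[[`, "par"))
  expect_lt(max(abs(pars[, 1] - 353.5)), 0.5)
  expect_lt(max(abs(pars[, 2] + 21.5)), 0.05)
  expect_error(fit_matrix(experiment_curves(list(
    tension_FF = data.frame(amount = c(1, 1.1), stress = c(0, 1))))),
    class = "wmrve_invalid")
})

test_that("step 2 recovers the fiber parameters on the same network", {
  net <- generate_rve(cc_sp(), 10, seed = 51)
  mp <- cc_mp(); fp <- cc_fp()
  lam <- seq(1, 1.10, length.out = 21)
  sim <- response_curve(net, "tension_FF", mp = mp, fp = fp, amounts = lam)
  exp2 <- experiment_curves(list(tension_FF = data.frame(amount = lam,
                                                         stress = sim$P_total)))
  fit <- fit_fibers(exp2, mp, net)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$mu - 80.8) / 80.8, 0.02)
  expect_lt(abs(fit$alpha - 62.3) / 62.3, 0.02)
})

test_that("unrecruited data range is flagged non-identifiable", {
  # two tortuous fibers recruiting only beyond 17% stretch
  net <- fiber_network(10, data.frame(
    anchor_x = c(0, 0), anchor_y = c(3.1, 6.2), anchor_z = c(4.4, 5.7),
    Nx = 1, Ny = 0, Nz = 0, L0 = 10, d = c(0.5, 0.6), Ps = c(0.85, 0.82)))
  mp <- cc_mp()
  lam <- seq(1, 1.10, length.out = 8)
  stress <- uniaxial_incompressible_nominal(lam, mp$mu, mp$alpha)
  exp2 <- experiment_curves(list(tension_FF = data.frame(amount = lam,
                                                         stress = stress)))
  expect_warning(fit <- fit_fibers(exp2, mp, net, starts = list(c(100, 40))),
                 "not identifiable")
  expect_false(fit$identifiable)
})

test_that("identification is scale invariant", {
  exp1 <- analytic_matrix_curves(353.5, -21.5)
  k <- 1000
  scaled <- experiment_curves(lapply(unclass(exp1), function(cv) {
    cv$stress <- cv$stress * k; cv
  }))
  fit <- fit_matrix(scaled, bounds = list(lower = c(50 * k, -50),
                                          upper = c(5000 * k, 50)))
  expect_lt(abs(fit$mu - 353.5 * k) / (353.5 * k), 0.01)
  expect_lt(abs(fit$alpha - (-21.5)) / 21.5, 0.01)
})

test_that("the two-step pipeline closes on its own synthetic data", {
  cfg <- synthetic_config(cc_mp(), cc_fp(), cc_sp(), La = 10, noise_sd = 0,
                          seed = 53)
  ex <- make_experiment(cfg)
  res <- identify_two_step(ex, attr(ex, "network"))
  expect_lt(abs(res$matrix_fit$mu - 353.5) / 353.5, 0.01)
  expect_lt(abs(res$matrix_fit$alpha + 21.5) / 21.5, 0.01)
  expect_lt(abs(res$fiber_fit$mu - 80.8) / 80.8, 0.02)
  expect_lt(abs(res$fiber_fit$alpha - 62.3) / 62.3, 0.02)
  # rerun is bit-identical (stored seeds, deterministic optimizer)
  ex2 <- make_experiment(cfg)
  res2 <- identify_two_step(ex2, attr(ex2, "network"))
  expect_identical(res$chi2, res2$chi2)
  expect_identical(unclass(res$fiber_params), unclass(res2$fiber_params))
  # missing tension_FF: step 2 fails
  part <- experiment_curves(unclass(ex)[c("compression_FF", "tension_TT")])
  expect_error(identify_two_step(part, attr(ex, "network")),
               class = "wmrve_invalid")
})

test_that("experiment curves round-trip through CSV + manifest", {
  cfg <- synthetic_config(cc_mp(), cc_fp(), cc_sp(), La = 8, noise_sd = 0.05,
                          seed = 54)
  ex <- make_experiment(cfg)
  dir <- tempfile()
  write_experiment(ex, dir)
  back <- read_experiment(dir)
  expect_equal(lapply(unclass(back), as.data.frame),
               lapply(unclass(ex), as.data.frame), tolerance = 1e-12)
})
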