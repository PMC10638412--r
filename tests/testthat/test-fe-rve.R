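# Periodic finite-element engine: meshing, fiber embedding, constraint
# structure, solver correctness against closed forms, Hill-Mandel.

test_that("structured meshes tile the cube exactly", {
  m <- build_mesh(5, 1.25)
  expect_equal(nrow(m$elems), 64L)
  expect_equal(nrow(m$nodes), 125L)
  m2 <- build_mesh(25, 1.25)
  expect_equal(nrow(m2$elems), 8000L)
  # node coordinates exact multiples of h
  expect_true(all(abs(m$nodes / m$h - round(m$nodes / m$h)) < 1e-12))
  expect_error(build_mesh(5, 6), class = "wmrve_invalid")
  expect_error(build_mesh(5, 1.3), class = "wmrve_invalid")
})

test_that("fibers are cut exactly at host-element faces", {
  mesh <- build_mesh(5, 1.25)
  # axial fiber through element interiors: one segment per element crossed
  net <- single_axial_fiber_net(5, y = 2.6, z = 2.6)
  tr <- embed_fibers(net, mesh)
  expect_equal(nrow(tr$segments), 4L)
  expect_equal(sum(tr$segments$L0), 5, tolerance = 1e-10)
  # local coordinates inside the reference cube
  expect_true(all(abs(as.matrix(tr$nodes[, c("xi1", "xi2", "xi3")])) <= 1 + 1e-12))
  # oblique fiber: segment count equals grid-plane crossings + 1
  # (ray-marching oracle)
  N <- c(0.8, 0.36, sqrt(1 - 0.8^2 - 0.36^2))
  p1 <- c(0.3, 0.4, 0.7); L0 <- 4.5
  netd <- fiber_network(5, data.frame(anchor_x = p1[1], anchor_y = p1[2],
                                      anchor_z = p1[3], Nx = N[1], Ny = N[2],
                                      Nz = N[3], L0 = L0, d = 0.5, Ps = 0.9))
  trd <- embed_fibers(netd, mesh)
  crossings <- 0L
  for (ax in 1:3) {
    tc <- ((0:4) * 1.25 - p1[ax]) / N[ax]
    crossings <- crossings + sum(tc > 1e-9 & tc < L0 - 1e-9)
  }
  expect_equal(nrow(trd$segments), crossings + 1L)
  expect_equal(sum(trd$segments$L0), L0, tolerance = 1e-10)
  # fiber outside the cube is rejected
  netb <- fiber_network(5, data.frame(anchor_x = 4, anchor_y = 2, anchor_z = 2,
                                      Nx = 1, Ny = 0, Nz = 0, L0 = 3,
                                      d = 0.5, Ps = 1))
  expect_error(embed_fibers(netb, mesh), class = "wmrve_invalid")
})

test_that("periodic constraints pair each dependent node exactly once", {
  mesh <- build_mesh(5, 1.25)
  F <- macro_F("shear_FT", 0.1)
  pc <- periodic_constraints(mesh, F)
  n <- mesh$n
  n_dep <- (n + 1)^3 - n^3
  expect_equal(sum(pc$master_of > 0), n_dep)
  expect_equal(pc$n_constraints, 3L * n_dep)
  # masters are never dependent
  expect_true(all(pc$master_of[pc$master_of > 0] != which(pc$master_of > 0)))
  expect_true(all(pc$master_of[unique(pc$master_of[pc$master_of > 0])] == 0))
  # the affine field satisfies every relation with zero fluctuation
  u_aff <- mesh$nodes %*% t(F - diag(3))
  dep <- which(pc$master_of > 0)
  gap <- u_aff[dep, ] - u_aff[pc$master_of[dep], ] -
    pc$delta[dep, ] %*% t(F - diag(3))
  expect_lt(max(abs(gap)), 1e-12)
})

test_that("fiber-free periodic RVE reproduces the homogeneous closed form", {
  mesh <- build_mesh(5, 1.25)
  mp <- cc_mp(); fp <- cc_fp()
  for (mode_amt in list(c("shear_TF", 0.15), c("tension_FF", 1.1))) {
    F <- macro_F(mode_amt[1], as.numeric(mode_amt[2]))
    res <- solve_rve(mesh, NULL, periodic_constraints(mesh, F), mp, fp, F,
                     settings = list(n_increments = 2))
    expect_true(res$converged)
    Pref <- matrix_pk1(F, mp)
    expect_lt(max(abs(res$P_total - Pref)) / max(abs(Pref)), 1e-6)
  }
  # zero load: zero displacement and stress
  res0 <- solve_rve(mesh, NULL, NULL, mp, fp, diag(3),
                    settings = list(n_increments = 1))
  expect_true(res0$converged)
  expect_lt(max(abs(res0$U)), 1e-12)
  expect_lt(max(abs(res0$P_total)), 1e-8)
})

test_that("a single aligned embedded fiber matches the affine rule of mixtures", {
  mesh <- build_mesh(5, 1.25)
  mp <- cc_mp(); fp <- cc_fp()
  net <- single_axial_fiber_net(5)
  truss <- embed_fibers(net, mesh)
  F <- macro_F("tension_FF", 1.1)
  res <- solve_rve(mesh, truss, periodic_constraints(mesh, F), mp, fp, F,
                   settings = list(n_increments = 4))
  expect_true(res$converged)
  aff <- homogenize(net, F, mp, fp)
  c_fe <- conj(res$P_total, "tension_FF", 1.1)
  c_af <- conj(aff$P_total, "tension_FF", 1.1)
  expect_lt(abs(c_fe - c_af) / abs(c_af), 0.01)
})

test_that("Hill-Mandel: averaged stress power equals the energy change", {
  # oblique recruited fiber -> genuinely nonuniform fluctuation field
  mesh <- build_mesh(5, 1.25)
  mp <- cc_mp(); fp <- cc_fp()
  net <- oblique_fiber_net(5)
  truss <- embed_fibers(net, mesh)
  lams <- seq(1, 1.1, length.out = 11)
  W <- numeric(length(lams)); Pc <- numeric(length(lams))
  for (i in seq_along(lams)) {
    F <- macro_F("tension_FF", lams[i])
    res <- solve_rve(mesh, truss, periodic_constraints(mesh, F), mp, fp, F,
                     settings = list(n_increments = 2))
    expect_true(res$converged)
    W[i] <- res$energy
    ## P_total weights the fiber average by v_f, matching the energy sum
    Pc[i] <- conj(res$P_total, "tension_FF", lams[i])
  }
  V <- 5^3
  work <- sum(diff(lams) * (head(Pc, -1) + tail(Pc, -1)) / 2) * V
  expect_equal(work, W[length(W)] - W[1],
               tolerance = 1e-3 * abs(W[length(W)] - W[1]))
})

test_that("analytic consistent tangent matches finite differences", {
  mp <- cc_mp()
  fd_tan <- function(F) {
    A <- matrix(0, 9, 9); h <- 1e-6
    for (k in 1:3) for (L in 1:3) {
      Fp <- F; Fp[k, L] <- Fp[k, L] + h
      Fm <- F; Fm[k, L] <- Fm[k, L] - h
      A[, (L - 1) * 3 + k] <- as.vector((matrix_pk1(Fp, mp) -
                                           matrix_pk1(Fm, mp)) / (2 * h))
    }
    A
  }
  set.seed(77)
  for (k in 1:3) {
    F <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
    A <- wmrve:::pk1_and_tangent(F, mp)$A9
    expect_lt(max(abs(A - fd_tan(F))) / max(abs(A)), 1e-6)
  }
  # coincident-stretch branch
  for (F in list(diag(3), diag(c(1.1, 1.1, 0.95)), diag(c(1.05, 1.05, 1.05)))) {
    A <- wmrve:::pk1_and_tangent(F, mp)$A9
    expect_false(any(is.na(A)))
    expect_lt(max(abs(A - fd_tan(F))) / max(abs(A)), 1e-6)
  }
})

test_that("mesh refinement leaves the homogenized response unchanged", {
  mp <- cc_mp(); fp <- cc_fp()
  # fiber-free: mesh-independent to solver tolerance
  netf <- fiber_network(5, data.frame(anchor_x = numeric(0), anchor_y = numeric(0),
                                      anchor_z = numeric(0), Nx = numeric(0),
                                      Ny = numeric(0), Nz = numeric(0),
                                      L0 = numeric(0), d = numeric(0),
                                      Ps = numeric(0)))
  tabf <- mesh_convergence(netf, c(2.5, 1.25), "shear_TF", 0.15, mp, fp,
                           settings = list(n_increments = 2))
  expect_true(all(tabf$converged))
  expect_lt(attr(tabf, "relative_spread"), 1e-8)
  # small fibered RVE: self-convergence below 2%
  net <- oblique_fiber_net(5)
  tab <- mesh_convergence(net, c(2.5, 1.25), "tension_FF", 1.08, mp, fp,
                          settings = list(n_increments = 2))
  expect_true(all(tab$converged))
  expect_lt(attr(tab, "relative_spread"), 0.02)
  expect_error(mesh_convergence(net, numeric(0), "tension_FF", 1.1, mp, fp),
               class = "wmrve_invalid")
})

test_that("FE and affine engines agree for a small aligned RVE at moderate stretch", {
  mp <- cc_mp(); fp <- cc_fp()
  net <- generate_rve(cc_sp(), 5, seed = 21)
  cv_fe <- response_curve(net, "tension_FF", mp = mp, fp = fp,
                          amounts = c(1, 1.05, 1.1), engine = "fe",
                          fe_opts = list(h = 1.25,
                                         settings = list(n_increments = 2)))
  cv_af <- response_curve(net, "tension_FF", mp = mp, fp = fp,
                          amounts = c(1, 1.05, 1.1))
  # affine (Taylor) kinematics is exact here up to fluctuation effects
  expect_lt(abs(cv_fe$P_total[3] - cv_af$P_total[3]) / abs(cv_af$P_total[3]),
            0.05)
})
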