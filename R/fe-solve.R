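## Total-Lagrangian Newton solver for the periodic RVE: displacement-based
## trilinear hexes (2x2x2 quadrature) carrying the nearly incompressible
## Ogden matrix law, embedded truss segments carrying the recruitment fiber
## law, periodicity and embedding imposed by exact linear-constraint
## elimination, sparse direct solve of the reduced tangent.

## ---- Ogden first-PK tangent in principal axes ---------------------------

## d^2 Psi / dlambda_a dlambda_b for the matrix law (deviatoric Ogden +
## volumetric penalty); s_a = lam_bar_a^alpha
matrix_d2psi <- function(lam, mp) {
  J <- prod(lam)
  s <- (lam * J^(-1 / 3))^mp$alpha
  Ssum <- sum(s)
  il <- 1 / lam
  ## d(s_a - Ssum/3)/dlam_b = (alpha/lam_b)(s_a d_ab - s_a/3 - s_b/3 + Ssum/9)
  D1 <- mp$alpha * (diag(s, 3) - outer(s, rep(1, 3)) / 3 -
                    outer(rep(1, 3), s) / 3 + Ssum / 9) * outer(rep(1, 3), il)
  H <- 2 * mp$mu / mp$alpha * (D1 * outer(il, rep(1, 3)) -
                               diag((s - Ssum / 3) * il^2, 3))
  if (!mp$incompressible) {
    Jl <- J * il
    ## d/dlam_b [(J-1) J/lam_a]: note J/lam_a is independent of lam_a
    H <- H + (2 / mp$D) * (outer(Jl, Jl) +
                           (J - 1) * (outer(il, Jl) - diag(Jl * il, 3)))
  }
  H
}

## A9[(J-1)*3+i, (L-1)*3+k] = dP_iJ/dF_kL at F; also returns P (3x3).
## Principal-axis form with the (S_a - S_b)/(lambda_a^2 - lambda_b^2)
## shear terms; coincident stretches (rel. diff < 1e-8) use the analytic
## limit (c_aa - c_ab)/2 to avoid catastrophic cancellation.
pk1_and_tangent <- function(F, mp) {
  s <- svd(F)
  lam <- s$d
  psi1 <- matrix_dpsi(lam, mp)
  P <- s$u %*% (psi1 * t(s$v))
  Sprin <- psi1 / lam                     # principal 2nd PK values
  H <- matrix_d2psi(lam, mp)
  ## c_ab = (1/lam_b) d S_a / d lam_b
  dS <- H / lam - diag(psi1 / lam^2, 3)   # dS_a/dlam_b  (rows a)
  cab <- sweep(dS, 2, lam, "/")
  Nv <- s$v                               # columns: principal directions N_a
  C9 <- matrix(0, 9, 9)
  vecM <- function(a, b) as.vector(outer(Nv[, a], Nv[, b]))
  for (a in 1:3) for (b in 1:3) {
    C9 <- C9 + cab[a, b] * tcrossprod(vecM(a, a), vecM(b, b))
    if (a != b) {
      gam <- if (abs(lam[a] - lam[b]) < 1e-8 * max(lam))
        (cab[a, a] - cab[a, b]) / 2
      else (Sprin[a] - Sprin[b]) / (lam[a]^2 - lam[b]^2)
      C9 <- C9 + gam * (tcrossprod(vecM(a, b), vecM(a, b)) +
                        tcrossprod(vecM(a, b), vecM(b, a)))
    }
  }
  Smat <- Nv %*% (Sprin * t(Nv))
  ## A9 = kron(S, I3) + blockwise F . C9 . F^T (avoids kronecker() overhead)
  A9 <- matrix(0, 9, 9)
  tF <- t(F)
  for (J in 1:3) {
    rJ <- (J - 1L) * 3L + 1:3
    for (L in 1:3) {
      rL <- (L - 1L) * 3L + 1:3
      A9[rJ, rL] <- F %*% C9[rJ, rL] %*% tF + diag(Smat[J, L], 3)
    }
  }
  list(P = P, A9 = A9)
}

## ---- constraint elimination ---------------------------------------------

## scatter matrix S (3*nn x 3*n_red): full nodal fluctuations from reduced
## master fluctuations (slaves copy their master, pinned node is zero)
fluctuation_scatter <- function(mesh, pc) {
  nn <- nrow(mesh$nodes)
  owner <- ifelse(pc$master_of == 0L, seq_len(nn), pc$master_of)
  masters <- setdiff(which(pc$master_of == 0L), pc$pinned)
  red_id <- integer(nn)
  red_id[masters] <- seq_along(masters)
  rows <- which(red_id[owner] > 0L)
  ii <- rep((rows - 1L) * 3L, each = 3L) + 1:3
  jj <- rep((red_id[owner[rows]] - 1L) * 3L, each = 3L) + 1:3
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(3L * nn, 3L * length(masters)))
}

## affine nodal displacement field (F - I) X, nn x 3
affine_field <- function(mesh, F) mesh$nodes %*% t(F - I3)

## ---- assembly ------------------------------------------------------------

fe_precompute <- function(mesh) {
  gp <- 1 / sqrt(3)
  xis <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  wdet <- (mesh$h / 2)^3
  Gs <- lapply(seq_len(8), function(g) hex_grads(xis[g, ], mesh$h))
  ## B (24 x 9): B[(a-1)*3+i, (J-1)*3+i] = G[a, J]
  Bs <- lapply(Gs, function(G) {
    B <- matrix(0, 24, 9)
    for (a in 1:8) for (i in 1:3) for (J in 1:3)
      B[(a - 1) * 3 + i, (J - 1) * 3 + i] <- G[a, J]
    B
  })
  list(Gs = Gs, Bs = Bs, wdet = wdet)
}

## truss-node interpolation weights onto host-element nodes (8 per node)
truss_interp <- function(truss, mesh) {
  if (is.null(truss) || !nrow(truss$segments)) return(NULL)
  W <- t(apply(as.matrix(truss$nodes[, c("xi1", "xi2", "xi3")]), 1, hex_weights))
  hosts <- truss$nodes$host
  list(W = W, conn = mesh$elems[hosts, , drop = FALSE])
}

## displacement of truss nodes from full nodal displacement U (nn x 3)
truss_disp <- function(ti, U) {
  nt <- nrow(ti$W)
  out <- matrix(0, nt, 3)
  for (a in 1:8) out <- out + ti$W[, a] * U[ti$conn[, a], , drop = FALSE]
  out
}

## internal forces (and optionally tangent triplets) of the whole model
fe_internal <- function(mesh, truss, ti, mp, fp, U, pre, tangent = TRUE,
                        settings) {
  nn <- nrow(mesh$nodes)
  fint <- matrix(0, nn, 3)
  energy <- 0
  nel <- nrow(mesh$elems)
  seg <- if (is.null(truss)) NULL else truss$segments
  nseg <- if (is.null(seg)) 0L else nrow(seg)
  ntrip <- if (tangent) nel * 576L + nseg * 2304L else 0L
  Ti <- integer(ntrip); Tj <- integer(ntrip); Tx <- numeric(ntrip)
  pos <- 0L
  dofs3 <- function(nodes) rep((nodes - 1L) * 3L, each = 3L) + 1:3
  for (e in seq_len(nel)) {
    conn <- mesh$elems[e, ]
    ue <- U[conn, , drop = FALSE]          # 8 x 3
    fe <- matrix(0, 8, 3)
    Ke <- if (tangent) matrix(0, 24, 24) else NULL
    for (g in 1:8) {
      G <- pre$Gs[[g]]
      F <- I3 + t(ue) %*% G
      if (det(F) <= 0) stop_invalid("negative Jacobian in element ", e)
      if (tangent) {
        pa <- pk1_and_tangent(F, mp)
        B <- pre$Bs[[g]]
        Ke <- Ke + (B %*% pa$A9 %*% t(B)) * pre$wdet
        P <- pa$P
      } else P <- matrix_pk1(F, mp)
      fe <- fe + (G %*% t(P)) * pre$wdet
      energy <- energy + matrix_energy(F, mp) * pre$wdet
    }
    fint[conn, ] <- fint[conn, ] + fe
    if (tangent) {
      dd <- dofs3(conn)
      idx <- pos + seq_len(576L)
      Ti[idx] <- rep(dd, times = 24L)
      Tj[idx] <- rep(dd, each = 24L)
      Tx[idx] <- as.vector(Ke)
      pos <- pos + 576L
    }
  }
  if (nseg) {
    ut <- truss_disp(ti, U)
    X <- as.matrix(truss$nodes[, c("x", "y", "z")])
    for (s in seq_len(nseg)) {
      n1 <- seg$n1[s]; n2 <- seg$n2[s]
      x <- (X[n2, ] - X[n1, ]) + (ut[n2, ] - ut[n1, ])
      l <- sqrt(sum(x^2))
      lam <- l / seg$L0[s]
      dvec <- x / l
      Pf <- fiber_nominal_stress(lam, seg$Ps[s], fp)
      kf <- fiber_stiffness(lam, seg$Ps[s], fp)
      A0 <- seg$A0[s]
      fax <- A0 * Pf * dvec
      energy <- energy + A0 * seg$L0[s] * fiber_energy(lam, seg$Ps[s], fp)
      ## scatter force: node1 -fax, node2 +fax onto host hex nodes
      w1 <- ti$W[n1, ]; c1 <- ti$conn[n1, ]
      w2 <- ti$W[n2, ]; c2 <- ti$conn[n2, ]
      fint[c1, ] <- fint[c1, ] - outer(w1, fax)
      fint[c2, ] <- fint[c2, ] + outer(w2, fax)
      if (tangent) {
        K3 <- A0 * (kf / seg$L0[s]) * tcrossprod(dvec) +
          A0 * (Pf / l) * (I3 - tcrossprod(dvec))
        if (isTRUE(settings$numerical_fiber_stiffness) && kf == 0)
          K3 <- K3 + 1e-6 * fp$mu * A0 / seg$L0[s] * tcrossprod(dvec)
        d1 <- dofs3(c1); d2 <- dofs3(c2)
        ww <- list(list(w1, d1, w1, d1,  1), list(w1, d1, w2, d2, -1),
                   list(w2, d2, w1, d1, -1), list(w2, d2, w2, d2,  1))
        for (blk in ww) {
          Kblk <- kronecker(outer(blk[[1]], blk[[3]]), K3) * blk[[5]]
          idx <- pos + seq_len(576L)
          Ti[idx] <- rep(blk[[2]], times = 24L)
          Tj[idx] <- rep(blk[[4]], each = 24L)
          Tx[idx] <- as.vector(Kblk)
          pos <- pos + 576L
        }
      }
    }
  }
  K <- NULL
  if (tangent) {
    keep <- seq_len(pos)
    K <- Matrix::sparseMatrix(i = Ti[keep], j = Tj[keep], x = Tx[keep],
                              dims = c(3L * nn, 3L * nn))
  }
  list(f = fint, K = K, energy = energy)
}

## volume-averaged stresses of a converged state
fe_average <- function(mesh, truss, ti, mp, fp, U, pre) {
  V <- mesh$La^3
  Pm <- matrix(0, 3, 3)
  for (e in seq_len(nrow(mesh$elems))) {
    ue <- U[mesh$elems[e, ], , drop = FALSE]
    for (g in 1:8) {
      F <- I3 + t(ue) %*% pre$Gs[[g]]
      Pm <- Pm + matrix_pk1(F, mp) * pre$wdet
    }
  }
  Pm <- Pm / V
  seg <- if (is.null(truss)) NULL else truss$segments
  if (is.null(seg) || !nrow(seg)) {
    return(list(P_matrix = Pm, P_fiber = matrix(0, 3, 3), P_total = Pm,
                recruited_fraction = 0, v_f = 0))
  }
  ut <- truss_disp(ti, U)
  X <- as.matrix(truss$nodes[, c("x", "y", "z")])
  Pf <- matrix(0, 3, 3)
  Vf <- sum(seg$A0 * seg$L0)
  vol <- seg$A0 * seg$L0
  rec_vol <- 0
  for (s in seq_len(nrow(seg))) {
    n1 <- seg$n1[s]; n2 <- seg$n2[s]
    Nref <- (X[n2, ] - X[n1, ]) / seg$L0[s]
    x <- (X[n2, ] - X[n1, ]) + (ut[n2, ] - ut[n1, ])
    l <- sqrt(sum(x^2))
    lam <- l / seg$L0[s]
    p <- fiber_nominal_stress(lam, seg$Ps[s], fp)
    Pf <- Pf + vol[s] * p * outer(x / l, Nref)
    if (lam >= 1 / seg$Ps[s]) rec_vol <- rec_vol + vol[s]
  }
  Pf <- unname(Pf / Vf)
  vf <- Vf / V
  list(P_matrix = Pm, P_fiber = Pf, P_total = Pm + vf * Pf,
       recruited_fraction = rec_vol / Vf, v_f = vf)
}

default_fe_settings <- function() {
  list(n_increments = 10L, max_iter = 30L, max_cuts = 4L,
       tol_rel = 1e-8, tol_abs = 1e-12, numerical_fiber_stiffness = TRUE)
}

#' Solve the periodic RVE boundary-value problem
#'
#' Total-Lagrangian Newton iteration with load stepping: the macroscopic
#' deformation gradient is ramped in equal increments (automatic halving
#' on divergence, up to `max_cuts` times). Hex elements carry the Ogden
#' matrix law with the volumetric penalty; truss segments carry the
#' recruitment fiber law (no compressive response; optional small
#' numerical stiffness when slack). Periodicity and embedding are imposed
#' by exact elimination, and the reduced tangent is factorized sparsely.
#' Convergence: residual infinity-norm below
#' `tol_rel * mu_m * La^2` (with absolute floor `tol_abs`).
#'
#' @param mesh a [build_mesh()] mesh
#' @param truss an [embed_fibers()] truss set (or `NULL` for fiber-free)
#' @param constraints a [periodic_constraints()] set for `mesh`
#' @param mp,fp material parameter objects (`mp` must have finite `D`)
#' @param F 3x3 macroscopic deformation gradient
#' @param settings optional list overriding the defaults
#'   (`n_increments`, `max_iter`, `max_cuts`, `tol_rel`, `tol_abs`,
#'   `numerical_fiber_stiffness`)
#' @return object of class `fe_result`: `converged`, nodal displacements
#'   `U`, `increments_used`, volume-averaged `P_matrix`, `P_fiber`,
#'   `P_total`, `recruited_fraction`, total `energy` (Pa um^3) and a
#'   convergence `trace`; on failure `converged = FALSE` with diagnostics
#'   (no exception is thrown)
#' @export
solve_rve <- function(mesh, truss, constraints, mp, fp, F,
                      settings = list()) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(mp, "matrix_params"))
  if (mp$incompressible)
    stop_invalid("the FE engine uses the penalty formulation; ",
                 "'mp' must have finite D")
  if (!is_square3(F) || det(F) <= 0) stop_invalid("'F' must be 3x3 with det > 0")
  if (is.null(constraints)) constraints <- periodic_constraints(mesh, F)
  st <- utils::modifyList(default_fe_settings(), settings)
  pre <- fe_precompute(mesh)
  ti <- truss_interp(truss, mesh)
  S <- fluctuation_scatter(mesh, constraints)
  nn <- nrow(mesh$nodes)
  tol <- max(st$tol_rel * mp$mu * mesh$La^2, st$tol_abs)
  ured <- numeric(ncol(S))
  trace <- list()
  t_done <- 0; dt <- 1 / st$n_increments; cuts <- 0L; increments <- 0L
  while (t_done < 1 - 1e-12) {
    t_try <- min(1, t_done + dt)
    Ft <- I3 + t_try * (F - I3)
    aff <- affine_field(mesh, Ft)
    ured_try <- ured
    ok <- FALSE
    res_hist <- numeric(0)
    for (it in seq_len(st$max_iter)) {
      U <- aff + matrix(S %*% ured_try, nn, 3, byrow = TRUE)
      out <- tryCatch(
        fe_internal(mesh, truss, ti, mp, fp, U, pre, tangent = TRUE,
                    settings = st),
        wmrve_invalid = function(e) NULL)
      if (is.null(out)) break
      r <- as.numeric(Matrix::crossprod(S, as.vector(t(out$f))))
      res <- max(abs(r))
      res_hist <- c(res_hist, res)
      if (!is.finite(res)) break
      if (res <= tol) { ok <- TRUE; break }
      step <- tryCatch(as.numeric(Matrix::solve(
        Matrix::crossprod(S, out$K %*% S), -r)), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      ured_try <- ured_try + step
    }
    trace[[length(trace) + 1L]] <- list(t = t_try, iterations = it,
                                        residuals = res_hist, converged = ok)
    if (ok) {
      ured <- ured_try
      t_done <- t_try
      increments <- increments + 1L
    } else {
      cuts <- cuts + 1L
      dt <- dt / 2
      if (cuts > st$max_cuts) {
        return(structure(list(converged = FALSE, U = NULL,
                              increments_used = increments, trace = trace,
                              message = "no convergence after maximum step cuts"),
                         class = "fe_result"))
      }
    }
  }
  U <- affine_field(mesh, F) + matrix(S %*% ured, nn, 3, byrow = TRUE)
  avg <- fe_average(mesh, truss, ti, mp, fp, U, pre)
  W <- fe_internal(mesh, truss, ti, mp, fp, U, pre, tangent = FALSE,
                   settings = st)$energy
  structure(c(list(converged = TRUE, U = U, increments_used = increments,
                   trace = trace, energy = W, fluct = ured), avg),
            class = "fe_result")
}

#' @export
print.fe_result <- function(x, ...) {
  if (!x$converged) cat("FE solve FAILED:", x$message, "\n")
  else {
    cat(sprintf("FE solve converged in %d increment(s)\n", x$increments_used))
    cat("Homogenized P_total (Pa):\n"); print(signif(x$P_total, 6))
  }
  invisible(x)
}

## rows of a response curve computed with the FE engine (continuation in
## the loading amount, warm-started from the previous step)
fe_response_rows <- function(net, mode, amounts, mp, fp, fe_opts) {
  h <- fe_opts$h %||% (net$La / 8)
  settings <- utils::modifyList(default_fe_settings(),
                                fe_opts$settings %||% list())
  mesh <- build_mesh(net$La, h)
  truss <- if (nrow(net$fibers)) embed_fibers(net, mesh) else NULL
  lapply(amounts, function(a) {
    F <- macro_F(mode, a)
    res <- solve_rve(mesh, truss, periodic_constraints(mesh, F), mp, fp, F,
                     settings = settings)
    if (!res$converged)
      stop_invalid("FE engine failed to converge at amount ", a)
    c(a, conjugate_component(res$P_total, mode, a),
      conjugate_component(res$P_matrix, mode, a),
      conjugate_component(res$P_fiber, mode, a), res$recruited_fraction)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mesh-convergence study of the FE engine
#'
#' Solves the same RVE at several element sizes and reports the
#' work-conjugate homogenized stress at the final loading amount,
#' together with the relative spread across mesh sizes.
#'
#' @param net a [fiber_network()] object
#' @param h_list element sizes (um), at least 2; each must divide `La`
#' @param mode loading-mode label
#' @param amount final stretch or amount of shear
#' @param mp,fp material parameters
#' @param settings FE settings list
#' @return data.frame with columns `h`, `stress`, `converged`, plus
#'   attribute `relative_spread`
#' @export
mesh_convergence <- function(net, h_list, mode, amount, mp, fp,
                             settings = list()) {
  if (!length(h_list)) stop_invalid("'h_list' must not be empty")
  if (length(h_list) < 2) stop_invalid("need at least 2 mesh sizes")
  rows <- lapply(h_list, function(h) {
    mesh <- build_mesh(net$La, h)
    truss <- if (nrow(net$fibers)) embed_fibers(net, mesh) else NULL
    F <- macro_F(mode, amount)
    res <- solve_rve(mesh, truss, periodic_constraints(mesh, F), mp, fp, F,
                     settings = settings)
    data.frame(h = h,
               stress = if (res$converged)
                 conjugate_component(res$P_total, mode, amount) else NA_real_,
               converged = res$converged)
  })
  out <- do.call(rbind, rows)
  sOK <- out$stress[out$converged]
  attr(out, "relative_spread") <-
    if (length(sOK) > 1) diff(range(sOK)) / max(abs(sOK)) else NA_real_
  out
}
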