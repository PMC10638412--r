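## Rule-of-mixtures homogenization with affine (Taylor) micro-kinematics:
## every fiber sees the macroscopic deformation gradient. The homogenized
## nominal stress is P = P_matrix + v_f * P_fiber (volume-average rule of
## mixtures with the modified embedded-fiber energy, so the matrix field is
## integrated over the full cube with no double counting).

loading_mode_labels <- c("compression_FF", "tension_FF", "compression_TT",
                         "tension_TT", "shear_FT", "shear_TF", "shear_TT")

## shear convention: first letter = displacement direction, second =
## face-normal direction; the fiber axis is x (F), transverse is y/z (T).
shear_dyads <- list(shear_FT = c(1L, 2L), shear_TF = c(2L, 1L),
                    shear_TT = c(2L, 3L))

is_uniaxial_mode <- function(mode) !startsWith(mode, "shear")

check_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L ||
      !(mode %in% loading_mode_labels))
    stop_invalid("unknown loading mode '", paste(mode, collapse = ","),
                 "'; valid modes: ", paste(loading_mode_labels, collapse = ", "))
  mode
}

#' Macroscopic deformation gradient of a canonical loading mode
#'
#' Uniaxial modes use the isochoric ansatz `diag(lambda, lambda^-1/2,
#' lambda^-1/2)` (stretch axis x for FF, y for TT; exact lateral
#' kinematics in the incompressible matrix limit). Shear modes are simple
#' shear `I + gamma e_i (x) e_j` with (i,j) = (1,2) for FT, (2,1) for TF,
#' (2,3) for TT.
#'
#' @param mode one of `compression_FF`, `tension_FF`, `compression_TT`,
#'   `tension_TT`, `shear_FT`, `shear_TF`, `shear_TT`
#' @param amount stretch `lambda` (uniaxial) or amount of shear `gamma`
#' @return 3x3 deformation gradient
#' @export
#' @examples
#' macro_F("tension_FF", 1.2)
#' macro_F("shear_TF", 0.2)
macro_F <- function(mode, amount) {
  check_mode(mode)
  check_scalar(amount, "amount")
  if (is_uniaxial_mode(mode)) {
    if (amount <= 0) stop_invalid("uniaxial stretch must be > 0")
    axis <- if (endsWith(mode, "FF")) 1L else 2L
    lam <- rep(amount^(-0.5), 3)
    lam[axis] <- amount
    diag(lam)
  } else {
    if (amount < 0) stop_invalid("amount of shear must be >= 0")
    ij <- shear_dyads[[mode]]
    F <- diag(3)
    F[ij[1], ij[2]] <- amount
    F
  }
}

## dF/d(amount): direction of loading, used for the work-conjugate stress
macro_F_dot <- function(mode, amount) {
  if (is_uniaxial_mode(mode)) {
    axis <- if (endsWith(mode, "FF")) 1L else 2L
    dd <- rep(-0.5 * amount^(-1.5), 3)
    dd[axis] <- 1
    diag(dd)
  } else {
    ij <- shear_dyads[[mode]]
    D <- matrix(0, 3, 3)
    D[ij[1], ij[2]] <- 1
    D
  }
}

#' Stretch of a fiber direction under a deformation gradient
#'
#' Affine kinematics of a 1-D segment: `lambda = ||F N||`.
#' @param F 3x3 deformation gradient, positive determinant
#' @param N unit direction vector
#' @return scalar stretch
#' @export
fiber_stretch <- function(F, N) {
  if (!is_square3(F) || det(F) <= 0) stop_invalid("'F' must be 3x3 with det > 0")
  if (abs(sum(N^2) - 1) > 1e-8) stop_invalid("'N' must be a unit vector")
  sqrt(sum((F %*% N)^2))
}

#' Affine homogenization of a fiber network at one deformation state
#'
#' The matrix contributes its nominal stress at the macroscopic `F`; each
#' fiber contributes its 1-D nominal stress along its deformed direction,
#' weighted by its share of the total fiber volume. The homogenized stress
#' assembles by the rule of mixtures, `P_total = P_matrix + v_f P_fiber`.
#'
#' @param net a [fiber_network()] object
#' @param F 3x3 macroscopic deformation gradient
#' @param mp a [matrix_params()] object
#' @param fp a [fiber_params()] object
#' @return list with 3x3 tensors `P_total`, `P_matrix`, `P_fiber`, plus
#'   `recruited_fraction` (volume-weighted share of recruited fibers) and
#'   `energy` (matrix + v_f * mean fiber energy, Pa)
#' @export
homogenize <- function(net, F, mp, fp) {
  stopifnot(inherits(net, "fiber_network"), inherits(mp, "matrix_params"),
            inherits(fp, "fiber_params"))
  if (!is_square3(F) || det(F) <= 0) stop_invalid("'F' must be 3x3 with det > 0")
  P_m <- matrix_pk1(F, mp)
  fib <- net$fibers
  if (!nrow(fib)) {
    return(list(P_total = P_m, P_matrix = P_m,
                P_fiber = matrix(0, 3, 3), recruited_fraction = 0,
                energy = matrix_energy(F, mp)))
  }
  N <- as.matrix(fib[, c("Nx", "Ny", "Nz")])
  FN <- N %*% t(F)                    # rows: F %*% N_i
  lam <- sqrt(rowSums(FN^2))
  vol <- pi * fib$d^2 / 4 * fib$L0
  w <- vol / sum(vol)
  p_f <- fiber_nominal_stress(lam, fib$Ps, fp)
  m <- FN / lam
  ## P_fiber = sum_i w_i p_i m_i (x) N_i
  cw <- w * p_f
  P_f <- unname(t(m * cw) %*% N)
  rec <- recruitment_split(lam, fib$Ps)$recruited
  vf <- net$achieved_vf
  W_f <- sum(w * fiber_energy(lam, fib$Ps, fp))
  list(P_total = P_m + vf * P_f, P_matrix = P_m, P_fiber = P_f,
       recruited_fraction = sum(w[rec]),
       energy = matrix_energy(F, mp) + vf * W_f)
}

conjugate_component <- function(P, mode, amount) sum(P * macro_F_dot(mode, amount))

#' Homogenized stress-deformation response curve
#'
#' Sweeps one loading mode from the identity to `max_amount` and reports
#' the work-conjugate nominal component at each step: `P : dF/d(amount)`.
#' For uniaxial modes with the isochoric ansatz this is the total
#' derivative of the energy with respect to the stretch and coincides with
#' the analytic incompressible uniaxial nominal stress of the matrix; for
#' shear modes it is the `P_ij` component conjugate to `gamma`.
#'
#' @param net a [fiber_network()] object
#' @param mode loading-mode label (see [macro_F()])
#' @param max_amount final stretch (uniaxial) or amount of shear
#' @param mp,fp material parameter objects
#' @param n_steps number of points including the identity, >= 2
#' @param amounts optional explicit amount grid (overrides `max_amount`)
#' @param engine `"affine"` (default) or `"fe"` (periodic finite-element
#'   engine; see [solve_rve()] for the extra `fe_opts`)
#' @param fe_opts list of options for the FE engine (`h`, `settings`)
#' @param lateral lateral kinematics for uniaxial modes: `"isochoric"`
#'   (default ansatz `lambda^-1/2`) or `"zero_stress"` (affine engine
#'   only: the lateral stretch is solved so the lateral nominal stress
#'   vanishes, relevant for dispersed orientations; the reported
#'   component is then the axial `P_ii`)
#' @return a data.frame of class `homogenized_curve` with columns
#'   `amount`, `P_total`, `P_matrix`, `P_fiber`, `recruited_fraction`,
#'   with the mode and engine stored as attributes
#' @export
response_curve <- function(net, mode, max_amount = NULL, mp, fp, n_steps = 21,
                           amounts = NULL, engine = c("affine", "fe"),
                           fe_opts = list(),
                           lateral = c("isochoric", "zero_stress")) {
  check_mode(mode)
  engine <- match.arg(engine)
  lateral <- match.arg(lateral)
  if (lateral == "zero_stress" &&
      (engine != "affine" || !is_uniaxial_mode(mode)))
    stop_invalid("'zero_stress' lateral kinematics is available only for ",
                 "the affine engine on uniaxial modes")
  if (is.null(amounts)) {
    if (is.null(max_amount)) stop_invalid("give 'max_amount' or 'amounts'")
    if (n_steps < 2) stop_invalid("'n_steps' must be >= 2")
    start <- if (is_uniaxial_mode(mode)) 1 else 0
    amounts <- seq(start, max_amount, length.out = n_steps)
  }
  if (is.unsorted(amounts) && is.unsorted(rev(amounts)))
    stop_invalid("'amounts' must be monotone")
  if (engine == "affine" && lateral == "zero_stress") {
    axis <- if (endsWith(mode, "FF")) 1L else 2L
    lat_axes <- setdiff(1:3, axis)
    rows <- lapply(amounts, function(a) {
      F_of <- function(lat) {
        lam <- rep(lat, 3); lam[axis] <- a
        diag(lam)
      }
      g <- function(lat) {
        P <- homogenize(net, F_of(lat), mp, fp)$P_total
        P[lat_axes[1], lat_axes[1]] + P[lat_axes[2], lat_axes[2]]
      }
      lat <- if (abs(a - 1) < 1e-12) 1
      else stats::uniroot(g, c(0.6, 1.6) * a^(-0.5), extendInt = "yes",
                          tol = 1e-12)$root
      h <- homogenize(net, F_of(lat), mp, fp)
      c(a, h$P_total[axis, axis], h$P_matrix[axis, axis],
        h$P_fiber[axis, axis], h$recruited_fraction)
    })
  } else if (engine == "affine") {
    rows <- lapply(amounts, function(a) {
      h <- homogenize(net, macro_F(mode, a), mp, fp)
      c(a, conjugate_component(h$P_total, mode, a),
        conjugate_component(h$P_matrix, mode, a),
        conjugate_component(h$P_fiber, mode, a), h$recruited_fraction)
    })
  } else {
    rows <- fe_response_rows(net, mode, amounts, mp, fp, fe_opts)
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("amount", "P_total", "P_matrix", "P_fiber",
                  "recruited_fraction")
  structure(out, mode = mode, engine = engine,
            class = c("homogenized_curve", "data.frame"))
}

#' Write / read a homogenized curve (CSV + JSON metadata)
#'
#' @param curve a `homogenized_curve` from [response_curve()]
#' @param path CSV path; metadata goes to `<path>.json`
#' @param metadata extra fields merged into the JSON sidecar
#' @return `read_curve()` returns the curve with its attributes restored
#' @export
write_curve <- function(curve, path, metadata = list()) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  jsonlite::write_json(c(list(mode = attr(curve, "mode"),
                              engine = attr(curve, "engine")), metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  out <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(out, mode = meta$mode, engine = meta$engine,
            class = c("homogenized_curve", "data.frame"))
}
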