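## One-term Ogden constitutive laws: nearly incompressible ground matrix
## (principal-stretch form with a quadratic volumetric penalty) and embedded
## 1-D fibers with the recruitment-stretch mechanism for tortuosity.
## The only stress measure exposed is the nominal (first Piola-Kirchhoff)
## stress.

#' Ground-matrix material parameters
#'
#' One-term Ogden law with shear modulus `mu` (Pa), exponent `alpha` and
#' volumetric compliance `D` (1/Pa). The default `D = 0.04/mu` corresponds
#' to an initial Poisson's ratio of 0.49; `incompressible = TRUE` drops the
#' volumetric term (analytic incompressible limit).
#'
#' @param mu shear modulus (Pa), > 0
#' @param alpha Ogden exponent, nonzero
#' @param D volumetric compliance (1/Pa), > 0; ignored when `incompressible`
#' @param incompressible logical flag
#' @return object of class `matrix_params`
#' @export
#' @examples
#' matrix_params(353.5, -21.5)  # corpus callosum ground matrix
matrix_params <- function(mu, alpha, D = 0.04 / mu, incompressible = FALSE) {
  check_scalar(mu, "mu", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha == 0) stop_invalid("'alpha' must be nonzero")
  if (!incompressible) check_scalar(D, "D", positive = TRUE)
  structure(list(mu = mu, alpha = alpha,
                 D = if (incompressible) NA_real_ else D,
                 incompressible = incompressible),
            class = "matrix_params")
}

#' @export
print.matrix_params <- function(x, ...) {
  cat(sprintf("Ogden matrix: mu = %g Pa, alpha = %g, %s\n", x$mu, x$alpha,
              if (x$incompressible) "incompressible"
              else sprintf("D = %g 1/Pa (nu0 = %0.4f)", x$D, initial_poisson(x))))
  invisible(x)
}

#' Embedded-fiber material parameters
#'
#' Parameters of the modified strain-energy of the embedded fibers (the
#' matrix energy of the occupied volume is already accounted for by the
#' host continuum, so these are embedded-fiber constants, not properties
#' of an isolated axon).
#'
#' @param mu shear modulus (Pa), > 0
#' @param alpha Ogden exponent, nonzero
#' @return object of class `fiber_params`
#' @export
#' @examples
#' fiber_params(80.8, 62.3)  # embedded axon fibers
fiber_params <- function(mu, alpha) {
  check_scalar(mu, "mu", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha == 0) stop_invalid("'alpha' must be nonzero")
  structure(list(mu = mu, alpha = alpha), class = "fiber_params")
}

#' @export
print.fiber_params <- function(x, ...) {
  cat(sprintf("Embedded fiber: mu = %g Pa, alpha = %g\n", x$mu, x$alpha))
  invisible(x)
}

#' Split a fiber stretch into recruitment and true stretch
#'
#' A tortuous fiber with straightness `Ps` first unbends (recruitment
#' stretch `lambda_r`, no load) and only then stretches truly
#' (`lambda_t`): `lambda = lambda_r * lambda_t`, with `lambda_t = 1` while
#' `lambda < 1/Ps` and `lambda_t = lambda * Ps` beyond. Stretches below 1
#' are treated as unrecruited (fibers bear no compressive load).
#'
#' @param lambda total fiber stretch(es) `l/L0`, >= 0
#' @param Ps straightness in (0, 1]
#' @return list with vectors `lambda`, `lambda_r`, `lambda_t`, `recruited`
#' @export
recruitment_split <- function(lambda, Ps) {
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop_invalid("'lambda' must be finite and >= 0")
  if (any(!is.finite(Ps)) || any(Ps <= 0) || any(Ps > 1))
    stop_invalid("'Ps' must lie in (0, 1]")
  recruited <- lambda >= 1 / Ps
  lambda_r <- ifelse(recruited, 1 / Ps, lambda)
  lambda_t <- ifelse(recruited, lambda * Ps, 1)
  list(lambda = lambda, lambda_r = lambda_r, lambda_t = lambda_t,
       recruited = recruited)
}

#' Strain energy of an embedded fiber
#'
#' Modified one-term Ogden energy in the true stretch; identically zero
#' while the fiber is unrecruited.
#'
#' @param lambda total fiber stretch(es)
#' @param Ps straightness in (0, 1]
#' @param fp a [fiber_params()] object
#' @return energy density (Pa), vectorized over `lambda`
#' @export
fiber_energy <- function(lambda, Ps, fp) {
  stopifnot(inherits(fp, "fiber_params"))
  lt <- recruitment_split(lambda, Ps)$lambda_t
  2 * fp$mu / fp$alpha^2 * (lt^fp$alpha + 2 * lt^(-fp$alpha / 2) - 3)
}

#' Nominal stress of an embedded fiber
#'
#' Derivative of [fiber_energy()] with respect to the total stretch
#' (reference configuration: straight, end-to-end length). Zero up to the
#' recruitment point and continuous there.
#'
#' @inheritParams fiber_energy
#' @return nominal stress (Pa), vectorized
#' @export
fiber_nominal_stress <- function(lambda, Ps, fp) {
  stopifnot(inherits(fp, "fiber_params"))
  rs <- recruitment_split(lambda, Ps)
  lt <- rs$lambda_t
  s <- 2 * fp$mu / fp$alpha * (lt^(fp$alpha - 1) - lt^(-fp$alpha / 2 - 1)) * Ps
  ifelse(rs$recruited, s, 0)
}

#' Tangent stiffness of an embedded fiber
#'
#' d(nominal stress)/d(lambda); used by the finite-element truss tangent.
#' @inheritParams fiber_energy
#' @return stiffness (Pa), vectorized
#' @export
fiber_stiffness <- function(lambda, Ps, fp) {
  stopifnot(inherits(fp, "fiber_params"))
  rs <- recruitment_split(lambda, Ps)
  lt <- rs$lambda_t
  k <- 2 * fp$mu / fp$alpha *
    ((fp$alpha - 1) * lt^(fp$alpha - 2) +
     (fp$alpha / 2 + 1) * lt^(-fp$alpha / 2 - 2)) * Ps^2
  ifelse(rs$recruited, k, 0)
}

## principal stretches of F via singular values (robust also for repeated
## stretches: any singular basis is valid for an isotropic energy)
principal_stretches <- function(F) {
  if (!is_square3(F)) stop_invalid("'F' must be a finite 3x3 matrix")
  if (det(F) <= 0) stop_invalid("det(F) must be > 0")
  svd(F)
}

## dPsi/dlambda_k for the matrix law. The Ogden term acts on the
## deviatoric stretches lam_bar = J^(-1/3) lam (stress-free reference
## state; mu is the initial shear modulus); the penalty (1/D)(J-1)^2
## carries the volumetric response with initial bulk modulus K = 2/D.
matrix_dpsi <- function(lam, mp) {
  J <- prod(lam)
  s <- (lam * J^(-1 / 3))^mp$alpha
  d <- 2 * mp$mu / mp$alpha * (s - sum(s) / 3) / lam
  if (!mp$incompressible) d <- d + (2 / mp$D) * (J - 1) * J / lam
  d
}

#' Strain energy of the ground matrix
#'
#' One-term Ogden energy in the deviatoric principal stretches of `F`
#' (`lam_bar = J^(-1/3) lam`, the standard nearly incompressible split:
#' the reference state is stress-free and `mu` is the initial shear
#' modulus) plus the quadratic volumetric penalty `(1/D)(J-1)^2` (omitted
#' for the incompressible flag). On isochoric deformations (`J = 1`) the
#' deviatoric and total stretches coincide and the energy reduces to the
#' plain one-term Ogden expression.
#'
#' @param F 3x3 deformation gradient with positive determinant
#' @param mp a [matrix_params()] object
#' @return energy density (Pa)
#' @export
matrix_energy <- function(F, mp) {
  stopifnot(inherits(mp, "matrix_params"))
  lam <- principal_stretches(F)$d
  J <- prod(lam)
  W <- 2 * mp$mu / mp$alpha^2 * (sum((lam * J^(-1 / 3))^mp$alpha) - 3)
  if (!mp$incompressible) W <- W + (J - 1)^2 / mp$D
  W
}

#' Nominal stress tensor of the ground matrix
#'
#' First Piola-Kirchhoff stress, computed in the principal basis of `F`
#' (`P = U diag(dPsi/dlambda) V'` for `F = U diag(lambda) V'`); the
#' expression is invariant to the choice of basis inside repeated
#' singular-value subspaces, so coincident stretches need no special
#' branch at the stress level.
#'
#' @inheritParams matrix_energy
#' @return 3x3 nominal stress (Pa)
#' @export
matrix_pk1 <- function(F, mp) {
  stopifnot(inherits(mp, "matrix_params"))
  s <- principal_stretches(F)
  s$u %*% (matrix_dpsi(s$d, mp) * t(s$v))
}

#' Initial Poisson's ratio of the matrix law
#'
#' Small-strain ratio from the initial shear modulus `mu` and initial bulk
#' modulus `K = 2/D`: `nu = (3K - 2mu) / (2(3K + mu))`. Exactly 0.5 for
#' the incompressible flag.
#'
#' @param mp a [matrix_params()] object
#' @return dimensionless Poisson's ratio
#' @export
#' @examples
#' initial_poisson(matrix_params(353.5, -21.5))  # ~0.49
initial_poisson <- function(mp) {
  stopifnot(inherits(mp, "matrix_params"))
  if (mp$incompressible) return(0.5)
  K <- 2 / mp$D
  (3 * K - 2 * mp$mu) / (2 * (3 * K + mp$mu))
}

#' Analytic incompressible uniaxial nominal stress
#'
#' One-term Ogden, incompressible, uniaxial: the work-conjugate nominal
#' stress `P = (2 mu / alpha)(lambda^(alpha-1) - lambda^(-alpha/2-1))`.
#' Used as the fast forward model in step 1 of the parameter
#' identification.
#'
#' @param lambda axial stretch(es), > 0
#' @param mu shear modulus (Pa)
#' @param alpha Ogden exponent, nonzero
#' @return nominal stress (Pa), vectorized
#' @export
uniaxial_incompressible_nominal <- function(lambda, mu, alpha) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop_invalid("'lambda' must be finite and > 0")
  check_scalar(mu, "mu")
  check_scalar(alpha, "alpha")
  if (alpha == 0) stop_invalid("'alpha' must be nonzero")
  2 * mu / alpha * (lambda^(alpha - 1) - lambda^(-alpha / 2 - 1))
}

## ---------------------------------------------------------------- JSON ----

#' Write / read material parameters as JSON
#'
#' Units are pascal; the incompressible flag is stored explicitly.
#' @param mp a [matrix_params()] object
#' @param fp a [fiber_params()] object
#' @param path JSON file
#' @return `read_material_params()` returns `list(matrix =, fiber =)`
#' @export
write_material_params <- function(mp, fp, path) {
  stopifnot(inherits(mp, "matrix_params"), inherits(fp, "fiber_params"))
  jsonlite::write_json(list(
    units = "Pa",
    matrix = list(mu = mp$mu, alpha = mp$alpha, D = mp$D,
                  incompressible = mp$incompressible),
    fiber = list(mu = fp$mu, alpha = fp$alpha)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_material_params
#' @export
read_material_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mp <- if (isTRUE(x$matrix$incompressible))
    matrix_params(x$matrix$mu, x$matrix$alpha, incompressible = TRUE)
  else matrix_params(x$matrix$mu, x$matrix$alpha, D = x$matrix$D)
  list(matrix = mp, fiber = fiber_params(x$fiber$mu, x$fiber$alpha))
}
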