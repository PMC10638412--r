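## Fiber-property probability models: generalized extreme value (diameter,
## um), beta (straightness P_s in (0,1)) and bivariate von Mises
## (orientation angles Phi, Theta).

#' Generalized extreme value parameters
#'
#' Location/scale/shape parameterization of the GEV law used for the axon
#' outer diameter. The density support is the set of diameters d with
#' 1 + xi (d - mu) / sigma > 0.
#'
#' @param mu location (um)
#' @param sigma scale (um), must be positive
#' @param xi shape (dimensionless); negative values give a bounded upper tail
#' @return object of class `gev_params`
#' @export
#' @examples
#' gev_params(0.426, 0.200, -0.305)  # human corpus callosum diameters
gev_params <- function(mu, sigma, xi) {
  check_scalar(mu, "mu")
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(xi, "xi")
  structure(list(mu = mu, sigma = sigma, xi = xi), class = "gev_params")
}

#' @export
print.gev_params <- function(x, ...) {
  cat(sprintf("GEV(mu = %g um, sigma = %g um, xi = %g)\n", x$mu, x$sigma, x$xi))
  invisible(x)
}

#' Beta distribution parameters (fiber straightness)
#'
#' @param a,b positive shape parameters
#' @return object of class `beta_params`
#' @export
beta_params <- function(a, b) {
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b", positive = TRUE)
  structure(list(a = a, b = b), class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(a = %g, b = %g), mean %0.4f\n", x$a, x$b, x$a / (x$a + x$b)))
  invisible(x)
}

#' Bivariate von Mises orientation parameters
#'
#' Concentrations of the in-plane (azimuth Phi) and out-of-plane (elevation
#' Theta) angular densities. `Inf` denotes perfect alignment of the
#' corresponding angle (an explicit degenerate case; the finite-density
#' functions reject it, the sampler handles it exactly).
#'
#' @param alpha in-plane concentration, >= 0 or `Inf`
#' @param beta out-of-plane concentration, >= 0 or `Inf`
#' @return object of class `orientation_params`
#' @export
#' @examples
#' orientation_params(Inf, Inf)  # perfectly aligned axons
#' orientation_params(0, 0)      # isotropic dispersion
orientation_params <- function(alpha, beta) {
  for (v in list(alpha = alpha, beta = beta)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_invalid("concentration parameters must be single numbers >= 0 (Inf allowed)")
  }
  structure(list(alpha = alpha, beta = beta,
                 aligned_ip = is.infinite(alpha),
                 aligned_op = is.infinite(beta)),
            class = "orientation_params")
}

#' @export
print.orientation_params <- function(x, ...) {
  cat(sprintf("Orientation(alpha = %s, beta = %s)\n",
              format(x$alpha), format(x$beta)))
  invisible(x)
}

## ---------------------------------------------------------------- GEV ----

#' GEV probability density
#'
#' Density of the generalized extreme value law; diameters outside the
#' support return zero density.
#'
#' @param d diameters (um), vectorized
#' @param p a [gev_params()] object
#' @return densities (1/um)
#' @export
gev_pdf <- function(d, p) {
  stopifnot(inherits(p, "gev_params"))
  if (!is.numeric(d)) stop_invalid("'d' must be numeric")
  z <- 1 + p$xi * (d - p$mu) / p$sigma
  out <- numeric(length(d))
  if (abs(p$xi) < 1e-12) {
    t <- exp(-(d - p$mu) / p$sigma)     # Gumbel limit
    out <- t * exp(-t) / p$sigma
  } else {
    ok <- z > 0
    t <- z[ok]^(-1 / p$xi)
    out[ok] <- t^(p$xi + 1) * exp(-t) / p$sigma
  }
  out
}

gev_quantile <- function(u, p) {
  if (abs(p$xi) < 1e-12) p$mu - p$sigma * log(-log(u))
  else p$mu + p$sigma * ((-log(u))^(-p$xi) - 1) / p$xi
}

gev_cdf <- function(d, p) {
  z <- 1 + p$xi * (d - p$mu) / p$sigma
  if (abs(p$xi) < 1e-12) return(exp(-exp(-(d - p$mu) / p$sigma)))
  out <- ifelse(z <= 0, if (p$xi > 0) 0 else 1, exp(-pmax(z, 1e-300)^(-1 / p$xi)))
  ## for xi<0, z<=0 on the upper side -> CDF 1; for xi>0 lower side -> 0
  out
}

#' Mean of a GEV distribution
#'
#' Finite for xi < 1; used as an oracle for sampling checks.
#' @param p a [gev_params()] object
#' @return the distribution mean (um)
#' @export
gev_mean <- function(p) {
  stopifnot(inherits(p, "gev_params"))
  if (p$xi >= 1) return(Inf)
  if (abs(p$xi) < 1e-12) return(p$mu + p$sigma * 0.5772156649015329)
  p$mu + p$sigma * (gamma(1 - p$xi) - 1) / p$xi
}

#' Sample fiber diameters from a GEV law
#'
#' Inverse-CDF sampling; non-positive draws (possible for some parameter
#' sets) are rejected and redrawn, so the returned sample follows the
#' zero-truncated law. The number of rejected draws is attached as
#' attribute `"rejected"`.
#'
#' @param p a [gev_params()] object
#' @param n number of samples, >= 1
#' @param seed integer seed (sampling is bit-reproducible)
#' @return vector of `n` positive diameters (um)
#' @export
gev_sample <- function(p, n, seed) {
  stopifnot(inherits(p, "gev_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("'n' must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    out <- numeric(0)
    rejected <- 0L
    while (length(out) < n) {
      m <- n - length(out)
      x <- gev_quantile(stats::runif(m), p)
      rejected <- rejected + sum(x <= 0)
      out <- c(out, x[x > 0])
    }
    structure(out, rejected = rejected)
  })
}

gev_nll <- function(theta, x, truncation = NULL) {
  p <- list(mu = theta[1], sigma = theta[2], xi = theta[3])
  if (p$sigma <= 0) return(1e10)
  z <- 1 + p$xi * (x - p$mu) / p$sigma
  if (any(z <= 0)) return(1e10)
  if (abs(p$xi) < 1e-12) {
    w <- (x - p$mu) / p$sigma
    ll <- sum(-w - exp(-w)) - length(x) * log(p$sigma)
  } else {
    lt <- -log(z) / p$xi
    ll <- sum((p$xi + 1) * lt - exp(lt)) - length(x) * log(p$sigma)
  }
  if (!is.null(truncation)) {
    Ftr <- gev_cdf(truncation, structure(p, class = "gev_params"))
    if (Ftr >= 1) return(1e10)
    ll <- ll - length(x) * log1p(-Ftr)
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Maximum-likelihood fit of a GEV law
#'
#' Bounded quasi-Newton (`L-BFGS-B`) maximization of the log-likelihood
#' from a moment-based start plus deterministic restarts; ties are broken
#' by the highest log-likelihood, then the lowest parameter norm.
#'
#' When the sample was produced by rejection of non-positive values (as
#' [gev_sample()] does), set `truncation = 0` to maximize the matching
#' zero-truncated likelihood; the untruncated likelihood (default) carries
#' a small location bias for parameter sets with mass below zero.
#'
#' @param x numeric sample, at least 50 values
#' @param truncation optional left-truncation point of the sampling scheme
#' @return a list of class `gev_fit` with elements `params`
#'   ([gev_params()]), `logLik`, and `converged`
#' @export
gev_fit <- function(x, truncation = NULL) {
  if (!is.numeric(x) || length(x) < 50)
    stop_invalid("GEV fitting requires at least 50 samples")
  if (stats::sd(x) == 0)
    return(structure(list(params = NULL, logLik = -Inf, converged = FALSE,
                          message = "degenerate (constant) sample"),
                     class = "gev_fit"))
  s0 <- stats::sd(x) * sqrt(6) / pi
  m0 <- mean(x) - 0.5772156649015329 * s0
  starts <- list(c(m0, s0, -0.3), c(m0, s0, -0.1), c(m0, s0, 0.1))
  lower <- c(-Inf, 1e-10, -0.95)
  upper <- c(Inf, Inf, 0.95)
  best <- NULL
  for (th0 in starts) {
    fit <- try(stats::optim(th0, gev_nll, x = x, truncation = truncation,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-10 ||
        (abs(fit$value - best$value) <= 1e-10 &&
         sum(fit$par^2) < sum(best$par^2)))
      best <- fit
  }
  if (is.null(best))
    return(structure(list(params = NULL, logLik = -Inf, converged = FALSE,
                          message = "all starts failed"), class = "gev_fit"))
  structure(list(params = gev_params(best$par[1], best$par[2], best$par[3]),
                 logLik = -best$value, converged = best$convergence == 0),
            class = "gev_fit")
}

#' @export
print.gev_fit <- function(x, ...) {
  if (!x$converged && is.null(x$params)) cat("GEV fit failed:", x$message, "\n")
  else {
    cat("GEV maximum-likelihood fit (logLik ", format(x$logLik), ")\n", sep = "")
    print(x$params)
  }
  invisible(x)
}

## --------------------------------------------------------------- beta ----

#' Beta probability density for the straightness parameter
#'
#' Zero outside (0,1).
#' @param ps straightness values
#' @param p a [beta_params()] object
#' @return densities
#' @export
beta_pdf <- function(ps, p) {
  stopifnot(inherits(p, "beta_params"))
  out <- numeric(length(ps))
  ok <- ps > 0 & ps < 1
  out[ok] <- stats::dbeta(ps[ok], p$a, p$b)
  out
}

#' Sample straightness values from a beta law
#'
#' @inheritParams gev_sample
#' @param p a [beta_params()] object
#' @return vector of `n` values in (0,1)
#' @export
beta_sample <- function(p, n, seed) {
  stopifnot(inherits(p, "beta_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("'n' must be >= 1")
  with_seed(seed, stats::rbeta(as.integer(n), p$a, p$b))
}

#' Maximum-likelihood fit of a beta law
#'
#' Optimizes the log shapes by `L-BFGS-B` from a method-of-moments start
#' plus deterministic restarts.
#'
#' @param x sample in (0,1), at least 50 values
#' @return a list of class `beta_fit` with `params`, `logLik`, `converged`
#' @export
beta_fit <- function(x) {
  if (!is.numeric(x) || length(x) < 50)
    stop_invalid("beta fitting requires at least 50 samples")
  if (any(x <= 0 | x >= 1)) stop_invalid("samples must lie strictly in (0,1)")
  if (stats::sd(x) == 0)
    return(structure(list(params = NULL, logLik = -Inf, converged = FALSE,
                          message = "degenerate (constant) sample"),
                     class = "beta_fit"))
  m <- mean(x); v <- stats::var(x)
  k <- m * (1 - m) / v - 1
  start <- log(pmax(c(m * k, (1 - m) * k), 1e-3))
  nll <- function(lth) {
    a <- exp(lth[1]); b <- exp(lth[2])
    if (!is.finite(a) || !is.finite(b)) return(1e10)
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  best <- NULL
  for (th0 in list(start, start + c(0.5, -0.5), start + c(-0.5, 0.5))) {
    fit <- try(stats::optim(th0, nll, method = "L-BFGS-B",
                            lower = log(1e-6), upper = log(1e6),
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  structure(list(params = beta_params(exp(best$par[1]), exp(best$par[2])),
                 logLik = -best$value, converged = best$convergence == 0),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  if (is.null(x$params)) cat("beta fit failed:", x$message, "\n")
  else { cat("Beta maximum-likelihood fit\n"); print(x$params) }
  invisible(x)
}

## ----------------------------------------------------------- histogram ----

#' Least-squares fit of a density to histogram data
#'
#' Alternative fitting criterion for binned inputs (bin centre, density
#' value): minimizes the sum of squared differences between the model
#' density and the histogram heights.
#'
#' @param centers bin centres
#' @param values histogram density values
#' @param family `"gev"` or `"beta"`
#' @return fitted parameter object (`gev_params` or `beta_params`)
#' @export
fit_histogram <- function(centers, values, family = c("gev", "beta")) {
  family <- match.arg(family)
  if (length(centers) != length(values) || length(centers) < 4)
    stop_invalid("histogram fit needs >= 4 (center, value) pairs")
  if (family == "gev") {
    obj <- function(th) {
      if (th[2] <= 0) return(1e10)
      sum((gev_pdf(centers, gev_params(th[1], th[2], th[3])) - values)^2)
    }
    m <- sum(centers * values) / sum(values)
    fit <- stats::optim(c(m, diff(range(centers)) / 4, -0.1), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    gev_params(fit$par[1], fit$par[2], fit$par[3])
  } else {
    obj <- function(lth) {
      p <- beta_params(exp(lth[1]), exp(lth[2]))
      sum((beta_pdf(centers, p) - values)^2)
    }
    fit <- stats::optim(c(log(2), log(2)), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    beta_params(exp(fit$par[1]), exp(fit$par[2]))
  }
}

#' Read a sample or histogram CSV for distribution fitting
#'
#' Raw samples are one-column CSVs; histograms are two-column
#' (`bin_center,value`).
#'
#' @param path CSV file
#' @param histogram logical; is the file binned data?
#' @return numeric vector (raw) or data.frame with `bin_center`, `value`
#' @export
read_sample_csv <- function(path, histogram = FALSE) {
  dat <- utils::read.csv(path)
  if (histogram) {
    if (ncol(dat) < 2) stop_invalid("histogram CSV needs columns bin_center,value")
    data.frame(bin_center = dat[[1]], value = dat[[2]])
  } else dat[[1]]
}

## -------------------------------------------------------- orientation ----

orientation_factors <- function(phi, theta, p) {
  rho_ip <- exp(p$alpha * cos(2 * phi)) / besselI(p$alpha, 0)
  rho_op <- if (p$beta < 1e-12) rep(1, length(theta))
  else 2 * sqrt(2 * p$beta / pi) *
    exp(p$beta * (cos(2 * theta) - 1)) / erf(sqrt(2 * p$beta))
  rho_ip * rho_op
}

#' Bivariate von Mises orientation density
#'
#' Product of the in-plane factor in the azimuth Phi and the out-of-plane
#' factor in the elevation Theta. With `normalized = FALSE` the analytic
#' factors are returned as printed (each normalized against a uniform
#' angular reference measure); with `normalized = TRUE` (default) the
#' product is rescaled by a numerically computed constant so that it
#' integrates to one against the spherical area measure
#' cos(Theta) dTheta dPhi.
#'
#' @param phi azimuth in [0, 2*pi] (vectorized)
#' @param theta elevation in [-pi/2, pi/2] (vectorized)
#' @param p an [orientation_params()] object with finite concentrations
#' @param normalized logical, see Details
#' @return density values
#' @export
orientation_pdf <- function(phi, theta, p, normalized = TRUE) {
  stopifnot(inherits(p, "orientation_params"))
  if (p$aligned_ip || p$aligned_op)
    stop_invalid("orientation_pdf requires finite concentrations; ",
                 "use orientation_sample for the aligned degenerate case")
  val <- orientation_factors(phi, theta, p)
  if (!normalized) return(val)
  val / orientation_norm_const(p)
}

orientation_norm_const <- function(p) {
  ## integral of the analytic product against cos(theta) dtheta dphi
  ip <- stats::integrate(function(ph) exp(p$alpha * cos(2 * ph)),
                         0, 2 * pi, rel.tol = 1e-10)$value / besselI(p$alpha, 0)
  opf <- function(th) {
    f <- if (p$beta < 1e-12) rep(1, length(th))
    else 2 * sqrt(2 * p$beta / pi) *
      exp(p$beta * (cos(2 * th) - 1)) / erf(sqrt(2 * p$beta))
    f * cos(th)
  }
  op <- stats::integrate(opf, -pi / 2, pi / 2, rel.tol = 1e-10)$value
  ip * op
}

#' Sample unit fiber directions from the orientation distribution
#'
#' Angles are drawn by rejection sampling (the normalization constant
#' cancels): the azimuth against a uniform proposal, the elevation against
#' the uniform-on-the-sphere proposal (so isotropic concentrations give
#' directions uniform on the sphere). Aligned (`Inf`) concentrations pin
#' the corresponding angle to zero exactly; perfect alignment returns
#' every direction equal to (1,0,0).
#'
#' @param p an [orientation_params()] object
#' @param n number of directions
#' @param seed integer seed
#' @return an `n` x 3 matrix of unit vectors
#' @export
orientation_sample <- function(p, n, seed) {
  stopifnot(inherits(p, "orientation_params"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_invalid("'n' must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    phi <- if (p$aligned_ip) rep(0, n) else sample_vonmises_phi(p$alpha, n)
    theta <- if (p$aligned_op) rep(0, n) else sample_vonmises_theta(p$beta, n)
    cbind(cos(phi) * cos(theta), sin(phi) * cos(theta), sin(theta))
  })
}

sample_vonmises_phi <- function(alpha, n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- (n - length(out)) * 2L + 16L
    ph <- stats::runif(m, 0, 2 * pi)
    acc <- stats::runif(m) < exp(alpha * (cos(2 * ph) - 1))
    out <- c(out, ph[acc])
  }
  out[seq_len(n)]
}

sample_vonmises_theta <- function(beta, n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- (n - length(out)) * 2L + 16L
    th <- asin(stats::runif(m, -1, 1))   # uniform on the sphere
    acc <- stats::runif(m) < exp(beta * (cos(2 * th) - 1))
    out <- c(out, th[acc])
  }
  out[seq_len(n)]
}
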