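## Two-step inverse identification of the Ogden constants: step 1 fits the
## ground matrix (mu_m, alpha_m) to compression-FF and tension-TT curves
## jointly, using the analytic incompressible uniaxial model (aligned
## fibers contribute nothing in these modes); step 2 fits the embedded
## fibers (mu_f, alpha_f) to the tension-FF curve with forward evaluations
## of the homogenization engine. Both steps minimize the unweighted sum of
## squared stress residuals under box bounds.

#' Experimental (or pseudo-experimental) stress curves
#'
#' A named collection of per-mode stress-deformation arrays.
#'
#' @param curves named list; each element a data.frame/list with `amount`
#'   (strictly monotone) and `stress` (Pa)
#' @return object of class `experiment_curves`
#' @export
experiment_curves <- function(curves) {
  if (!is.list(curves) || is.null(names(curves)) || !length(curves))
    stop_invalid("'curves' must be a non-empty named list")
  bad <- setdiff(names(curves), loading_mode_labels)
  if (length(bad)) stop_invalid("unknown mode(s): ", paste(bad, collapse = ", "))
  out <- lapply(curves, function(cv) {
    cv <- as.data.frame(cv)
    if (!all(c("amount", "stress") %in% names(cv)))
      stop_invalid("each curve needs 'amount' and 'stress'")
    if (any(diff(cv$amount) <= 0)) stop_invalid("'amount' must be strictly increasing")
    cv[, c("amount", "stress")]
  })
  structure(out, class = "experiment_curves")
}

#' @export
print.experiment_curves <- function(x, ...) {
  cat("Experiment curves:",
      paste(sprintf("%s (%d pts)", names(x), vapply(x, nrow, 0L)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Sum of squared stress residuals between two curve sets
#'
#' The objective of the identification: the unweighted sum over all shared
#' modes and experimental points of `(P_exp - P_sim)^2`, with the
#' simulated curve linearly interpolated onto the experimental amounts.
#'
#' @param sim,exp [experiment_curves()] objects (or named lists coercible)
#' @return scalar (Pa^2)
#' @export
chi2 <- function(sim, exp) {
  sim <- experiment_curves(unclass(sim)); exp <- experiment_curves(unclass(exp))
  shared <- intersect(names(sim), names(exp))
  if (!length(shared)) stop_invalid("curve sets share no loading mode")
  sum(vapply(shared, function(m) {
    ps <- stats::approx(sim[[m]]$amount, sim[[m]]$stress,
                        xout = exp[[m]]$amount, rule = 2)$y
    sum((exp[[m]]$stress - ps)^2)
  }, numeric(1)))
}

truncate_curve <- function(cv, max_deformation, shear = FALSE) {
  keep <- if (shear) cv$amount <= max_deformation + 1e-12
  else abs(cv$amount - 1) <= max_deformation + 1e-12
  cv[keep, , drop = FALSE]
}

## deterministic interior multistart grid inside box bounds
interior_starts <- function(lower, upper, k = 5) {
  frac <- seq(0.15, 0.85, length.out = k)
  lo <- pmax(lower, c(-500, -500)); up <- pmin(upper, c(500, 500))
  lapply(seq_len(k), function(i) lo + frac[i] * (up - lo))
}

#' Step 1: fit the ground-matrix Ogden parameters
#'
#' Bounded least squares (Levenberg-Marquardt with box bounds) of the
#' analytic incompressible uniaxial nominal-stress model to the
#' compression-FF and tension-TT curves jointly, restricted to 10 percent
#' deformation. For aligned fiber networks the fibers contribute nothing
#' in either mode, so the matrix is identified in isolation. Five
#' deterministic interior starting points guard against local minima.
#'
#' @param exp an [experiment_curves()] object containing `compression_FF`
#'   and `tension_TT`
#' @param bounds list with `lower` and `upper` length-2 vectors for
#'   `(mu_m, alpha_m)`; defaults to mu in [50, 5000] Pa, alpha in [-50, 50]
#' @param max_deformation data truncation (default 0.10)
#' @return list of class `matrix_fit`: `params` ([matrix_params()] with
#'   the default volumetric compliance), `chi2`, `starts` (per-start
#'   results), `bound_active`, `converged`
#' @export
fit_matrix <- function(exp, bounds = list(lower = c(50, -50),
                                          upper = c(5000, 50)),
                       max_deformation = 0.10) {
  exp <- experiment_curves(unclass(exp))
  need <- c("compression_FF", "tension_TT")
  if (!all(need %in% names(exp)))
    stop_invalid("fit_matrix needs modes ", paste(need, collapse = " and "))
  dat <- lapply(exp[need], truncate_curve, max_deformation = max_deformation)
  lam <- c(dat[[1]]$amount, dat[[2]]$amount)
  pexp <- c(dat[[1]]$stress, dat[[2]]$stress)
  resid_fn <- function(th) uniaxial_incompressible_nominal(lam, th[1], th[2]) - pexp
  runs <- lapply(interior_starts(bounds$lower, bounds$upper), function(th0) {
    fit <- try(minpack.lm::nls.lm(par = th0, fn = resid_fn,
                                  lower = bounds$lower, upper = bounds$upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = fit$par, chi2 = sum(fit$fvec^2), info = fit$info)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop_invalid("matrix fit failed from all starting points")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "chi2"))]]
  on_bound <- abs(best$par - bounds$lower) < 1e-6 |
    abs(best$par - bounds$upper) < 1e-6
  if (any(on_bound))
    warning("matrix fit ended on a bound; possible non-interior optimum")
  structure(list(params = matrix_params(best$par[1], best$par[2]),
                 mu = best$par[1], alpha = best$par[2],
                 chi2 = best$chi2, starts = runs,
                 bound_active = on_bound, converged = TRUE),
            class = "matrix_fit")
}

#' @export
print.matrix_fit <- function(x, ...) {
  cat(sprintf("Matrix fit: mu_m = %.4g Pa, alpha_m = %.4g (chi2 = %.3g Pa^2)\n",
              x$mu, x$alpha, x$chi2))
  invisible(x)
}

#' Step 2: fit the embedded-fiber Ogden parameters
#'
#' Bounded least squares of the homogenized tension-FF curve (forward
#' evaluations of [response_curve()] on a fixed network) against the
#' experimental tension-FF data up to 10 percent stretch, with the matrix
#' parameters held fixed. The affine engine is the default forward model;
#' the FE engine is available via `engine = "fe"`. The fiber exponent is
#' unbounded in principle and soft-clamped at +-500 internally to avoid
#' overflow in `lambda^alpha`. If no fiber is recruited over the data
#' range the objective is flat in the fiber parameters and the result is
#' flagged non-identifiable.
#'
#' @param exp an [experiment_curves()] object containing `tension_FF`
#' @param mp fixed [matrix_params()] from step 1
#' @param net the [fiber_network()] on which the forward model runs
#' @param engine `"affine"` or `"fe"`
#' @param bounds list with `lower`/`upper` for `(mu_f, alpha_f)`;
#'   defaults mu_f in [20, 5000] Pa, alpha_f unbounded
#' @param max_deformation data truncation (default 0.10)
#' @param starts optional list of starting `(mu_f, alpha_f)` pairs
#' @param fe_opts options passed to the FE engine
#' @return list of class `fiber_fit`: `params` ([fiber_params()]),
#'   `chi2`, `bound_active`, `identifiable`, `starts`
#' @export
fit_fibers <- function(exp, mp, net, engine = c("affine", "fe"),
                       bounds = list(lower = c(20, -Inf),
                                     upper = c(5000, Inf)),
                       max_deformation = 0.10, starts = NULL,
                       fe_opts = list()) {
  engine <- match.arg(engine)
  exp <- experiment_curves(unclass(exp))
  if (!"tension_FF" %in% names(exp))
    stop_invalid("fit_fibers needs a tension_FF curve")
  stopifnot(inherits(mp, "matrix_params"), inherits(net, "fiber_network"))
  dat <- truncate_curve(exp$tension_FF, max_deformation)
  lam <- dat$amount; pexp <- dat$stress
  ## identifiability: is any fiber recruited anywhere on the data range?
  lam_max <- max(lam)
  identifiable <- any(1 / net$fibers$Ps <= lam_max)
  lower <- pmax(bounds$lower, c(-Inf, -500))
  upper <- pmin(bounds$upper, c(Inf, 500))
  resid_fn <- function(th) {
    fp <- fiber_params(th[1], th[2])
    cv <- response_curve(net, "tension_FF", mp = mp, fp = fp,
                         amounts = lam, engine = engine, fe_opts = fe_opts)
    cv$P_total - pexp
  }
  if (is.null(starts))
    starts <- list(c(100, 10), c(100, 40), c(100, 80), c(500, 25), c(50, 60))
  runs <- lapply(starts, function(th0) {
    fit <- try(minpack.lm::nls.lm(par = th0, fn = resid_fn,
                                  lower = lower, upper = upper,
                                  control = minpack.lm::nls.lm.control(
                                    maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
               silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = fit$par, chi2 = sum(fit$fvec^2), info = fit$info)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop_invalid("fiber fit failed from all starting points")
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "chi2"))]]
  on_bound <- (abs(best$par - lower) < 1e-6 | abs(best$par - upper) < 1e-6) &
    is.finite(lower) & is.finite(upper)
  if (!identifiable)
    warning("no fiber recruited over the data range; ",
            "fiber parameters are not identifiable")
  structure(list(params = fiber_params(best$par[1], best$par[2]),
                 mu = best$par[1], alpha = best$par[2], chi2 = best$chi2,
                 starts = runs, bound_active = on_bound,
                 identifiable = identifiable, engine = engine),
            class = "fiber_fit")
}

#' @export
print.fiber_fit <- function(x, ...) {
  cat(sprintf("Fiber fit (%s engine): mu_f = %.4g Pa, alpha_f = %.4g (chi2 = %.3g Pa^2)%s\n",
              x$engine, x$mu, x$alpha, x$chi2,
              if (!x$identifiable) " [NOT IDENTIFIABLE]" else ""))
  invisible(x)
}

#' Two-step identification of matrix and fiber parameters
#'
#' Runs [fit_matrix()] on compression-FF / tension-TT, then [fit_fibers()]
#' on tension-FF with the matrix fixed; records everything needed to
#' reproduce the run.
#'
#' @param exp an [experiment_curves()] object with the required modes
#' @param net the forward-model [fiber_network()]
#' @param engine forward engine for step 2
#' @param matrix_bounds,fiber_bounds bound lists (see the step functions)
#' @param max_deformation data truncation for both steps (default 0.10)
#' @param fe_opts options for the FE engine
#' @return list of class `ident_result`: `matrix_fit`, `fiber_fit`,
#'   `matrix_params`, `fiber_params`, `chi2` (per step), `network_seed`
#' @export
identify_two_step <- function(exp, net, engine = c("affine", "fe"),
                              matrix_bounds = list(lower = c(50, -50),
                                                   upper = c(5000, 50)),
                              fiber_bounds = list(lower = c(20, -Inf),
                                                  upper = c(5000, Inf)),
                              max_deformation = 0.10, fe_opts = list()) {
  engine <- match.arg(engine)
  step1 <- fit_matrix(exp, bounds = matrix_bounds,
                      max_deformation = max_deformation)
  step2 <- fit_fibers(exp, step1$params, net, engine = engine,
                      bounds = fiber_bounds,
                      max_deformation = max_deformation, fe_opts = fe_opts)
  structure(list(matrix_fit = step1, fiber_fit = step2,
                 matrix_params = step1$params, fiber_params = step2$params,
                 chi2 = c(matrix = step1$chi2, fiber = step2$chi2),
                 network_seed = net$seed, engine = engine),
            class = "ident_result")
}

#' @export
print.ident_result <- function(x, ...) {
  cat("Two-step identification\n")
  print(x$matrix_fit); print(x$fiber_fit)
  invisible(x)
}

## ---------------------------------------------------------------- IO ----

#' Write / read experiment curves (per-mode CSVs + JSON manifest)
#'
#' @param exp an [experiment_curves()] object
#' @param dir output directory (created if missing)
#' @return `read_experiment()` returns the reconstructed object
#' @export
write_experiment <- function(exp, dir) {
  exp <- experiment_curves(unclass(exp))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in names(exp))
    utils::write.csv(exp[[m]], file.path(dir, paste0(m, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(list(modes = names(exp)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  experiment_curves(stats::setNames(lapply(man$modes, function(m)
    utils::read.csv(file.path(dir, paste0(m, ".csv")))), man$modes))
}

#' Write an identification result as JSON
#'
#' Mirrors the layout of a material-parameter table: one block for the
#' ground matrix, one for the embedded fibers, plus the per-step residuals.
#' @param res an `ident_result`
#' @param path JSON file
#' @export
write_ident_result <- function(res, path) {
  jsonlite::write_json(list(
    ground_matrix = list(mu_Pa = res$matrix_fit$mu,
                         alpha = res$matrix_fit$alpha),
    embedded_fibers = list(mu_Pa = res$fiber_fit$mu,
                           alpha = res$fiber_fit$alpha),
    chi2 = as.list(res$chi2), engine = res$engine,
    network_seed = res$network_seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
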