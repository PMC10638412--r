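## Pseudo-experimental data: forward-model stress curves with optional
## multiplicative noise, and distribution sample fixtures. Every test of
## the identification pipeline can source its inputs from here plus the
## printed structural/material parameter tables.

#' Configuration for pseudo-experimental curve generation
#'
#' @param mp,fp ground-truth material parameters
#' @param sp ground-truth [structural_params()]
#' @param La RVE edge length (um) for the forward network
#' @param modes loading modes to generate
#' @param grids named list of amount grids (defaults: 21 points to 10
#'   percent deformation per mode)
#' @param noise_sd multiplicative noise level sigma (default 0.05;
#'   `stress * (1 + sigma * eps)` with standard normal `eps`)
#' @param noise `"multiplicative"` (default) or `"additive"` (then
#'   `noise_sd` is in Pa)
#' @param seed integer seed (network and noise both derive from it)
#' @param engine forward engine
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(mp, fp, sp, La = 25,
                             modes = c("compression_FF", "tension_TT",
                                       "tension_FF"),
                             grids = NULL, noise_sd = 0.05,
                             noise = c("multiplicative", "additive"),
                             seed = 1L, engine = c("affine", "fe")) {
  stopifnot(inherits(mp, "matrix_params"), inherits(fp, "fiber_params"),
            inherits(sp, "structural_params"))
  noise <- match.arg(noise); engine <- match.arg(engine)
  if (noise_sd < 0) stop_invalid("'noise_sd' must be >= 0")
  for (m in modes) check_mode(m)
  if (is.null(grids)) {
    grids <- lapply(modes, function(m) {
      if (!is_uniaxial_mode(m)) seq(0, 0.2, length.out = 21)
      else if (startsWith(m, "compression")) seq(0.90, 1, length.out = 21)
      else seq(1, 1.10, length.out = 21)
    })
    names(grids) <- modes
  }
  structure(list(mp = mp, fp = fp, sp = sp, La = La, modes = modes,
                 grids = grids, noise_sd = noise_sd, noise = noise,
                 seed = as.integer(seed), engine = engine),
            class = "synthetic_config")
}

#' Generate pseudo-experimental stress curves
#'
#' Runs the forward model (default: affine engine on a network generated
#' from the configured structural parameters) on the configured grids and
#' perturbs the stresses with the configured noise. Identity points
#' (stretch 1 / zero shear) are never perturbed: the zero-stress reference
#' state is a physical anchor. Fully reproducible from the seed; the
#' generated network is attached as attribute `"network"`.
#'
#' @param cfg a [synthetic_config()] object
#' @return an [experiment_curves()] object
#' @export
make_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  net <- generate_rve(cfg$sp, cfg$La, seed = cfg$seed)
  ## compression grids are decreasing in stretch: sort for the curve
  curves <- list()
  for (m in cfg$modes) {
    g <- sort(cfg$grids[[m]])
    cv <- response_curve(net, m, mp = cfg$mp, fp = cfg$fp, amounts = g,
                         engine = cfg$engine)
    stress <- cv$P_total
    if (cfg$noise_sd > 0) {
      eps <- with_seed(cfg$seed + match(m, cfg$modes), stats::rnorm(length(g)))
      idpt <- if (is_uniaxial_mode(m)) abs(g - 1) < 1e-12 else g < 1e-12
      pert <- if (cfg$noise == "multiplicative")
        stress * (1 + cfg$noise_sd * eps) else stress + cfg$noise_sd * eps
      stress <- ifelse(idpt, stress, pert)
    }
    curves[[m]] <- data.frame(amount = g, stress = stress)
  }
  out <- experiment_curves(curves)
  attr(out, "network") <- net
  attr(out, "config") <- cfg
  out
}

#' Write a distribution sample fixture to CSV
#'
#' Samples the requested family with the package's own samplers and
#' writes a one-column CSV in the format [read_sample_csv()] consumes.
#' Byte-identical for a fixed seed.
#'
#' @param family `"gev"` or `"beta"`
#' @param params a [gev_params()] or [beta_params()] object
#' @param n sample size
#' @param seed integer seed
#' @param path output CSV
#' @return `path`, invisibly
#' @export
make_histogram_fixture <- function(family = c("gev", "beta"), params, n,
                                   seed, path) {
  family <- match.arg(family)
  x <- switch(family,
              gev = gev_sample(params, n, seed),
              beta = beta_sample(params, n, seed))
  writeLines(c("value", sprintf("%.17g", as.numeric(x))), path)
  invisible(path)
}
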