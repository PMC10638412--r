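## Study orchestration: the RVE-size convergence study and the command-line
## dispatcher used by the inst/cli/wmrve script.

#' Default corpus callosum structural parameters
#'
#' The fitted histology statistics for human corpus callosum: volume
#' fraction 0.400, GEV diameter law (0.426, 0.200, -0.305) um, beta
#' straightness law (9.155, 1.275) and perfectly aligned orientation.
#'
#' @return a [structural_params()] object
#' @export
cc_structural_params <- function() {
  structural_params(0.400,
                    gev_params(0.426, 0.200, -0.305),
                    beta_params(9.155, 1.275),
                    orientation_params(Inf, Inf))
}

#' Identified corpus callosum material parameters
#'
#' Ground matrix (353.5 Pa, -21.5) with the default volumetric compliance
#' and embedded fibers (80.8 Pa, 62.3).
#'
#' @return list with elements `matrix` and `fiber`
#' @export
cc_material_params <- function() {
  list(matrix = matrix_params(353.5, -21.5), fiber = fiber_params(80.8, 62.3))
}

#' RVE-size convergence study
#'
#' Generates `n` random networks per edge length (seeds derived
#' deterministically from the base seed: `base + replicate index`,
#' counted over all groups), homogenizes one loading mode to the final
#' amount, and summarizes the work-conjugate stress per group. The
#' convergence indicator is the coefficient of variation sd/mean, which
#' narrows as the RVE grows.
#'
#' @param edge_lengths strictly increasing RVE edge lengths (um)
#' @param n replicates per group, >= 2
#' @param mode loading-mode label (default `tension_FF`)
#' @param amount final loading amount (default 1.2)
#' @param sp structural parameters (default [cc_structural_params()])
#' @param mp,fp material parameters (default [cc_material_params()])
#' @param engine `"affine"` (default) or `"fe"`
#' @param base_seed base integer seed
#' @param fe_opts options for the FE engine
#' @return data.frame of class `convergence_study` with one row per
#'   group: `La`, `n`, `mean`, `sd`, `min`, `max`, `cv`, `Nf_min`,
#'   `Nf_max`, `failures`; per-replicate values in attribute `replicates`
#' @export
run_convergence <- function(edge_lengths = c(5, 15, 25, 50), n = 10,
                            mode = "tension_FF", amount = 1.2,
                            sp = cc_structural_params(),
                            mp = cc_material_params()$matrix,
                            fp = cc_material_params()$fiber,
                            engine = c("affine", "fe"), base_seed = 1L,
                            fe_opts = list(), allow_long = FALSE) {
  engine <- match.arg(engine)
  check_mode(mode)
  if (engine == "fe" && any(edge_lengths > 25) && !allow_long)
    stop_invalid("FE groups above La = 25 um are long-running; ",
                 "set allow_long = TRUE to proceed")
  if (n < 2) stop_invalid("'n' must be >= 2")
  if (length(edge_lengths) < 1 || any(diff(edge_lengths) <= 0))
    stop_invalid("'edge_lengths' must be strictly increasing")
  rep_rows <- list(); k <- 0L
  for (gi in seq_along(edge_lengths)) {
    La <- edge_lengths[gi]
    for (r in seq_len(n)) {
      k <- k + 1L
      seed <- base_seed + k
      stress <- NA_real_; Nf <- NA_integer_; ok <- FALSE
      res <- try({
        net <- generate_rve(sp, La, seed = seed)
        cv <- response_curve(net, mode, mp = mp, fp = fp,
                             amounts = c(if (is_uniaxial_mode(mode)) 1 else 0,
                                         amount),
                             engine = engine, fe_opts = fe_opts)
        stress <- cv$P_total[nrow(cv)]
        Nf <- nrow(net$fibers)
        ok <- TRUE
      }, silent = TRUE)
      rep_rows[[k]] <- data.frame(La = La, replicate = r, seed = seed,
                                  stress = stress, Nf = Nf, ok = ok)
    }
  }
  reps <- do.call(rbind, rep_rows)
  groups <- lapply(split(reps, reps$La), function(g) {
    s <- g$stress[g$ok]
    data.frame(La = g$La[1], n = sum(g$ok), mean = mean(s), sd = stats::sd(s),
               min = min(s), max = max(s), cv = stats::sd(s) / mean(s),
               Nf_min = min(g$Nf[g$ok]), Nf_max = max(g$Nf[g$ok]),
               failures = sum(!g$ok))
  })
  out <- do.call(rbind, groups)
  out <- out[order(out$La), ]
  rownames(out) <- NULL
  structure(out, replicates = reps, mode = mode, amount = amount,
            engine = engine, base_seed = base_seed,
            class = c("convergence_study", "data.frame"))
}

## --------------------------------------------------------------- CLI ----

cli_usage <- function() {
  paste(
    "usage: wmrve <command> [options]",
    "commands:",
    "  generate-rve   --config FILE --out PREFIX   generate and write a network",
    "  simulate       --config FILE --out PREFIX   homogenize a response curve",
    "  identify       --config FILE --out FILE     two-step identification",
    "  convergence    --config FILE --out FILE     RVE-size convergence study",
    "  make-synthetic --config FILE --out DIR      pseudo-experimental curves",
    "config: YAML; every run logs its resolved configuration and seeds.",
    sep = "\n")
}

cli_structural <- function(cfg) {
  s <- cfg$structural %||% list()
  structural_params(
    s$v_f %||% 0.400,
    do.call(gev_params, as.list(s$diameter %||% c(0.426, 0.200, -0.305))),
    do.call(beta_params, as.list(s$straightness %||% c(9.155, 1.275))),
    do.call(orientation_params,
            lapply(as.list(s$orientation %||% c(Inf, Inf)),
                   function(v) if (identical(v, "Inf")) Inf else as.numeric(v))))
}

cli_materials <- function(cfg) {
  m <- cfg$material %||% list()
  list(matrix = do.call(matrix_params, as.list(m$matrix %||%
                                                 list(mu = 353.5, alpha = -21.5))),
       fiber = do.call(fiber_params, as.list(m$fiber %||%
                                               list(mu = 80.8, alpha = 62.3))))
}

#' Command-line dispatcher
#'
#' Backs the `inst/cli/wmrve` Rscript; exposed so the commands can be
#' driven (and tested) in-process. Returns the exit status instead of
#' calling `quit()`.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status (0 on success)
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  log_msg <- function(...) message("[wmrve] ", ...)
  fail <- function(...) { message("error: ", ...); 1L }
  if (!length(args)) { message(cli_usage()); return(1L) }
  cmd <- args[1]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opts[[substring(args[i], 3)]] <- args[i + 1L]; i <- i + 2L
    } else return(fail("cannot parse argument '", args[i], "'"))
  }
  if (is.null(opts$config)) return(fail("--config FILE is required"))
  if (!file.exists(opts$config))
    return(fail("config file not found: ", opts$config))
  cfg <- yaml::read_yaml(opts$config)
  out <- opts$out %||% "wmrve_out"
  seed <- as.integer(cfg$seed %||% 1L)
  res <- tryCatch(switch(
    cmd,
    "generate-rve" = {
      sp <- cli_structural(cfg)
      net <- generate_rve(sp, as.numeric(cfg$La %||% 25), seed = seed)
      write_network(net, paste0(out, ".csv"))
      log_msg("wrote ", paste0(out, ".csv"), " (N_f = ", nrow(net$fibers),
              ", v_f = ", signif(net$achieved_vf, 4), ", seed ", seed, ")")
      0L
    },
    "simulate" = {
      mat <- cli_materials(cfg)
      net <- if (!is.null(cfg$network)) read_network(cfg$network)
      else generate_rve(cli_structural(cfg), as.numeric(cfg$La %||% 25),
                        seed = seed)
      mode <- cfg$mode %||% "tension_FF"
      engine <- cfg$engine %||% "affine"
      if (!engine %in% c("affine", "fe"))
        stop_invalid("unknown engine '", engine, "' (valid: affine, fe)")
      cvr <- response_curve(net, mode,
                            max_amount = as.numeric(cfg$amount %||%
                                                      if (startsWith(mode, "shear")) 0.2 else 1.2),
                            mp = mat$matrix, fp = mat$fiber,
                            n_steps = as.integer(cfg$n_steps %||% 21),
                            engine = engine)
      write_curve(cvr, paste0(out, ".csv"),
                  metadata = list(seed = seed, engine = engine,
                                  units = list(length = "um", stress = "Pa")))
      log_msg("wrote ", paste0(out, ".csv"), " (mode ", mode, ", engine ",
              engine, ", seed ", seed, ")")
      0L
    },
    "identify" = {
      exp <- read_experiment(cfg$experiment)
      net <- if (!is.null(cfg$network)) read_network(cfg$network)
      else generate_rve(cli_structural(cfg), as.numeric(cfg$La %||% 25),
                        seed = seed)
      r <- identify_two_step(exp, net, engine = cfg$engine %||% "affine")
      write_ident_result(r, out)
      log_msg("wrote ", out)
      print(r)
      0L
    },
    "convergence" = {
      mat <- cli_materials(cfg)
      st <- run_convergence(
        edge_lengths = as.numeric(cfg$edge_lengths %||% c(5, 15, 25, 50)),
        n = as.integer(cfg$n %||% 10),
        mode = cfg$mode %||% "tension_FF",
        amount = as.numeric(cfg$amount %||% 1.2),
        sp = cli_structural(cfg), mp = mat$matrix, fp = mat$fiber,
        engine = cfg$engine %||% "affine", base_seed = seed,
        allow_long = isTRUE(cfg$allow_long))
      utils::write.csv(as.data.frame(st), out, row.names = FALSE)
      log_msg("wrote ", out)
      0L
    },
    "make-synthetic" = {
      mat <- cli_materials(cfg)
      sc <- synthetic_config(mat$matrix, mat$fiber, cli_structural(cfg),
                             La = as.numeric(cfg$La %||% 25),
                             noise_sd = as.numeric(cfg$noise_sd %||% 0.05),
                             seed = seed)
      exp <- make_experiment(sc)
      write_experiment(exp, out)
      log_msg("wrote curves to ", out, " (seed ", seed, ")")
      0L
    },
    { message(cli_usage()); 1L }),
    error = function(e) { message("error: ", conditionMessage(e)); 1L })
  if (is.null(res)) 0L else res
}
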