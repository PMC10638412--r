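## Random axon-fiber network generation inside a cubic RVE. Fibers are
## straight 1-D chords clipped to the cube (no periodic wrapping); volume
## bookkeeping uses the end-to-end (chord) length, tortuosity entering the
## model only through the constitutive recruitment law.

#' Structural parameters of an RVE population
#'
#' Histology statistics that define a random network: target fiber volume
#' fraction plus the diameter, straightness and orientation laws.
#'
#' @param v_f target fiber volume fraction in (0, 1)
#' @param diameter a [gev_params()] object (um)
#' @param straightness a [beta_params()] object
#' @param orientation an [orientation_params()] object
#' @return object of class `structural_params`
#' @export
#' @examples
#' sp <- structural_params(0.400,
#'                         gev_params(0.426, 0.200, -0.305),
#'                         beta_params(9.155, 1.275),
#'                         orientation_params(Inf, Inf))
structural_params <- function(v_f, diameter, straightness, orientation) {
  check_scalar(v_f, "v_f")
  if (v_f <= 0 || v_f >= 1) stop_invalid("'v_f' must lie in (0, 1)")
  stopifnot(inherits(diameter, "gev_params"),
            inherits(straightness, "beta_params"),
            inherits(orientation, "orientation_params"))
  structure(list(v_f = v_f, diameter = diameter,
                 straightness = straightness, orientation = orientation),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf("Structural parameters: v_f = %g\n", x$v_f))
  print(x$diameter); print(x$straightness); print(x$orientation)
  invisible(x)
}

#' Construct a fiber network object
#'
#' Usually produced by [generate_rve()]; the constructor is exported so
#' that deterministic benchmark networks (e.g. a single straight fiber)
#' can be built directly.
#'
#' @param La RVE edge length (um)
#' @param fibers data.frame with columns `anchor_x, anchor_y, anchor_z,
#'   Nx, Ny, Nz, L0, d, Ps`
#' @param seed integer seed used for generation (NA for hand-built)
#' @param metadata optional list stored alongside
#' @return object of class `fiber_network`
#' @export
fiber_network <- function(La, fibers, seed = NA_integer_, metadata = list()) {
  check_scalar(La, "La", positive = TRUE)
  cols <- c("anchor_x", "anchor_y", "anchor_z", "Nx", "Ny", "Nz", "L0", "d", "Ps")
  if (!is.data.frame(fibers) || !all(cols %in% names(fibers)))
    stop_invalid("'fibers' must be a data.frame with columns ",
                 paste(cols, collapse = ","))
  fibers <- fibers[, cols, drop = FALSE]
  if (nrow(fibers)) {
    if (any(fibers$d <= 0)) stop_invalid("fiber diameters must be > 0")
    if (any(fibers$L0 <= 0)) stop_invalid("fiber lengths must be > 0")
    if (any(fibers$Ps <= 0 | fibers$Ps > 1))
      stop_invalid("straightness must lie in (0, 1]")
  }
  net <- structure(list(La = La, fibers = fibers, seed = seed,
                        achieved_vf = 0, metadata = metadata),
                   class = "fiber_network")
  net$achieved_vf <- network_volume_fraction(net)
  net
}

#' @export
print.fiber_network <- function(x, ...) {
  cat(sprintf("Fiber network: La = %g um, N_f = %d, v_f = %0.4f (seed %s)\n",
              x$La, nrow(x$fibers), x$achieved_vf, format(x$seed)))
  invisible(x)
}

#' Fiber volume fraction of a network
#'
#' Sum over fibers of `pi d^2/4 * L0` divided by the cube volume `La^3`.
#' The default uses the end-to-end (chord) length `L0` — tortuosity acts
#' through the constitutive recruitment law, so arc length would
#' double-count it; `use_arc_length = TRUE` switches to the arc length
#' `L0/Ps` for comparison.
#'
#' @param net a [fiber_network()] object
#' @param use_arc_length logical; divide each chord length by its
#'   straightness
#' @return dimensionless volume fraction (0 for an empty network)
#' @export
network_volume_fraction <- function(net, use_arc_length = FALSE) {
  stopifnot(inherits(net, "fiber_network"))
  if (!nrow(net$fibers)) return(0)
  L <- if (use_arc_length) net$fibers$L0 / net$fibers$Ps else net$fibers$L0
  sum(pi * net$fibers$d^2 / 4 * L) / net$La^3
}

## chord of the line anchor + t*N through the [0,La]^3 cube (slab method)
cube_chord <- function(anchor, N, La) {
  t_lo <- -Inf; t_hi <- Inf
  for (i in 1:3) {
    if (abs(N[i]) > 1e-14) {
      ts <- sort(c((0 - anchor[i]) / N[i], (La - anchor[i]) / N[i]))
      t_lo <- max(t_lo, ts[1]); t_hi <- min(t_hi, ts[2])
    }
  }
  c(t_lo, t_hi)
}

#' Generate a random fiber network inside a cubic RVE
#'
#' Fibers are added one at a time: a direction from the orientation law,
#' an interior anchor point uniform in the cube, the segment extended to
#' the cube boundary in both directions, a diameter from the GEV law and a
#' straightness from the beta law, until the cumulative fiber volume
#' reaches `v_f * La^3`. The achieved volume fraction overshoots the
#' target by at most one fiber's volume. Chords shorter than `min_length`
#' are rejected (keeps the finite-element embedding well-posed).
#'
#' @param sp a [structural_params()] object
#' @param La RVE edge length (um)
#' @param seed integer seed; a fixed seed reproduces the network bit-for-bit
#' @param min_length minimum chord length kept (um); default `La/20`
#' @param max_fibers safety bound on the number of fibers attempted
#' @return a [fiber_network()] object
#' @export
#' @examples
#' sp <- structural_params(0.4, gev_params(0.426, 0.2, -0.305),
#'                         beta_params(9.155, 1.275), orientation_params(Inf, Inf))
#' net <- generate_rve(sp, La = 10, seed = 1)
generate_rve <- function(sp, La, seed, min_length = La / 20,
                         max_fibers = 1e6) {
  stopifnot(inherits(sp, "structural_params"))
  check_scalar(La, "La", positive = TRUE)
  target <- sp$v_f * La^3
  rejected_short <- 0L; rejected_diam <- 0L
  with_seed(seed, {
    rows <- vector("list", 64L); nrows <- 0L
    vol <- 0; total <- 0L
    while (vol < target) {
      if (total >= max_fibers)
        stop_invalid("failed to reach target volume fraction within ",
                     max_fibers, " fibers (achieved ", signif(vol / La^3, 4),
                     " of ", sp$v_f, ")")
      batch <- min(256L, max_fibers - total)
      ## draw a batch; order of draws fixed: directions, anchors, d, Ps
      N <- sample_directions(sp$orientation, batch)
      anchor <- matrix(stats::runif(3L * batch, 0, La), ncol = 3L)
      d <- sample_diameters(sp$diameter, batch)
      rejected_diam <- rejected_diam + attr(d, "rejected")
      Ps <- stats::rbeta(batch, sp$straightness$a, sp$straightness$b)
      for (i in seq_len(batch)) {
        total <- total + 1L
        tt <- cube_chord(anchor[i, ], N[i, ], La)
        L0 <- tt[2] - tt[1]
        if (!is.finite(L0) || L0 < min_length) {
          rejected_short <- rejected_short + 1L
          next
        }
        p1 <- anchor[i, ] + tt[1] * N[i, ]
        nrows <- nrows + 1L
        if (nrows > length(rows)) length(rows) <- 2L * nrows
        rows[[nrows]] <- c(p1, N[i, ], L0, d[i], Ps[i])
        vol <- vol + pi * d[i]^2 / 4 * L0
        if (vol >= target) break
      }
    }
    fib <- do.call(rbind, rows[seq_len(nrows)])
    fibers <- data.frame(anchor_x = fib[, 1], anchor_y = fib[, 2],
                         anchor_z = fib[, 3], Nx = fib[, 4], Ny = fib[, 5],
                         Nz = fib[, 6], L0 = fib[, 7], d = fib[, 8],
                         Ps = fib[, 9])
    net <- fiber_network(La, fibers, seed = seed,
                         metadata = list(
                           structural_params = unclass_params(sp),
                           clipping = "chord", wrapping = "none",
                           min_length = min_length,
                           rejected_short = rejected_short,
                           rejected_nonpositive_diameter = rejected_diam))
    net
  })
}

## in-stream samplers (share the active RNG stream; no nested reseeding)
sample_directions <- function(p, n) {
  phi <- if (p$aligned_ip) rep(0, n) else sample_vonmises_phi(p$alpha, n)
  theta <- if (p$aligned_op) rep(0, n) else sample_vonmises_theta(p$beta, n)
  cbind(cos(phi) * cos(theta), sin(phi) * cos(theta), sin(theta))
}

sample_diameters <- function(p, n) {
  out <- numeric(0); rejected <- 0L
  while (length(out) < n) {
    x <- gev_quantile(stats::runif(n - length(out)), p)
    rejected <- rejected + sum(x <= 0)
    out <- c(out, x[x > 0])
  }
  structure(out, rejected = rejected)
}

unclass_params <- function(sp) {
  list(v_f = sp$v_f,
       diameter = unclass(sp$diameter),
       straightness = unclass(sp$straightness),
       orientation = unclass(sp$orientation)[c("alpha", "beta")])
}

## ------------------------------------------------------------------ IO ----

#' Write / read a fiber network
#'
#' The network is stored as a CSV of fibers plus a JSON sidecar
#' (`<path>.json`) carrying `La`, the seed, the structural parameters and
#' the achieved volume fraction; the round-trip is lossless at full
#' precision.
#'
#' @param net a [fiber_network()] object
#' @param path CSV file path
#' @return `read_network()` returns the reconstructed [fiber_network()]
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "fiber_network"))
  df <- net$fibers
  ## full precision: format with 17 significant digits
  out <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%.17g", as.numeric(df[i, ])), collapse = ","), "")
  writeLines(c(paste(names(df), collapse = ","), out), path)
  jsonlite::write_json(list(La = net$La, seed = net$seed,
                            achieved_vf = net$achieved_vf,
                            metadata = net$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop_invalid("empty network file: ", path)
  header <- strsplit(lines[1], ",")[[1]]
  cols <- c("anchor_x", "anchor_y", "anchor_z", "Nx", "Ny", "Nz", "L0", "d", "Ps")
  if (!identical(header, cols))
    stop_invalid("line 1: malformed header in ", path)
  if (length(lines) == 1L)
    stop_invalid("network file contains a header but no fibers: ", path)
  vals <- lapply(seq.int(2L, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(lines[i], ",")[[1]]))
    if (length(v) != 9L || anyNA(v))
      stop_invalid("line ", i, ": malformed fiber record in ", path)
    if (v[8] <= 0) stop_invalid("line ", i, ": non-positive diameter in ", path)
    if (v[7] <= 0) stop_invalid("line ", i, ": non-positive length in ", path)
    v
  })
  df <- as.data.frame(do.call(rbind, vals))
  names(df) <- cols
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  if (is.null(meta)) stop_invalid("missing JSON sidecar: ", meta_path)
  net <- fiber_network(meta$La, df, seed = meta$seed,
                       metadata = as.list(meta$metadata))
  net
}
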