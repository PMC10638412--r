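#' @keywords internal
"_PACKAGE"

## Units used package-wide: lengths in micrometres, stresses and moduli in
## pascal. Fiber volumes are um^3; forces carried internally by the FE engine
## are Pa.um^2 (consistent, never exposed).

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so library calls never
#' perturb user-level random streams.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## error function (appears in the out-of-plane orientation density)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("wmrve_invalid", "error")))
}

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid("'", name, "' must be a single number")
  if (finite && !is.finite(x)) stop_invalid("'", name, "' must be finite")
  if (positive && x <= 0) stop_invalid("'", name, "' must be > 0")
  invisible(x)
}

## 3x3 identity, used everywhere
I3 <- diag(3)

is_square3 <- function(F) is.matrix(F) && all(dim(F) == c(3L, 3L)) &&
  is.numeric(F) && all(is.finite(F))
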