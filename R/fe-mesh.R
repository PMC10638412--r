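## Structured hexahedral mesh of the RVE cube, embedding of 1-D fiber
## chords as truss segments (cut exactly at host-element face crossings),
## and periodic pairing of boundary nodes.

#' Build a structured hexahedral mesh of the RVE cube
#'
#' `(La/h)^3` trilinear hex elements on an exact grid; `La/h` must be an
#' integer >= 2.
#'
#' @param La cube edge length (um)
#' @param h element edge length (um)
#' @return object of class `hex_mesh` with fields `nodes` (n_nodes x 3),
#'   `elems` (n_elems x 8 connectivity), `h`, `La`, `n` (elements per edge)
#' @export
#' @examples
#' m <- build_mesh(5, 1.25)   # 64 elements, 125 nodes
build_mesh <- function(La, h) {
  check_scalar(La, "La", positive = TRUE)
  check_scalar(h, "h", positive = TRUE)
  n <- La / h
  if (abs(n - round(n)) > 1e-9 || round(n) < 2)
    stop_invalid("La/h must be an integer >= 2 (got ", La, "/", h, ")")
  n <- as.integer(round(n))
  np <- n + 1L
  nid <- function(i, j, k) 1L + i + np * (j + np * k)
  g <- expand.grid(i = 0:n, j = 0:n, k = 0:n)
  nodes <- as.matrix(g) * h
  colnames(nodes) <- c("x", "y", "z")
  ge <- expand.grid(i = 0:(n - 1L), j = 0:(n - 1L), k = 0:(n - 1L))
  elems <- with(ge, cbind(nid(i,     j,     k),
                          nid(i + 1, j,     k),
                          nid(i + 1, j + 1, k),
                          nid(i,     j + 1, k),
                          nid(i,     j,     k + 1),
                          nid(i + 1, j,     k + 1),
                          nid(i + 1, j + 1, k + 1),
                          nid(i,     j + 1, k + 1)))
  structure(list(nodes = nodes, elems = elems, h = h, La = La, n = n),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hex mesh: La = %g um, h = %g um, %d elements, %d nodes\n",
              x$La, x$h, nrow(x$elems), nrow(x$nodes)))
  invisible(x)
}

## element index (1-based) containing a point, clamping face points inward
point_element <- function(p, mesh) {
  ijk <- pmin(pmax(floor(p / mesh$h), 0), mesh$n - 1L)
  as.integer(1 + ijk[1] + mesh$n * (ijk[2] + mesh$n * ijk[3]))
}

## trilinear local coordinates of p inside element e, in [-1,1]^3
local_coords <- function(p, e, mesh) {
  origin <- mesh$nodes[mesh$elems[e, 1L], ]
  pmin(pmax(2 * (p - origin) / mesh$h - 1, -1), 1)
}

## reference hex node signs, matching build_mesh connectivity order
hex_signs <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))

## trilinear shape weights at local coords xi (length-8 vector)
hex_weights <- function(xi) {
  (1 + hex_signs[, 1] * xi[1]) * (1 + hex_signs[, 2] * xi[2]) *
    (1 + hex_signs[, 3] * xi[3]) / 8
}

## gradient of shape functions w.r.t. X at local coords xi (8 x 3)
hex_grads <- function(xi, h) {
  cbind(hex_signs[, 1] * (1 + hex_signs[, 2] * xi[2]) * (1 + hex_signs[, 3] * xi[3]),
        hex_signs[, 2] * (1 + hex_signs[, 1] * xi[1]) * (1 + hex_signs[, 3] * xi[3]),
        hex_signs[, 3] * (1 + hex_signs[, 1] * xi[1]) * (1 + hex_signs[, 2] * xi[2])) / 8 * (2 / h)
}

#' Embed fiber chords as truss segments in a hex mesh
#'
#' Each straight fiber is split at every crossing of a host-element face,
#' so embedded nodes lie exactly on element faces; each truss node stores
#' its host element and trilinear local coordinates. The per-fiber total
#' reference length is preserved exactly (cuts partition the chord).
#'
#' @param net a [fiber_network()] object
#' @param mesh a [build_mesh()] mesh of the same cube
#' @return object of class `embedded_truss_set` with `nodes` (data.frame:
#'   position, host element, local coordinates) and `segments` (data.frame:
#'   node pair, reference length, cross-section area, straightness, fiber id)
#' @export
embed_fibers <- function(net, mesh) {
  stopifnot(inherits(net, "fiber_network"), inherits(mesh, "hex_mesh"))
  if (abs(net$La - mesh$La) > 1e-9)
    stop_invalid("network and mesh edge lengths differ")
  fib <- net$fibers
  tol <- 1e-9 * mesh$La
  node_rows <- list(); seg_rows <- list()
  nn <- 0L
  for (f in seq_len(nrow(fib))) {
    p1 <- as.numeric(fib[f, c("anchor_x", "anchor_y", "anchor_z")])
    N <- as.numeric(fib[f, c("Nx", "Ny", "Nz")])
    L0 <- fib$L0[f]
    if (any(p1 < -tol) || any(p1 > mesh$La + tol) ||
        any(p1 + L0 * N < -tol) || any(p1 + L0 * N > mesh$La + tol))
      stop_invalid("fiber ", f, " lies outside the cube")
    ## parameter values of grid-plane crossings
    ts <- c(0, L0)
    for (ax in 1:3) {
      if (abs(N[ax]) > 1e-12) {
        tcross <- ((0:mesh$n) * mesh$h - p1[ax]) / N[ax]
        ts <- c(ts, tcross[tcross > tol & tcross < L0 - tol])
      }
    }
    ts <- sort(unique(round(ts / tol) * tol))
    ts <- ts[c(TRUE, diff(ts) > tol)]
    ts[1] <- 0; ts[length(ts)] <- L0
    npts <- length(ts)
    pts <- t(vapply(ts, function(t) p1 + t * N, numeric(3)))
    ## host of each sub-segment from its midpoint
    hosts <- vapply(seq_len(npts - 1L),
                    function(s) point_element(p1 + (ts[s] + ts[s + 1]) / 2 * N, mesh),
                    integer(1))
    ## node s uses the following segment's host (last node: preceding)
    node_host <- c(hosts, hosts[npts - 1L])
    ids <- nn + seq_len(npts)
    for (s in seq_len(npts)) {
      xi <- local_coords(pts[s, ], node_host[s], mesh)
      node_rows[[ids[s]]] <- c(pts[s, ], node_host[s], xi)
    }
    seg_rows[[f]] <- cbind(n1 = ids[-npts], n2 = ids[-1L],
                           L0 = diff(ts), A0 = pi * fib$d[f]^2 / 4,
                           Ps = fib$Ps[f], fiber = f)
    nn <- nn + npts
  }
  nodes <- as.data.frame(do.call(rbind, node_rows))
  names(nodes) <- c("x", "y", "z", "host", "xi1", "xi2", "xi3")
  nodes$host <- as.integer(nodes$host)
  segments <- as.data.frame(do.call(rbind, seg_rows))
  structure(list(nodes = nodes, segments = segments),
            class = "embedded_truss_set")
}

#' @export
print.embedded_truss_set <- function(x, ...) {
  cat(sprintf("Embedded truss set: %d nodes, %d segments, %d fibers\n",
              nrow(x$nodes), nrow(x$segments), length(unique(x$segments$fiber))))
  invisible(x)
}

#' Periodic boundary constraints for a structured mesh
#'
#' Every boundary node with a grid index equal to `n` is paired with the
#' node at the same indices modulo `n` (this handles faces, edges and the
#' seven dependent corners in one rule):
#' `u(X+) - u(X-) = (F - I)(X+ - X-)`. The fluctuation of the origin
#' corner node is pinned to zero to fix rigid translation.
#'
#' @param mesh a [build_mesh()] mesh
#' @param F 3x3 macroscopic deformation gradient (stored with the
#'   constraint set; the node pairing itself is F-independent)
#' @return object of class `periodic_constraints` with `master_of`
#'   (0 for master nodes), `delta` (X - X_master rows), `pinned` (node id),
#'   `n_constraints`, and the prescribed `F`
#' @export
periodic_constraints <- function(mesh, F = diag(3)) {
  stopifnot(inherits(mesh, "hex_mesh"))
  if (!is_square3(F)) stop_invalid("'F' must be a 3x3 matrix")
  n <- mesh$n; np <- n + 1L
  idx <- round(mesh$nodes / mesh$h)
  dep <- idx[, 1] == n | idx[, 2] == n | idx[, 3] == n
  mi <- idx %% n
  master <- as.integer(1 + mi[, 1] + np * (mi[, 2] + np * mi[, 3]))
  master_of <- integer(nrow(mesh$nodes))
  master_of[dep] <- master[dep]
  delta <- mesh$nodes - mesh$nodes[master, , drop = FALSE]
  delta[!dep, ] <- 0
  structure(list(master_of = master_of, delta = delta,
                 pinned = 1L,   # node at the origin (X = 0)
                 n_constraints = 3L * sum(dep), F = F),
            class = "periodic_constraints")
}

#' @export
print.periodic_constraints <- function(x, ...) {
  cat(sprintf("Periodic constraints: %d scalar relations, pinned node %d\n",
              x$n_constraints, x$pinned))
  invisible(x)
}
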