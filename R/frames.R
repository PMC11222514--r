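# Chirality-aware local frames. For an ordered atom pair (i, j) on centred
# coordinates the frame is
#   a = (x_i - x_j)/||x_i - x_j||      (true vector)
#   b = (x_i x x_j)/||x_i x x_j||      (pseudo-vector: flips under reflection)
#   c = a x b
# Projections onto (a, b, c) are rotation-invariant scalars; those onto b
# change sign under point reflection, which is what makes message passing
# chirality-sensitive.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Build the local geometric frame of an ordered atom pair
#'
#' @param x_i,x_j length-3 coordinates of the two atoms, assumed centred
#'   (zero-CoG) so the cross product is translation-independent.
#' @param tol degeneracy tolerance on the displacement and cross-product
#'   norms.
#' @return list with unit vectors `a`, `b`, `c` and logical `defined_flag`.
#'   Degenerate inputs (coincident atoms, or atoms colinear with the origin)
#'   give a zeroed frame with `defined_flag = FALSE` so downstream
#'   projections contribute nothing.
#' @examples
#' f <- build_local_frames(c(1, 0, 0), c(0, 1, 0))
#' crossprod(f$a, f$b)  # orthogonal
#' @export
build_local_frames <- function(x_i, x_j, tol = 1e-8) {
  x_i <- as.numeric(x_i); x_j <- as.numeric(x_j)
  d <- x_i - x_j
  nd <- sqrt(sum(d^2))
  cr <- cross3(x_i, x_j)
  ncr <- sqrt(sum(cr^2))
  if (nd < tol || ncr < tol) {
    z <- c(0, 0, 0)
    return(list(a = z, b = z, c = z, defined_flag = FALSE))
  }
  a <- d / nd
  b <- cr / ncr
  list(a = a, b = b, c = cross3(a, b), defined_flag = TRUE)
}

# Vectorized frames for an edge list on centred coordinates X (N x 3).
# Returns E x 3 matrices a, b, c (zero rows where degenerate) plus the
# distances and the defined flags.
edge_frames <- function(X, edges, tol = 1e-8) {
  xi <- X[edges[, 1], , drop = FALSE]
  xj <- X[edges[, 2], , drop = FALSE]
  d <- xi - xj
  nd <- sqrt(rowSums(d^2))
  cr <- cbind(xi[, 2] * xj[, 3] - xi[, 3] * xj[, 2],
              xi[, 3] * xj[, 1] - xi[, 1] * xj[, 3],
              xi[, 1] * xj[, 2] - xi[, 2] * xj[, 1])
  ncr <- sqrt(rowSums(cr^2))
  ok <- nd >= tol & ncr >= tol
  a <- d / pmax(nd, tol)
  b <- cr / pmax(ncr, tol)
  a[!ok, ] <- 0
  b[!ok, ] <- 0
  cc <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  list(a = a, b = b, c = cc, dist = nd, defined = ok)
}

#' Lift noisy coordinates into vector features
#'
#' The displacement sets derived directly from the noisy coordinate channel:
#' per-node vectors to the centre of gravity (identical to the centred
#' coordinates themselves) and per-edge displacements \eqn{x_i - x_j}. Both
#' transform equivariantly under rotation and are what seeds the denoiser's
#' vector channel.
#'
#' @param zx N x 3 zero-CoG coordinates.
#' @param edges E x 2 integer matrix of directed pairs (i, j).
#' @return list with `node` (N x 3) and `edge` (E x 3) vector features.
#' @export
lift_noisy_vectors <- function(zx, edges) {
  zx <- as.matrix(zx)
  if (is.null(edges) || nrow(edges) == 0L) {
    return(list(node = zx, edge = matrix(0, 0L, 3L)))
  }
  list(node = zx,
       edge = zx[edges[, 1], , drop = FALSE] - zx[edges[, 2], , drop = FALSE])
}

#' Fully-connected directed edge list
#'
#' @param n_atoms number of atoms.
#' @return E x 2 integer matrix of all ordered pairs (i, j), i != j.
#' @export
full_edges <- function(n_atoms) {
  if (n_atoms < 2L) return(matrix(integer(0), 0L, 2L))
  g <- expand.grid(i = seq_len(n_atoms), j = seq_len(n_atoms))
  as.matrix(g[g$i != g$j, c("i", "j")])
}
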