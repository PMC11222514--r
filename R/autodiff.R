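# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Only the operations the denoising network needs are provided;
# each op works on plain matrices when no tape is active, so inference pays
# no tracing overhead. Gradients are checked against central finite
# differences in the test suite.

#' Start a fresh autodiff tape
#'
#' A tape records every traced operation so that [ad_backward()] can run
#' reverse-mode accumulation. Inference code simply never creates one.
#'
#' @return An environment holding the (initially empty) operation record.
#' @keywords internal
#' @export
ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  class(t) <- "ad_tape"
  t
}

ad_is_node <- function(x) inherits(x, "ad_node")

ad_value <- function(x) if (ad_is_node(x)) x$v else x

tape_of <- function(...) {
  for (a in list(...)) if (ad_is_node(a)) return(a$tape)
  NULL
}

ad_record <- function(tape, v, parents, backs) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$tape <- tape
  nd$parents <- parents
  nd$backs <- backs
  nd$g <- NULL
  class(nd) <- "ad_node"
  n <- tape$n + 1L
  if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' Wrap a parameter matrix as a traced leaf on a tape
#' @keywords internal
#' @export
ad_leaf <- function(tape, v) ad_record(tape, v, list(), list())

# Generic binary/unary op builders -------------------------------------------

ad_op <- function(args, v, backs) {
  tp <- NULL
  for (a in args) if (inherits(a, "ad_node")) { tp <- a$tape; break }
  if (is.null(tp)) return(v)
  ad_record(tp, v, args, backs)
}

#' @name ad-ops
#' @title Traced matrix operations
#' @description Elementwise and structural operations recorded on the tape.
#'   `ad_rows` gathers rows, `ad_scatter` sum-aggregates rows into groups
#'   (message aggregation), and the `*_blocks` ops treat an `n x 3m` matrix
#'   as `m` contiguous 3-vector channels.
#' @param a,b,x,V,C,W,axis,bias operands (plain matrices or traced nodes)
#' @param idx integer row indices
#' @param n number of output rows for scatter
#' @param eps numerical floor for norms
#' @keywords internal
NULL

#' @rdname ad-ops
#' @export
ad_add <- function(a, b) {
  ad_op(list(a, b), ad_value(a) + ad_value(b),
        list(function(g) g, function(g) g))
}

#' @rdname ad-ops
#' @export
ad_sub <- function(a, b) {
  ad_op(list(a, b), ad_value(a) - ad_value(b),
        list(function(g) g, function(g) -g))
}

#' @rdname ad-ops
#' @export
ad_mul <- function(a, b) {
  va <- ad_value(a); vb <- ad_value(b)
  ad_op(list(a, b), va * vb,
        list(function(g) g * vb, function(g) g * va))
}

#' @rdname ad-ops
#' @param s plain numeric scalar
#' @export
ad_scale <- function(a, s) {
  ad_op(list(a), ad_value(a) * s, list(function(g) g * s))
}

#' @rdname ad-ops
#' @export
ad_matmul <- function(a, W) {
  va <- ad_value(a); vW <- ad_value(W)
  ad_op(list(a, W), va %*% vW,
        list(function(g) g %*% t(vW), function(g) crossprod(va, g)))
}

#' @rdname ad-ops
#' @export
ad_bias <- function(a, bias) {
  va <- ad_value(a); vb <- ad_value(bias)
  ad_op(list(a, bias), va + rep(as.numeric(vb), each = nrow(va)),
        list(function(g) g, function(g) matrix(colSums(g), nrow = 1L)))
}

#' @rdname ad-ops
#' @param parts list of operands to bind column-wise
#' @export
ad_cbind <- function(parts) {
  vals <- lapply(parts, ad_value)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  backs <- lapply(seq_along(parts), function(k) {
    force(k)
    function(g) g[, starts[k]:ends[k], drop = FALSE]
  })
  ad_op(parts, do.call(cbind, vals), backs)
}

#' @rdname ad-ops
#' @export
ad_rows <- function(a, idx) {
  va <- ad_value(a)
  nr <- nrow(va)
  ad_op(list(a), va[idx, , drop = FALSE],
        list(function(g) {
          out <- matrix(0, nr, ncol(g))
          acc <- rowsum(g, group = idx)
          out[as.integer(rownames(acc)), ] <- acc
          out
        }))
}

#' @rdname ad-ops
#' @export
ad_scatter <- function(a, idx, n) {
  va <- ad_value(a)
  v <- matrix(0, n, ncol(va))
  if (nrow(va) > 0L) {
    acc <- rowsum(va, group = idx)
    v[as.integer(rownames(acc)), ] <- acc
  }
  ad_op(list(a), v, list(function(g) g[idx, , drop = FALSE]))
}

#' @rdname ad-ops
#' @export
ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ad_value(x)))
  ad_op(list(x), v, list(function(g) g * v * (1 - v)))
}

#' @rdname ad-ops
#' @export
ad_silu <- function(x) {
  vx <- ad_value(x)
  s <- 1 / (1 + exp(-vx))
  ad_op(list(x), vx * s, list(function(g) g * (s + vx * s * (1 - s))))
}

#' @rdname ad-ops
#' @export
ad_sum <- function(x) {
  vx <- ad_value(x)
  nr <- nrow(vx); nc <- ncol(vx)
  ad_op(list(x), matrix(sum(vx), 1L, 1L),
        list(function(g) matrix(as.numeric(g), nr, nc)))
}

# Multiply each row of an n x d matrix by the row's scalar (n x 1).
#' @rdname ad-ops
#' @export
ad_colmul <- function(a, s) {
  va <- ad_value(a); vs <- as.numeric(ad_value(s))
  ad_op(list(a, s), va * vs,
        list(function(g) g * vs,
             function(g) matrix(rowSums(g * va), ncol = 1L)))
}

# --- 3-vector block channel ops ---------------------------------------------
# V is n x 3m: channel k occupies columns (k-1)*3 + 1:3. The three
# coordinate slices (x, y, z across all channels) are the strided column
# sets seq(c, 3m, by = 3), which keeps every op loop-free in m.

block_cols <- function(k) (k - 1L) * 3L + 1:3

coord_slice <- function(m, c) seq.int(c, 3L * m, by = 3L)

#' @rdname ad-ops
#' @export
ad_block_scale <- function(V, C) {
  vV <- ad_value(V); vC <- ad_value(C)
  m <- ncol(vC)
  idx <- rep(seq_len(m), each = 3L)
  ad_op(list(V, C), vV * vC[, idx, drop = FALSE],
        list(function(g) g * vC[, idx, drop = FALSE],
             function(g) {
               gv <- g * vV
               gv[, coord_slice(m, 1L), drop = FALSE] +
                 gv[, coord_slice(m, 2L), drop = FALSE] +
                 gv[, coord_slice(m, 3L), drop = FALSE]
             }))
}

#' @rdname ad-ops
#' @export
ad_proj_blocks <- function(V, axis) {
  stopifnot(!ad_is_node(axis))  # geometry is constant w.r.t. parameters
  vV <- ad_value(V)
  m <- ncol(vV) %/% 3L
  s1 <- coord_slice(m, 1L); s2 <- coord_slice(m, 2L); s3 <- coord_slice(m, 3L)
  v <- vV[, s1, drop = FALSE] * axis[, 1] + vV[, s2, drop = FALSE] * axis[, 2] +
    vV[, s3, drop = FALSE] * axis[, 3]
  ad_op(list(V), v,
        list(function(g) {
          out <- matrix(0, nrow(vV), ncol(vV))
          out[, s1] <- g * axis[, 1]
          out[, s2] <- g * axis[, 2]
          out[, s3] <- g * axis[, 3]
          out
        }))
}

#' @rdname ad-ops
#' @export
ad_axpy_blocks <- function(C, axis) {
  stopifnot(!ad_is_node(axis))
  vC <- ad_value(C)
  m <- ncol(vC)
  s1 <- coord_slice(m, 1L); s2 <- coord_slice(m, 2L); s3 <- coord_slice(m, 3L)
  v <- matrix(0, nrow(vC), 3L * m)
  v[, s1] <- vC * axis[, 1]
  v[, s2] <- vC * axis[, 2]
  v[, s3] <- vC * axis[, 3]
  ad_op(list(C), v,
        list(function(g) {
          g[, s1, drop = FALSE] * axis[, 1] + g[, s2, drop = FALSE] * axis[, 2] +
            g[, s3, drop = FALSE] * axis[, 3]
        }))
}

#' @rdname ad-ops
#' @export
ad_norm_blocks <- function(V, eps = 1e-8) {
  vV <- ad_value(V)
  m <- ncol(vV) %/% 3L
  s1 <- coord_slice(m, 1L); s2 <- coord_slice(m, 2L); s3 <- coord_slice(m, 3L)
  v <- sqrt(vV[, s1, drop = FALSE]^2 + vV[, s2, drop = FALSE]^2 +
              vV[, s3, drop = FALSE]^2 + eps)
  ad_op(list(V), v,
        list(function(g) {
          r <- g / v
          out <- matrix(0, nrow(vV), ncol(vV))
          out[, s1] <- r * vV[, s1, drop = FALSE]
          out[, s2] <- r * vV[, s2, drop = FALSE]
          out[, s3] <- r * vV[, s3, drop = FALSE]
          out
        }))
}

# Mix vector channels: out channel k = sum_l W[l, k] * V_l. Linear in the
# vectors, hence rotation-equivariant. Column-major reshaping of the block
# layout n x 3m into (3n) x m makes the mix a single matrix product.
#' @rdname ad-ops
#' @export
ad_blockmix <- function(V, W) {
  vV <- ad_value(V); vW <- ad_value(W)
  n <- nrow(vV); m <- nrow(vW); q <- ncol(vW)
  ad_op(list(V, W), matrix(matrix(vV, n * 3L, m) %*% vW, n, 3L * q),
        list(function(g) matrix(matrix(g, n * 3L, q) %*% t(vW), n, 3L * m),
             function(g) crossprod(matrix(vV, n * 3L, m), matrix(g, n * 3L, q))))
}

# Remove the column mean from an n x 3 matrix (orthogonal projection onto
# the zero centre-of-gravity subspace); self-adjoint, so backward = forward.
#' @rdname ad-ops
#' @export
ad_center_cols <- function(x) {
  vx <- ad_value(x)
  ctr <- function(z) sweep(z, 2L, colMeans(z), "-")
  ad_op(list(x), ctr(vx), list(function(g) ctr(g)))
}

#' Run reverse-mode accumulation from a scalar output node
#'
#' @param out the traced node holding a 1x1 scalar value
#' @return invisibly, the tape (leaf gradients readable via `$g`)
#' @keywords internal
#' @export
ad_backward <- function(out) {
  stopifnot(ad_is_node(out), length(ad_value(out)) == 1L)
  tape <- out$tape
  for (i in seq_len(tape$n)) tape$nodes[[i]]$g <- NULL
  out$g <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$g)) next
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!ad_is_node(p)) next
      pg <- nd$backs[[k]](nd$g)
      p$g <- if (is.null(p$g)) pg else p$g + pg
    }
  }
  invisible(tape)
}
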