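# The SE(3)-equivariant, chirality-aware denoising network. Two feature
# channels per node: invariant scalars H (N x h) and equivariant 3-vector
# channels V (N x 3m, m channels). Messages on the fully-connected graph
# combine sender/receiver scalars, edge scalars, vector norms, and local
# frame projections (when enabled), pass through an MLP, are gated by a
# per-edge logistic scalar message attention, and update both channels
# residually. The coordinate-noise head reads the final vector channel and
# re-projects to the zero-CoG subspace, so predictions transform with
# rotations and ignore translations by construction.

#' Denoiser configuration
#'
#' Paper-scale defaults: 9 message-passing layers with 256 scalar / 64
#' vector node features and 32 scalar / 16 vector edge features. Toy
#' profiles (e.g. 2 layers, 32/8/8/4) are what the test suite and the
#' desk-scale experiments use.
#'
#' @param n_layers number of message-passing layers.
#' @param node_scalar_dim,node_vector_dim,edge_scalar_dim,edge_vector_dim
#'   channel widths.
#' @param use_frames include chirality-aware local-frame projections in the
#'   scalar messages (reflection sensitivity on iff `TRUE`).
#' @param use_sma apply the per-edge logistic scalar-message-attention gate;
#'   with `FALSE` the gate is identically 1.
#' @param condition_dim 0 for unconditional models, 1 to append a
#'   normalized scalar property to the node scalars.
#' @param update_edges residually update the scalar edge features each layer
#'   instead of keeping the initial embedding fixed.
#' @return object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_layers = 9L,
                            node_scalar_dim = 256L,
                            node_vector_dim = 64L,
                            edge_scalar_dim = 32L,
                            edge_vector_dim = 16L,
                            use_frames = TRUE,
                            use_sma = TRUE,
                            condition_dim = 0L,
                            update_edges = FALSE) {
  cfg <- list(n_layers = as.integer(n_layers),
              node_scalar_dim = as.integer(node_scalar_dim),
              node_vector_dim = as.integer(node_vector_dim),
              edge_scalar_dim = as.integer(edge_scalar_dim),
              edge_vector_dim = as.integer(edge_vector_dim),
              use_frames = isTRUE(use_frames),
              use_sma = isTRUE(use_sma),
              condition_dim = as.integer(condition_dim),
              update_edges = isTRUE(update_edges))
  if (cfg$n_layers < 1L) stop("need at least one layer.", call. = FALSE)
  structure(cfg, class = "denoiser_config")
}

#' Per-edge scalar message attention gate
#'
#' A lightweight form of fully-connected graph self-attention: a logistic
#' gate in (0, 1) computed from each edge's message scalars and multiplied
#' into the message before aggregation.
#'
#' @param logits numeric vector/matrix of gate logits (one per edge).
#' @return values in (0, 1); 0.5 at zero logits.
#' @export
scalar_message_attention <- function(logits) 1 / (1 + exp(-logits))

n_time_features <- 5L  # t/T plus two sin/cos harmonics

time_features <- function(t_norm, n) {
  tf <- c(t_norm, sin(pi * t_norm), cos(pi * t_norm),
          sin(2 * pi * t_norm), cos(2 * pi * t_norm))
  matrix(tf, nrow = n, ncol = n_time_features, byrow = TRUE)
}

rbf_centers <- seq(0, 4, length.out = 8L)
rbf_width <- 0.5

dist_features <- function(d) {
  cbind(d, d^2, exp(-outer(d, rbf_centers, "-")^2 / (2 * rbf_width^2)))
}
n_dist_features <- 2L + 8L

msg_input_dim <- function(cfg) {
  2L * cfg$node_scalar_dim + cfg$edge_scalar_dim +
    2L * cfg$node_vector_dim + cfg$edge_vector_dim +
    (if (cfg$use_frames) 6L else 2L) * cfg$node_vector_dim
}

msg_output_dim <- function(cfg) {
  cfg$node_scalar_dim + 1L + 2L * cfg$node_vector_dim +
    (if (cfg$use_frames) cfg$node_vector_dim else 0L) +
    (if (cfg$update_edges) cfg$edge_scalar_dim else 0L)
}

xavier <- function(fan_in, fan_out, gain = 1) {
  matrix(stats::rnorm(fan_in * fan_out, sd = gain * sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

#' Initialize denoiser parameters
#'
#' @param config a [denoiser_config()].
#' @param d_in feature-channel dimension of the latent (alphabet size + 1).
#' @param seed RNG seed for the initialization draw.
#' @return nested list of weight matrices.
#' @export
init_denoiser <- function(config, d_in, seed = 1L) {
  set.seed(seed)
  h <- config$node_scalar_dim; m <- config$node_vector_dim
  e <- config$edge_scalar_dim; xv <- config$edge_vector_dim
  in_h <- d_in + n_time_features + config$condition_dim
  p <- list(
    embed_h = list(W = xavier(in_h, h), b = matrix(0, 1, h)),
    embed_v = list(W = xavier(1L, m, gain = 0.5)),
    embed_e = list(W = xavier(n_dist_features, e), b = matrix(0, 1, e)),
    embed_xi = list(W = xavier(1L, xv, gain = 0.5)),
    layers = lapply(seq_len(config$n_layers), function(l) {
      mi <- msg_input_dim(config); mo <- msg_output_dim(config)
      lay <- list(
        msg = list(W1 = xavier(mi, h), b1 = matrix(0, 1, h),
                   W2 = xavier(h, mo, gain = 0.5), b2 = matrix(0, 1, mo)),
        node = list(W1 = xavier(2L * h, h), b1 = matrix(0, 1, h),
                    W2 = xavier(h, h, gain = 0.5), b2 = matrix(0, 1, h)),
        vec = list(W = xavier(m, m, gain = 0.5))
      )
      lay
    }),
    head_h = list(W = xavier(h, d_in, gain = 0.5), b = matrix(0, 1, d_in)),
    head_x = list(W = xavier(m, 1L, gain = 0.5))
  )
  p
}

linear2 <- function(x, lay) {
  ad_bias(ad_matmul(ad_silu(ad_bias(ad_matmul(x, lay$W1), lay$b1)), lay$W2), lay$b2)
}

slice_cols <- function(x, from, width) {
  if (ad_is_node(x)) {
    # implemented through ad_cbind-compatible gather on columns
    v <- ad_value(x)[, from:(from + width - 1L), drop = FALSE]
    nc <- ncol(ad_value(x))
    ad_op(list(x), v, list(function(g) {
      out <- matrix(0, nrow(g), nc)
      out[, from:(from + width - 1L)] <- g
      out
    }))
  } else {
    x[, from:(from + width - 1L), drop = FALSE]
  }
}

#' Run the denoising network
#'
#' Predicts the joint noise \eqn{\hat\epsilon = [\hat\epsilon^{(x)},
#' \hat\epsilon^{(h)}]} for a noisy latent state. The timestep (as t/T plus
#' low-order Fourier features) and, for conditional models, the normalized
#' property value are appended to the input node scalars. Works on plain
#' matrices for inference and on autodiff-traced parameters for training.
#'
#' @param z a [latent_state()] with zero-CoG coordinate channel.
#' @param t timestep in `[1, T]`.
#' @param schedule the [build_noise_schedule()] the model was trained with.
#' @param config a [denoiser_config()].
#' @param params parameters from [init_denoiser()] (possibly tape-wrapped).
#' @param cond normalized scalar condition (required iff
#'   `config$condition_dim == 1`).
#' @return list with `zx` (N x 3 zero-CoG coordinate-noise prediction) and
#'   `zh` (N x d feature-noise prediction); traced nodes under a tape.
#' @export
denoise <- function(z, t, schedule, config, params, cond = NULL) {
  stopifnot(inherits(z, "latent_state"), inherits(config, "denoiser_config"))
  if (config$condition_dim > 0L && is.null(cond)) {
    stop("conditional model requires `cond`.", call. = FALSE)
  }
  n <- z$N
  edges <- full_edges(n)
  E <- nrow(edges)
  t_norm <- t / schedule$T

  h_in <- cbind(z$zh, time_features(t_norm, n))
  if (config$condition_dim > 0L) h_in <- cbind(h_in, matrix(cond, n, 1L))

  H <- ad_bias(ad_matmul(h_in, params$embed_h$W), params$embed_h$b)
  V <- ad_blockmix(z$zx, params$embed_v$W)   # lift node->CoG displacements

  if (E > 0L) {
    fr <- edge_frames(z$zx, edges)
    lift <- lift_noisy_vectors(z$zx, edges)
    Eattr <- ad_bias(ad_matmul(dist_features(fr$dist), params$embed_e$W),
                     params$embed_e$b)
    Xi <- ad_blockmix(lift$edge, params$embed_xi$W)
    xi_norms <- ad_norm_blocks(Xi)
  }

  m <- config$node_vector_dim
  h_dim <- config$node_scalar_dim

  for (l in seq_len(config$n_layers)) {
    lay <- params$layers[[l]]
    if (E == 0L) {
      Hagg <- matrix(0, n, h_dim)
      Hn <- ad_add(H, linear2(ad_cbind(list(H, Hagg)), lay$node))
      H <- Hn
      next
    }
    Hi <- ad_rows(H, edges[, 1])
    Hj <- ad_rows(H, edges[, 2])
    Vi <- ad_rows(V, edges[, 1])
    Vj <- ad_rows(V, edges[, 2])
    feats <- list(Hi, Hj, Eattr, ad_norm_blocks(Vi), ad_norm_blocks(Vj), xi_norms,
                  ad_proj_blocks(Vi, fr$a), ad_proj_blocks(Vj, fr$a))
    if (config$use_frames) {
      feats <- c(feats, list(ad_proj_blocks(Vi, fr$b), ad_proj_blocks(Vj, fr$b),
                             ad_proj_blocks(Vi, fr$c), ad_proj_blocks(Vj, fr$c)))
    }
    raw <- linear2(ad_cbind(feats), lay$msg)

    ofs <- 1L
    msg_s <- slice_cols(raw, ofs, h_dim); ofs <- ofs + h_dim
    gate_logit <- slice_cols(raw, ofs, 1L); ofs <- ofs + 1L
    cA <- slice_cols(raw, ofs, m); ofs <- ofs + m
    cW <- slice_cols(raw, ofs, m); ofs <- ofs + m
    if (config$use_frames) { cB <- slice_cols(raw, ofs, m); ofs <- ofs + m }
    if (config$update_edges) {
      dE <- slice_cols(raw, ofs, config$edge_scalar_dim)
      Eattr <- ad_add(Eattr, dE)
    }

    gate <- if (config$use_sma) ad_sigmoid(gate_logit) else matrix(1, E, 1L)

    msg_v <- ad_add(ad_axpy_blocks(cA, fr$a), ad_block_scale(Vj, cW))
    if (config$use_frames) msg_v <- ad_add(msg_v, ad_axpy_blocks(cB, fr$b))

    inv_deg <- 1 / (n - 1)
    Hagg <- ad_scale(ad_scatter(ad_colmul(msg_s, gate), edges[, 1], n), inv_deg)
    Vagg <- ad_scale(ad_scatter(gated_blocks(msg_v, gate), edges[, 1], n), inv_deg)

    H <- ad_add(H, linear2(ad_cbind(list(H, Hagg)), lay$node))
    V <- ad_add(V, ad_blockmix(Vagg, lay$vec$W))
  }

  eps_h <- ad_bias(ad_matmul(H, params$head_h$W), params$head_h$b)
  eps_x <- ad_center_cols(ad_blockmix(V, params$head_x$W))
  list(zx = eps_x, zh = eps_h)
}

# multiply every 3-vector block of an E x 3m matrix by the edge's gate
gated_blocks <- function(V, gate) {
  m <- ncol(ad_value(V)) %/% 3L
  if (is.numeric(gate) && isTRUE(all(ad_value(gate) == 1))) return(V)
  ad_block_scale(V, if (ad_is_node(gate)) rep_cols(gate, m) else
    matrix(ad_value(gate), nrow(ad_value(gate)), m))
}

rep_cols <- function(x, m) {
  vx <- ad_value(x)
  ad_op(list(x), vx[, rep(1L, m), drop = FALSE],
        list(function(g) matrix(rowSums(g), ncol = 1L)))
}

#' Count trainable parameters of a denoiser
#' @param params from [init_denoiser()].
#' @return integer number of scalar parameters.
#' @export
n_parameters <- function(params) {
  tot <- 0L
  walk <- function(x) {
    if (is.matrix(x)) tot <<- tot + length(x)
    else if (is.list(x)) for (el in x) walk(el)
  }
  walk(params)
  tot
}
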