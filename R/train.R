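# Training: stochastic denoising score matching with uniformly sampled
# timesteps and w(t) = 1, optimized with Adam over the autodiff tape.

wrap_params <- function(tape, p) {
  if (is.matrix(p)) return(ad_leaf(tape, p))
  lapply(p, wrap_params, tape = tape)
}

grad_of <- function(wp) {
  if (ad_is_node(wp)) {
    g <- wp$g
    if (is.null(g)) g <- matrix(0, nrow(wp$v), ncol(wp$v))
    return(g)
  }
  lapply(wp, grad_of)
}

map2_params <- function(a, b, f) {
  if (is.matrix(a)) return(f(a, b))
  Map(function(x, y) map2_params(x, y, f), a, b)
}

zeros_like <- function(p) {
  if (is.matrix(p)) return(p * 0)
  lapply(p, zeros_like)
}

adam_state <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- map2_params(st$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- map2_params(st$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- map2_params(st$m, st$v, function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = st)
}

normalize_property <- function(value, stats) (value - stats$center) / stats$scale

#' Train a diffusion denoiser
#'
#' Minimizes the denoising objective \eqn{\mathbb{E}\,\tfrac12 \lVert
#' \epsilon - \hat\epsilon \rVert^2} with one uniformly drawn timestep per
#' example and Adam updates. Deterministic for a fixed seed.
#'
#' @param dataset a `dataset_bundle` (see [make_toy_dataset()]) or plain
#'   list of [molecule_record()]s.
#' @param config a [denoiser_config()]; set `condition_dim = 1` together
#'   with `condition` for property-conditional training.
#' @param schedule a [build_noise_schedule()].
#' @param n_steps number of gradient steps.
#' @param lr Adam learning rate.
#' @param seed RNG seed covering initialization and the noise draws.
#' @param condition name of the property to condition on (`NULL` for
#'   unconditional training); values are normalized by the training-set
#'   center/scale stored with the model.
#' @param alphabet element alphabet; derived from the dataset if omitted.
#' @param scaling latent scalings, see [default_scaling()].
#' @param log_every record the running loss every this many steps.
#' @param batch_size molecules per gradient step (gradients accumulated).
#' @param lr_decay `"cosine"` (to 5% of `lr`) or `"none"`.
#' @param ema_decay exponential-moving-average decay for the inference
#'   parameters (0 disables averaging); the raw final parameters are kept
#'   in `params_raw`.
#' @return object of class `gcdm_model`: parameters, config, schedule,
#'   alphabet, scalings, size distribution, property normalizer, and a
#'   training-log tibble.
#' @export
train_denoiser <- function(dataset, config, schedule,
                           n_steps = 2000L, lr = 1e-3, seed = 1L,
                           condition = NULL, alphabet = NULL,
                           scaling = default_scaling(), log_every = 25L,
                           batch_size = 1L, lr_decay = c("cosine", "none"),
                           ema_decay = 0.999) {
  lr_decay <- match.arg(lr_decay)
  mols <- dataset_molecules(dataset)
  if (length(mols) == 0L) stop("empty training set.", call. = FALSE)
  if (is.null(alphabet)) alphabet <- sort(unique(unlist(lapply(mols, `[[`, "elements"))))
  d_in <- length(alphabet) + 1L

  prop_stats <- NULL
  if (!is.null(condition)) {
    if (config$condition_dim != 1L) {
      stop("conditional training needs `condition_dim = 1` in the config.", call. = FALSE)
    }
    vals <- vapply(mols, function(m) {
      if (is.null(m$property) || is.null(m$property[[condition]])) {
        stop(sprintf("molecule lacks property '%s'.", condition), call. = FALSE)
      }
      m$property[[condition]]
    }, numeric(1))
    prop_stats <- list(name = condition, center = mean(vals),
                       scale = max(stats::mad(vals), 1e-8))
  }

  set.seed(seed)
  params <- init_denoiser(config, d_in, seed = seed)
  st <- adam_state(params)
  feats <- lapply(mols, featurize, alphabet = alphabet, scaling = scaling)
  conds <- if (is.null(condition)) NULL else
    vapply(mols, function(m) normalize_property(m$property[[condition]], prop_stats),
           numeric(1))

  steps <- integer(0); losses <- numeric(0)
  ema <- NULL  # exponential moving average of parameters; used at inference
  run <- 0; run_n <- 0L
  for (step in seq_len(n_steps)) {
    grads <- NULL
    lv <- 0
    for (bi in seq_len(batch_size)) {
      i <- sample.int(length(mols), 1L)
      z0 <- feats[[i]]$z0
      t <- sample.int(schedule$T, 1L)
      eps <- sample_joint_noise(z0$N, d_in)
      z_t <- forward_noise(z0, t, eps, schedule)

      tape <- ad_tape()
      wp <- wrap_params(tape, params)
      pred <- denoise(z_t, t, schedule, config, wp,
                      cond = if (is.null(conds)) NULL else conds[i])
      dx <- ad_sub(pred$zx, eps$zx)
      dh <- ad_sub(pred$zh, eps$zh)
      loss <- ad_scale(ad_add(ad_sum(ad_mul(dx, dx)), ad_sum(ad_mul(dh, dh))),
                       0.5 / batch_size)
      li <- as.numeric(ad_value(loss))
      if (!is.finite(li)) {
        stop(sprintf("non-finite loss at step %d (t = %d): aborting.", step, t),
             call. = FALSE)
      }
      lv <- lv + li
      ad_backward(loss)
      g <- grad_of(wp)
      grads <- if (is.null(grads)) g else map2_params(grads, g, `+`)
    }
    lr_t <- if (lr_decay == "cosine") {
      lr * (0.05 + 0.95 * 0.5 * (1 + cos(pi * step / n_steps)))
    } else {
      lr
    }
    upd <- adam_step(params, grads, st, lr = lr_t)
    params <- upd$params; st <- upd$state
    ema <- if (is.null(ema)) params else
      map2_params(ema, params, function(e, p) ema_decay * e + (1 - ema_decay) * p)

    run <- run + lv; run_n <- run_n + 1L
    if (step %% log_every == 0L || step == n_steps) {
      steps <- c(steps, step); losses <- c(losses, run / run_n)
      run <- 0; run_n <- 0L
    }
  }

  structure(
    list(version = 1L,
         params = if (ema_decay > 0) ema else params,
         params_raw = params,
         config = config,
         schedule = schedule,
         alphabet = alphabet,
         scaling = scaling,
         size_dist = size_distribution(vapply(mols, function(m) length(m$elements), integer(1))),
         property_stats = prop_stats,
         log = tibble::tibble(step = steps, loss = losses)),
    class = "gcdm_model"
  )
}

dataset_molecules <- function(dataset) {
  if (inherits(dataset, "dataset_bundle")) {
    dataset$molecules[dataset$splits$train]
  } else if (inherits(dataset, "molecule_record")) {
    list(dataset)
  } else {
    dataset
  }
}

#' @export
print.gcdm_model <- function(x, ...) {
  cat(sprintf("<gcdm_model> %d layers, %d params, alphabet {%s}%s\n",
              x$config$n_layers, n_parameters(x$params),
              paste(x$alphabet, collapse = ","),
              if (is.null(x$property_stats)) "" else
                sprintf(", conditional on %s", x$property_stats$name)))
  if (nrow(x$log)) cat(sprintf("  final training loss: %.4f\n", utils::tail(x$log$loss, 1)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Versioned container holding parameters, configuration, schedule,
#' alphabet, scalings, size distribution, and property normalizers.
#'
#' @param model a `gcdm_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gcdm_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version) || obj$version != 1L) {
    stop("unsupported checkpoint schema version.", call. = FALSE)
  }
  class(obj$config) <- "denoiser_config"
  class(obj$schedule) <- "noise_schedule"
  class(obj$size_dist) <- "size_distribution"
  structure(obj, class = "gcdm_model")
}
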