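# Ancestral sampling, time-scaled (strided) sampling, and property-guided
# optimization of existing molecules.

model_denoiser_fn <- function(model, condition = NULL) {
  cond_norm <- NULL
  if (!is.null(condition)) {
    if (is.null(model$property_stats)) {
      stop("model was not trained with property conditioning.", call. = FALSE)
    }
    if (!is.null(condition$name) &&
        !identical(condition$name, model$property_stats$name)) {
      stop(sprintf("model conditions on '%s', not '%s'.",
                   model$property_stats$name, condition$name), call. = FALSE)
    }
    cond_norm <- normalize_property(condition$value, model$property_stats)
  } else if (!is.null(model$property_stats)) {
    stop("conditional model: supply `condition = list(name, value)`.", call. = FALSE)
  }
  function(z, t) denoise(z, t, model$schedule, model$config, model$params,
                         cond = cond_norm)
}

timestep_path <- function(T_steps, k_steps) {
  if (k_steps < 1L || k_steps > T_steps) {
    stop("`k_steps` must lie in [1, T].", call. = FALSE)
  }
  path <- unique(round(seq(T_steps, 0, length.out = k_steps + 1L)))
  as.integer(path)  # strictly decreasing, starts at T, ends at 0
}

run_reverse_chain <- function(z, denoiser_fn, schedule, path,
                              clip_clean = 20) {
  for (k in seq_len(length(path) - 1L)) {
    t <- path[k]; s <- path[k + 1L]
    eps_hat <- denoiser_fn(z, t)
    z <- reverse_step(z, eps_hat, s, schedule, clip_clean = clip_clean)
  }
  z
}

#' Generate a molecule by ancestral reverse diffusion
#'
#' Draws \eqn{z_T} from the zero-CoG subspace Gaussian (coordinates) and a
#' standard Gaussian (features), runs the learned reverse chain down the
#' full timestep grid, and decodes the final state. The decode happens at
#' t = 0 with no extra noise injection.
#'
#' @param model a trained `gcdm_model` (or [load_checkpoint()] result).
#' @param n_atoms atom count; drawn from the model's size distribution when
#'   `NULL`.
#' @param condition optional `list(name =, value =)` target property for
#'   conditional models (raw units; normalized internally).
#' @param seed optional RNG seed (bitwise-reproducible on one platform).
#' @return a [molecule_record()] with zero-CoG coordinates.
#' @export
generate <- function(model, n_atoms = NULL, condition = NULL, seed = NULL) {
  generate_strided(model, n_atoms = n_atoms, k_steps = model$schedule$T,
                   condition = condition, seed = seed)
}

#' Generate with time-scaled (strided) reverse diffusion
#'
#' Runs the reverse chain only at `k_steps` evenly spaced timesteps,
#' recomputing the conditional transition moments between consecutive
#' visited steps. With `k_steps = T` this is path-identical to [generate()];
#' small `k_steps` (e.g. 10) yields deliberately under-refined molecules.
#'
#' @inheritParams generate
#' @param k_steps number of visited reverse steps in `[1, T]`.
#' @return a [molecule_record()].
#' @export
generate_strided <- function(model, n_atoms = NULL, k_steps, condition = NULL,
                             seed = NULL) {
  stopifnot(inherits(model, "gcdm_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_atoms)) n_atoms <- sample_num_atoms(model$size_dist)
  if (n_atoms < 1L) stop("`n_atoms` must be >= 1.", call. = FALSE)
  d <- length(model$alphabet) + 1L
  fn <- model_denoiser_fn(model, condition)
  z <- latent_state(sample_subspace_gaussian(n_atoms),
                    matrix(stats::rnorm(n_atoms * d), n_atoms, d),
                    t = model$schedule$T)
  z <- run_reverse_chain(z, fn, model$schedule, timestep_path(model$schedule$T, k_steps))
  decode_latent(z, model$alphabet, model$scaling)
}

#' Generate a set of molecules
#'
#' @inheritParams generate_strided
#' @param n_molecules number of molecules to draw.
#' @param n_atoms fixed atom count, or `NULL` to draw each from p(N).
#' @return list of [molecule_record()]s.
#' @export
generate_set <- function(model, n_molecules, n_atoms = NULL,
                         k_steps = model$schedule$T, condition = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_molecules), function(i) {
    generate_strided(model, n_atoms = n_atoms, k_steps = k_steps,
                     condition = condition)
  })
}

#' Property-guided optimization of existing molecules
#'
#' Each molecule is featurized, forward-noised to timestep `t_opt` via the
#' closed-form marginal, and then reverse-diffused `t_opt -> 0` under a
#' property-conditional model with the requested target value, optimizing
#' atom types and 3D coordinates jointly while preserving the atom count.
#' `t_opt = 0` returns the featurize/decode round trip unchanged.
#'
#' @param mols list of [molecule_record()]s.
#' @param cond_model a property-conditional `gcdm_model`.
#' @param t_opt number of diffusion steps of optimization in `[0, T]`.
#' @param target target property value (raw units).
#' @param seed optional RNG seed.
#' @return list of optimized [molecule_record()]s (same length, same atom
#'   counts).
#' @export
optimize_molecules <- function(mols, cond_model, t_opt, target, seed = NULL) {
  stopifnot(inherits(cond_model, "gcdm_model"))
  if (is.null(cond_model$property_stats)) {
    stop("`cond_model` must be property-conditional.", call. = FALSE)
  }
  if (t_opt < 0L || t_opt > cond_model$schedule$T) {
    stop("`t_opt` must lie in [0, T].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  condition <- list(name = cond_model$property_stats$name, value = target)
  fn <- model_denoiser_fn(cond_model, condition)
  lapply(mols, function(mol) {
    feat <- featurize(mol, cond_model$alphabet, cond_model$scaling)
    if (t_opt == 0L) {
      return(decode_latent(feat$z0, cond_model$alphabet, cond_model$scaling))
    }
    z <- forward_noise(feat$z0, t_opt, NULL, cond_model$schedule)
    z <- run_reverse_chain(z, fn, cond_model$schedule, t_opt:0)
    decode_latent(z, cond_model$alphabet, cond_model$scaling)
  })
}

#' Pairwise interatomic distances of a molecule
#' @param mol a [molecule_record()].
#' @return numeric vector of the N(N-1)/2 pairwise distances (Angstrom).
#' @export
pairwise_distances <- function(mol) {
  as.numeric(stats::dist(mol$coords))
}

#' Mean pairwise distance (the toy conditioning property)
#' @param mol a [molecule_record()].
#' @return scalar mean of all pairwise distances (Angstrom).
#' @export
mean_pairwise_distance <- function(mol) mean(pairwise_distances(mol))
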