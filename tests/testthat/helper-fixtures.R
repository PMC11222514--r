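# Shared fixtures: tiny schedules/configs, geometry builders, and memoized
# trained toy models so the expensive fits run once per suite.

toy_schedule <- function(T_steps = 100L) build_noise_schedule(T_steps)

toy_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 2L, node_scalar_dim = 32L, node_vector_dim = 8L,
         edge_scalar_dim = 8L, edge_vector_dim = 4L),
    list(...))
  do.call(denoiser_config, args)
}

# capacity profile used by the desk-scale generative experiments
recovery_config <- function(...) {
  args <- utils::modifyList(
    list(n_layers = 3L, node_scalar_dim = 48L, node_vector_dim = 12L,
         edge_scalar_dim = 8L, edge_vector_dim = 4L),
    list(...))
  do.call(denoiser_config, args)
}

random_latent <- function(n, d = 3L, t = 1L) {
  latent_state(project_zero_cog(matrix(stats::rnorm(n * 3), n, 3)),
               matrix(stats::rnorm(n * d), n, d), t = t)
}

rotation_matrix <- function(axis = c(0, 0, 1), theta = 0.6) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

ideal_methane <- function() toy_templates()$methane

ideal_water <- function() toy_templates()$water

# the study conditions of the desk-scale experiments: a rigid 3-atom
# template with small jitter, T = 200 steps, a 2-layer denoiser
recovery_training_dataset <- function() {
  make_toy_dataset(toy_spec(templates = toy_templates()["water"], n = 256L,
                            jitter_sd = 0.02, seed = 11L))
}

.model_cache <- new.env(parent = emptyenv())

trained_toy_model <- function() {
  if (is.null(.model_cache$uncond)) {
    .model_cache$uncond <- train_denoiser(
      recovery_training_dataset(), recovery_config(), toy_schedule(),
      n_steps = 6000L, lr = 3e-3, seed = 5L, batch_size = 2L)
  }
  .model_cache$uncond
}

# scalable-chain conditional study: water template scaled in [0.8, 1.3],
# property = mean pairwise distance
conditional_training_dataset <- function() {
  make_toy_dataset(toy_spec(templates = toy_templates()["water"], n = 256L,
                            jitter_sd = 0.02,
                            property_rule = "mean_pairwise_distance",
                            property_name = "mpd",
                            scale_range = c(0.8, 1.3), seed = 13L))
}

trained_conditional_model <- function() {
  if (is.null(.model_cache$cond)) {
    .model_cache$cond <- train_denoiser(
      conditional_training_dataset(),
      recovery_config(condition_dim = 1L), toy_schedule(),
      n_steps = 6000L, lr = 3e-3, seed = 7L, batch_size = 2L,
      condition = "mpd")
  }
  .model_cache$cond
}

# the analytically optimal denoiser for a point-mass data distribution:
# eps_hat = (z_t - alpha_t z0) / sigma_t
optimal_denoiser_for <- function(z0, schedule) {
  function(z, t) {
    a <- schedule$alpha[t + 1L]; s <- schedule$sigma[t + 1L]
    list(zx = (z$zx - a * z0$zx) / s, zh = (z$zh - a * z0$zh) / s)
  }
}
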