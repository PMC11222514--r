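# Cheap structural properties of the sampling machinery; a briefly trained
# model keeps the reverse chains numerically tame. The stochastic recovery
# experiments live in the acceptance suite against fully trained models.

.gen_cache <- new.env(parent = emptyenv())

quick_model <- function(condition = FALSE) {
  key <- if (condition) "cond" else "uncond"
  if (is.null(.gen_cache[[key]])) {
    ds <- if (condition) conditional_training_dataset() else recovery_training_dataset()
    cfg <- toy_config(condition_dim = if (condition) 1L else 0L)
    .gen_cache[[key]] <- train_denoiser(
      ds, cfg, toy_schedule(), n_steps = 400L, seed = 1L,
      condition = if (condition) "mpd" else NULL)
  }
  .gen_cache[[key]]
}

test_that("generation is seed-deterministic with the requested size and alphabet", {
  model <- quick_model()
  m1 <- generate(model, n_atoms = 3, seed = 123)
  m2 <- generate(model, n_atoms = 3, seed = 123)
  expect_identical(m1$coords, m2$coords)
  expect_identical(m1$elements, m2$elements)
  expect_equal(length(m1$elements), 3L)
  expect_true(all(m1$elements %in% model$alphabet))
  expect_lt(max(abs(colMeans(m1$coords))), 1e-8)
  m3 <- generate(model, n_atoms = 3, seed = 124)
  expect_false(identical(m3$coords, m1$coords))
  # size drawn from p(N) when not requested
  m4 <- generate(model, seed = 5)
  expect_equal(length(m4$elements), 3L)  # training set is all triatomics
})

test_that("the strided timestep path is evenly spaced and full stride equals the grid", {
  T_steps <- toy_schedule()$T
  expect_identical(moldiff:::timestep_path(T_steps, T_steps), as.integer(T_steps:0))
  p10 <- moldiff:::timestep_path(T_steps, 10L)
  expect_equal(p10[1], T_steps)
  expect_equal(p10[length(p10)], 0L)
  expect_length(p10, 11L)
  expect_true(all(diff(p10) < 0))
  expect_identical(moldiff:::timestep_path(T_steps, 1L), c(T_steps, 0L))
  expect_error(moldiff:::timestep_path(T_steps, 0L), "1, T")
  # path-identity of full-stride sampling with the standard sampler
  model <- quick_model()
  g1 <- generate(model, n_atoms = 3, seed = 77)
  g2 <- generate_strided(model, n_atoms = 3, k_steps = model$schedule$T, seed = 77)
  expect_identical(g1$coords, g2$coords)
})

test_that("optimization preserves shapes and degenerates to a round trip at t_opt = 0", {
  cond <- quick_model(condition = TRUE)
  mols <- list(ideal_water(), ideal_water())
  out0 <- optimize_molecules(mols, cond, t_opt = 0L, target = 1.2, seed = 3)
  expect_length(out0, 2L)
  expect_identical(out0[[1]]$elements, mols[[1]]$elements)
  expect_equal(out0[[1]]$coords, project_zero_cog(mols[[1]]$coords),
               tolerance = 1e-12)
  out <- optimize_molecules(mols, cond, t_opt = 20L, target = 1.2, seed = 3)
  expect_length(out, 2L)
  expect_equal(vapply(out, function(m) length(m$elements), integer(1)), c(3L, 3L))
  # an unconditional model is refused
  uncond <- quick_model()
  expect_error(optimize_molecules(mols, uncond, 10L, 1.2), "conditional")
  expect_error(generate(uncond, 3, condition = list(name = "mpd", value = 1)),
               "not trained with property conditioning")
  expect_error(generate(cond, 3), "supply `condition")
})

test_that("training is seed-deterministic, logs a loss curve, and aborts on NaN", {
  ds <- recovery_training_dataset()
  cfg <- toy_config()
  m1 <- train_denoiser(ds, cfg, toy_schedule(), n_steps = 30L, seed = 9L,
                       log_every = 10L)
  m2 <- train_denoiser(ds, cfg, toy_schedule(), n_steps = 30L, seed = 9L,
                       log_every = 10L)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params$head_h$W, m2$params$head_h$W)
  expect_equal(nrow(m1$log), 3L)
  expect_true(all(is.finite(m1$log$loss)))
  # checkpoint round trip
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m1, ck)
  back <- load_checkpoint(ck)
  expect_identical(back$params$head_h$W, m1$params$head_h$W)
  g3 <- generate(back, n_atoms = 3, seed = 11)
  g4 <- generate(m1, n_atoms = 3, seed = 11)
  expect_identical(g3$coords, g4$coords)
})

test_that("tidy/glance/autoplot expose the fitted model", {
  m <- quick_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "loss"))
  gl <- glance(m)
  expect_equal(gl$n_layers, 2L)
  expect_false(gl$conditional)
  expect_s3_class(autoplot(m), "ggplot")
})
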