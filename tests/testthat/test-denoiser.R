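# Equivariance contracts of the denoising network, probed with random
# parameters in double precision so contract violations are separated from
# float noise.

denoise_pair <- function(z, t, cfg, params, sch) {
  pr <- denoise(z, t, sch, cfg, params)
  list(zx = ad_value(pr$zx), zh = ad_value(pr$zh))
}

test_that("denoiser output transforms correctly under SE(3) and permutations", {
  sch <- toy_schedule()
  cfg <- toy_config()
  params <- init_denoiser(cfg, 3L, seed = 21)
  set.seed(22)
  for (rep in 1:3) {
    z <- random_latent(5, t = 100L)
    pr <- denoise_pair(z, 100L, cfg, params, sch)
    expect_lt(max(abs(colMeans(pr$zx))), 1e-6)

    R <- rotation_matrix(rnorm(3), runif(1, 0.2, 2))
    zr <- latent_state(z$zx %*% R, z$zh, t = 100L)
    prr <- denoise_pair(zr, 100L, cfg, params, sch)
    expect_lt(max(abs(prr$zx - pr$zx %*% R)), 1e-4)
    expect_lt(max(abs(prr$zh - pr$zh)), 1e-4)

    # translation of raw coordinates is absorbed by centring before the net
    shift <- matrix(rnorm(3), 5, 3, byrow = TRUE)
    zt <- latent_state(project_zero_cog(z$zx + shift), z$zh, t = 100L)
    prt <- denoise_pair(zt, 100L, cfg, params, sch)
    expect_lt(max(abs(prt$zx - pr$zx)), 1e-10)

    perm <- sample(5)
    zp <- latent_state(z$zx[perm, ], z$zh[perm, ], t = 100L)
    prp <- denoise_pair(zp, 100L, cfg, params, sch)
    expect_lt(max(abs(prp$zx - pr$zx[perm, ])), 1e-10)
    expect_lt(max(abs(prp$zh - pr$zh[perm, ])), 1e-10)
  }
})

test_that("reflection sensitivity is present iff local frames are enabled", {
  sch <- toy_schedule()
  P <- diag(c(-1, 1, 1))
  n_sensitive <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    z <- random_latent(4, t = 80L)
    zm <- latent_state(z$zx %*% P, z$zh, t = 80L)

    cfg_on <- toy_config(use_frames = TRUE)
    p_on <- init_denoiser(cfg_on, 3L, seed = seed)
    d0 <- denoise_pair(z, 80L, cfg_on, p_on, sch)
    dm <- denoise_pair(zm, 80L, cfg_on, p_on, sch)
    if (max(abs(dm$zh - d0$zh)) > 1e-6) n_sensitive <- n_sensitive + 1L

    # frames off: the network is blind to handedness, so a mirrored input
    # must give exactly mirrored outputs
    cfg_off <- toy_config(use_frames = FALSE)
    p_off <- init_denoiser(cfg_off, 3L, seed = seed)
    e0 <- denoise_pair(z, 80L, cfg_off, p_off, sch)
    em <- denoise_pair(zm, 80L, cfg_off, p_off, sch)
    expect_lt(max(abs(em$zh - e0$zh)), 1e-10)
    expect_lt(max(abs(em$zx - e0$zx %*% P)), 1e-10)
  }
  expect_equal(n_sensitive, 10L)
})

test_that("disabling scalar message attention reduces to ungated message passing", {
  sch <- toy_schedule()
  cfg_sma <- toy_config(use_sma = TRUE)
  cfg_off <- toy_config(use_sma = FALSE)
  params <- init_denoiser(cfg_sma, 3L, seed = 31)
  set.seed(32)
  z <- random_latent(4, t = 60L)
  # force every gate logit to saturate high: outputs of the gated net then
  # approach the ungated net clamped at gate = 1
  p_sat <- params
  h <- cfg_sma$node_scalar_dim
  for (l in seq_along(p_sat$layers)) {
    p_sat$layers[[l]]$msg$b2[1, h + 1L] <- 80
  }
  gated <- denoise_pair(z, 60L, cfg_sma, p_sat, sch)
  ungated <- denoise_pair(z, 60L, cfg_off, p_sat, sch)
  expect_lt(max(abs(gated$zh - ungated$zh)), 1e-10)
  expect_lt(max(abs(gated$zx - ungated$zx)), 1e-10)
})

test_that("single-atom inputs give a zero coordinate prediction", {
  sch <- toy_schedule()
  cfg <- toy_config()
  params <- init_denoiser(cfg, 3L, seed = 41)
  z1 <- latent_state(matrix(0, 1, 3), matrix(rnorm(3), 1, 3), t = 50L)
  pr <- denoise_pair(z1, 50L, cfg, params, sch)
  expect_equal(pr$zx, matrix(0, 1, 3))
  expect_true(all(is.finite(pr$zh)))
})

test_that("config accounting: frames and dimensions change the parameter count", {
  p1 <- init_denoiser(toy_config(use_frames = TRUE), 3L, seed = 1)
  p2 <- init_denoiser(toy_config(use_frames = FALSE), 3L, seed = 1)
  expect_gt(n_parameters(p1), n_parameters(p2))
  p3 <- init_denoiser(toy_config(node_scalar_dim = 64L), 3L, seed = 1)
  expect_gt(n_parameters(p3), n_parameters(p1))
})

test_that("a 2-layer toy config overfits one fixed denoising pair", {
  # capacity smoke test: the training loss on a single frozen (z0, eps, t)
  # pair must collapse by orders of magnitude
  sch <- toy_schedule()
  cfg <- toy_config()
  set.seed(51)
  z0 <- random_latent(3, t = 0L)
  eps <- sample_joint_noise(3, 3)
  t_fix <- 60L
  z_t <- forward_noise(z0, t_fix, eps, sch)
  params <- init_denoiser(cfg, 3L, seed = 51)
  st <- moldiff:::adam_state(params)
  loss0 <- NULL
  for (step in 1:400) {
    tape <- ad_tape()
    wp <- moldiff:::wrap_params(tape, params)
    pred <- denoise(z_t, t_fix, sch, cfg, wp)
    dx <- ad_sub(pred$zx, eps$zx); dh <- ad_sub(pred$zh, eps$zh)
    loss <- ad_scale(ad_add(ad_sum(ad_mul(dx, dx)), ad_sum(ad_mul(dh, dh))), 0.5)
    if (step == 1) loss0 <- as.numeric(ad_value(loss))
    ad_backward(loss)
    upd <- moldiff:::adam_step(params, moldiff:::grad_of(wp), st, lr = 5e-3)
    params <- upd$params; st <- upd$state
  }
  final <- as.numeric(ad_value(loss))
  expect_lt(final, 1e-3)
  expect_lt(final, loss0 / 100)
})
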