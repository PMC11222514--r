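# Closed-form diffusion mathematics on the joint latent z = [z^(x), z^(h)]:
# forward noising, true Gaussian posterior, epsilon-parametrized reverse
# step, and the training loss. The coordinate channel lives on the zero
# centre-of-gravity (zero-CoG) subspace throughout, which is what makes the
# coordinate likelihood translation-invariant.

#' Construct a joint latent state
#'
#' The latent variable of the diffusion chain: a zero-CoG coordinate channel
#' `zx` (N x 3) and an invariant feature channel `zh` (N x d, scaled one-hot
#' atom types plus a charge slot).
#'
#' @param zx N x 3 numeric matrix, column means must be zero (within 1e-6).
#' @param zh N x d numeric matrix.
#' @param t integer timestep the state lives at.
#' @return object of class `latent_state`.
#' @export
latent_state <- function(zx, zh, t = 0L) {
  zx <- as.matrix(zx); zh <- as.matrix(zh)
  if (nrow(zx) != nrow(zh)) stop("zx and zh must have the same number of rows.", call. = FALSE)
  if (ncol(zx) != 3L) stop("zx must be N x 3.", call. = FALSE)
  if (isTRUE(max(abs(colMeans(zx))) > 1e-6 * max(1, max(abs(zx))))) {
    stop("coordinate channel must have zero column means (zero-CoG).", call. = FALSE)
  }
  structure(list(zx = zx, zh = zh, t = as.integer(t), N = nrow(zx)),
            class = "latent_state")
}

#' @export
print.latent_state <- function(x, ...) {
  cat(sprintf("<latent_state> N = %d, d = %d, t = %d\n", x$N, ncol(x$zh), x$t))
  invisible(x)
}

#' Project coordinates onto the zero centre-of-gravity subspace
#'
#' Orthogonal projection onto \eqn{\{X : \sum_i x_i = 0\}}: subtracts the
#' column means. Idempotent; annihilates global translations.
#'
#' @param coords N x 3 numeric matrix, N >= 1.
#' @return N x 3 matrix with zero column means.
#' @export
project_zero_cog <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("`coords` must contain at least one atom.", call. = FALSE)
  sweep(coords, 2L, colMeans(coords), "-")
}

#' Draw a standard Gaussian restricted to the zero-CoG subspace
#'
#' Samples N x 3 i.i.d. standard normals and projects them onto the
#' zero-column-mean subspace; the result is exactly the standard Gaussian of
#' the (N-1) x 3 dimensional subspace. For N = 1 the subspace is \{0\}.
#'
#' @param n_atoms number of atoms N >= 1.
#' @return N x 3 matrix with zero column means.
#' @export
sample_subspace_gaussian <- function(n_atoms) {
  if (n_atoms < 1L) stop("`n_atoms` must be >= 1.", call. = FALSE)
  if (n_atoms == 1L) return(matrix(0, 1L, 3L))
  project_zero_cog(matrix(stats::rnorm(n_atoms * 3L), n_atoms, 3L))
}

#' Draw joint noise for a latent state
#'
#' Coordinate part from the zero-CoG subspace Gaussian, feature part from a
#' standard Gaussian.
#'
#' @param n_atoms number of atoms.
#' @param d feature dimension.
#' @return list with `zx` (N x 3, zero-CoG) and `zh` (N x d).
#' @export
sample_joint_noise <- function(n_atoms, d) {
  list(zx = sample_subspace_gaussian(n_atoms),
       zh = matrix(stats::rnorm(n_atoms * d), n_atoms, d))
}

#' Forward-noise a clean latent state to timestep t
#'
#' The closed-form marginal of the variance-preserving chain:
#' \eqn{z_t = \alpha_t z_0 + \sigma_t \epsilon} (the schedule tables are the
#' marginal coefficients, i.e. \eqn{\alpha_{t|0}} up to the precision clip
#' at step 0), applied channelwise
#' to coordinates and features. The coordinate noise must itself be zero-CoG
#' so the coordinate channel never leaves the subspace.
#'
#' @param z0 clean [latent_state()] at t = 0.
#' @param t target timestep.
#' @param eps noise as returned by [sample_joint_noise()] (or `NULL` to draw).
#' @param schedule a [build_noise_schedule()] object.
#' @return noisy `latent_state` at timestep `t`.
#' @export
forward_noise <- function(z0, t, eps = NULL, schedule) {
  stopifnot(inherits(z0, "latent_state"))
  if (z0$t != 0L) stop("`z0` must live at t = 0.", call. = FALSE)
  if (is.null(eps)) eps <- sample_joint_noise(z0$N, ncol(z0$zh))
  if (!identical(dim(eps$zx), dim(z0$zx)) || !identical(dim(eps$zh), dim(z0$zh))) {
    stop("noise shapes must match the latent state.", call. = FALSE)
  }
  if (isTRUE(max(abs(colMeans(eps$zx))) > 1e-6)) {
    stop("coordinate noise must be zero-CoG.", call. = FALSE)
  }
  a_t <- sched_alpha(schedule, t)
  s_t <- sched_sigma(schedule, t)
  latent_state(a_t * z0$zx + s_t * eps$zx,
               a_t * z0$zh + s_t * eps$zh,
               t = t)
}

#' True denoising posterior moments q(z_s | z_t, z_0)
#'
#' The Gaussian posterior of the noising chain:
#' \deqn{\mu_{t\to s} = \frac{\alpha_s \sigma_{t|s}^2}{\sigma_t^2} z_0 +
#'       \frac{\alpha_{t|s} \sigma_s^2}{\sigma_t^2} z_t, \qquad
#'       \sigma_{t\to s} = \frac{\sigma_{t|s}\,\sigma_s}{\sigma_t}.}
#'
#' @param z_t noisy latent at step t.
#' @param z0 clean latent (true or predicted).
#' @param s target step, \eqn{0 \le s < t}.
#' @param schedule a [build_noise_schedule()] object.
#' @return list with `mu` (list `zx`, `zh`) and scalar `sigma_t_to_s`.
#' @export
posterior_moments <- function(z_t, z0, s, schedule) {
  stopifnot(inherits(z_t, "latent_state"))
  t <- z_t$t
  if (s >= t) stop("need s < t for the denoising posterior.", call. = FALSE)
  sig_t <- sched_sigma(schedule, t)
  if (sig_t <= 0) stop("degenerate posterior: sigma_t = 0.", call. = FALSE)
  cm <- conditional_moments(schedule, s, t)
  a_s <- sched_alpha(schedule, s)
  sig_s <- sched_sigma(schedule, s)
  w0 <- a_s * cm$sigma_ts^2 / sig_t^2
  wt <- cm$alpha_ts * sig_s^2 / sig_t^2
  list(mu = list(zx = w0 * z0$zx + wt * z_t$zx,
                 zh = w0 * z0$zh + wt * z_t$zh),
       sigma_t_to_s = cm$sigma_ts * sig_s / sig_t)
}

#' Recover the clean state implied by a noise prediction
#'
#' Inverts the forward marginal given predicted noise:
#' \eqn{\tilde z_0 = z_t/\alpha_t - \hat\epsilon\, \sigma_t/\alpha_t},
#' channelwise. Exact when the true noise is supplied.
#'
#' @param z_t noisy latent at step t >= 1.
#' @param eps_hat predicted noise: list with `zx`, `zh`.
#' @param schedule a [build_noise_schedule()] object.
#' @return predicted clean `latent_state` (t = 0).
#' @export
predict_clean <- function(z_t, eps_hat, schedule) {
  stopifnot(inherits(z_t, "latent_state"))
  if (z_t$t < 1L) stop("`z_t` must live at t >= 1.", call. = FALSE)
  a_t <- sched_alpha(schedule, z_t$t)
  if (a_t < 1e-12) stop("alpha_t below numerical floor.", call. = FALSE)
  s_t <- sched_sigma(schedule, z_t$t)
  latent_state(z_t$zx / a_t - eps_hat$zx * s_t / a_t,
               z_t$zh / a_t - eps_hat$zh * s_t / a_t,
               t = 0L)
}

#' One ancestral reverse step z_t -> z_s
#'
#' Samples \eqn{z_s \sim \mathcal{N}(\mu_{t\to s}(z_t, \tilde z_0),
#' \sigma_{t\to s}^2 I)} with \eqn{\tilde z_0} from [predict_clean()]. The
#' coordinate noise is drawn on the zero-CoG subspace, so the coordinate
#' channel never acquires a centre-of-gravity drift.
#'
#' @param z_t noisy latent at step t.
#' @param eps_hat predicted noise (list `zx`, `zh`).
#' @param s target step `s < t`.
#' @param schedule a [build_noise_schedule()] object.
#' @param noise optional pre-drawn noise (list `zx`, `zh`); pass zeros to
#'   obtain the posterior mean deterministically.
#' @param clip_clean optional symmetric bound applied elementwise to the
#'   predicted clean state before the posterior step. Large strides amplify
#'   denoiser error through \eqn{1/\alpha_t}; clipping the implied
#'   \eqn{\tilde z_0} to a generous data-scale bound is the standard
#'   stabilization and leaves ordinary samples untouched.
#' @return `latent_state` at step `s`.
#' @export
reverse_step <- function(z_t, eps_hat, s, schedule, noise = NULL,
                         clip_clean = NULL) {
  z0_hat <- predict_clean(z_t, eps_hat, schedule)
  if (!is.null(clip_clean)) {
    z0_hat <- latent_state(
      project_zero_cog(pmax(pmin(z0_hat$zx, clip_clean), -clip_clean)),
      pmax(pmin(z0_hat$zh, clip_clean), -clip_clean), t = 0L)
  }
  pm <- posterior_moments(z_t, z0_hat, s, schedule)
  if (is.null(noise)) noise <- sample_joint_noise(z_t$N, ncol(z_t$zh))
  latent_state(pm$mu$zx + pm$sigma_t_to_s * noise$zx,
               pm$mu$zh + pm$sigma_t_to_s * noise$zh,
               t = s)
}

#' Denoising score-matching loss
#'
#' \eqn{\tfrac12 w_t \lVert \epsilon - \hat\epsilon \rVert^2} over both
#' channels, with `reduction = "sum"` per molecule (default) or `"mean"`
#' over entries. The training objective uses \eqn{w_t = 1}.
#'
#' @param eps true noise (list `zx`, `zh`).
#' @param eps_hat predicted noise (list `zx`, `zh`).
#' @param w_t scalar weight (default 1).
#' @param reduction `"sum"` or `"mean"`.
#' @return non-negative scalar.
#' @export
diffusion_loss <- function(eps, eps_hat, w_t = 1, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!identical(dim(eps$zx), dim(eps_hat$zx)) ||
      !identical(dim(eps$zh), dim(eps_hat$zh))) {
    stop("noise shapes must match.", call. = FALSE)
  }
  ss <- sum((eps$zx - eps_hat$zx)^2) + sum((eps$zh - eps_hat$zh)^2)
  if (reduction == "mean") ss <- ss / (length(eps$zx) + length(eps$zh))
  0.5 * w_t * ss
}
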