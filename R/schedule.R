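# Variance-preserving noise schedules and their conditional moments.

#' Build a variance-preserving noise schedule
#'
#' Constructs the per-timestep signal/noise tables \eqn{(\alpha_t, \sigma_t)}
#' for a discrete variance-preserving diffusion chain with
#' \eqn{\alpha_t^2 + \sigma_t^2 = 1}. The default `"polynomial"` family sets
#' \eqn{\alpha_t^2 = (1 - (t/T)^2)^2}, clips the stepwise ratio
#' \eqn{\alpha_t^2/\alpha_{t-1}^2} below at 0.001 for numerical stability,
#' and rescales the whole table into \eqn{[\texttt{precision},
#' 1 - \texttt{precision}]} so that both chain ends stay strictly inside
#' \eqn{(0, 1)}. A `"cosine"` family is also available.
#'
#' @param T_steps integer number of diffusion steps \eqn{T \ge 1}; the tables
#'   cover the grid \eqn{t = 0, \dots, T}.
#' @param kind schedule family, `"polynomial"` (default) or `"cosine"`.
#' @param precision small positive clipping parameter in \eqn{(0, 0.5)}
#'   bounding the schedule away from the degenerate endpoints.
#' @return An object of class `noise_schedule`: list with `T`, `alpha`,
#'   `sigma` (numeric vectors of length `T + 1`, entry `t + 1` holds step
#'   `t`), `kind`, and `precision`.
#' @examples
#' sch <- build_noise_schedule(1000)
#' sch$alpha[1]          # ~1 at the clean end
#' sch$sigma[1001]       # ~1 at the noise end
#' @export
build_noise_schedule <- function(T_steps, kind = c("polynomial", "cosine"),
                                 precision = 1e-5) {
  kind <- match.arg(kind)
  if (length(T_steps) != 1L || !is.finite(T_steps) || T_steps < 1 ||
      T_steps != round(T_steps)) {
    stop("`T_steps` must be a positive integer.", call. = FALSE)
  }
  if (length(precision) != 1L || !is.finite(precision) ||
      precision <= 0 || precision >= 0.5) {
    stop("`precision` must lie in (0, 0.5).", call. = FALSE)
  }
  T_steps <- as.integer(T_steps)
  t <- 0:T_steps
  alpha2 <- switch(kind,
    polynomial = (1 - (t / T_steps)^2)^2,
    cosine = cos((t / T_steps + 0.008) / 1.008 * pi / 2)^2
  )
  # clip stepwise ratios so alpha^2 never collapses faster than 1000x/step
  ratio <- alpha2[-1] / alpha2[-length(alpha2)]
  ratio[!is.finite(ratio)] <- 0
  ratio <- pmin(pmax(ratio, 0.001), 1)
  alpha2 <- cumprod(c(alpha2[1], ratio))
  alpha2 <- alpha2 / alpha2[1]
  # rescale into [precision, 1 - precision]: keeps both ends non-degenerate
  alpha2 <- (1 - 2 * precision) * alpha2 + precision
  structure(
    list(T = T_steps,
         alpha = sqrt(alpha2),
         sigma = sqrt(1 - alpha2),
         kind = kind,
         precision = precision),
    class = "noise_schedule"
  )
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T = %d, precision = %g\n",
              x$kind, x$T, x$precision))
  cat(sprintf("  alpha: %.6f -> %.6f ; sigma: %.6f -> %.6f\n",
              x$alpha[1], x$alpha[x$T + 1], x$sigma[1], x$sigma[x$T + 1]))
  invisible(x)
}

sched_alpha <- function(schedule, t) schedule$alpha[t + 1L]
sched_sigma <- function(schedule, t) schedule$sigma[t + 1L]

#' Conditional transition moments between two timesteps
#'
#' For \eqn{0 \le s \le t \le T}, returns \eqn{\alpha_{t|s} =
#' \alpha_t/\alpha_s} and \eqn{\sigma_{t|s}} with
#' \eqn{\sigma_{t|s}^2 = \sigma_t^2 - \alpha_{t|s}^2 \sigma_s^2}, the unique
#' coefficients for which composing the Gaussian transitions
#' \eqn{q(z_s | z_0)} and \eqn{q(z_t | z_s)} reproduces the marginal
#' \eqn{q(z_t | z_0)}.
#'
#' @param schedule a [build_noise_schedule()] object.
#' @param s,t source and target steps, \eqn{s \le t}.
#' @return list with `alpha_ts`, `sigma_ts`, `s`, `t`.
#' @export
conditional_moments <- function(schedule, s, t) {
  stopifnot(inherits(schedule, "noise_schedule"))
  if (s > t) stop("`s` must not exceed `t`.", call. = FALSE)
  if (s < 0 || t > schedule$T) stop("steps out of range [0, T].", call. = FALSE)
  a_ts <- sched_alpha(schedule, t) / sched_alpha(schedule, s)
  s2 <- sched_sigma(schedule, t)^2 - a_ts^2 * sched_sigma(schedule, s)^2
  list(alpha_ts = a_ts, sigma_ts = sqrt(max(s2, 0)), s = s, t = t)
}
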