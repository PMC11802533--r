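#' Build a diffusion variance schedule
#'
#' Per-step variance increments \eqn{\beta_t} in (0,1), retention factors
#' \eqn{\alpha_t = 1 - \beta_t}, the cumulative signal level
#' \eqn{\gamma_t = \prod_{i \le t} \alpha_i}, and the fixed reverse-process
#' variance \eqn{\sigma_t^2 = 1 - \alpha_t}. The default is the full-scale
#' schedule (T = 2000, linear \eqn{\beta} from 1e-6 to 1e-2), for which
#' \eqn{\gamma_T \approx e^{-10}}: the terminal state is indistinguishable
#' from pure noise.
#'
#' @param T number of diffusion steps.
#' @param beta_start,beta_end endpoints of the \eqn{\beta} ramp.
#' @param kind `"linear"` (default) or `"quadratic"` (linear in
#'   \eqn{\sqrt{\beta}}).
#' @return object of class `noise_schedule` with vectors `beta`, `alpha`,
#'   `gamma`, `sigma2`, each of length `T`.
#' @export
noise_schedule <- function(T = 2000L, beta_start = 1e-6, beta_end = 1e-2,
                           kind = c("linear", "quadratic")) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  if (T < 1L) stop("T must be >= 1")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("need 0 < beta_start <= beta_end < 1")
  beta <- switch(kind,
    linear = seq(beta_start, beta_end, length.out = T),
    quadratic = seq(sqrt(beta_start), sqrt(beta_end), length.out = T)^2
  )
  alpha <- 1 - beta
  structure(list(
    T = T, beta = beta, alpha = alpha,
    gamma = cumprod(alpha), sigma2 = 1 - alpha,
    kind = kind, beta_start = beta_start, beta_end = beta_end
  ), class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("Noise schedule: T = %d, beta %s in [%.2g, %.2g], gamma_T = %.3g\n",
              x$T, x$kind, x$beta_start, x$beta_end, x$gamma[x$T]))
  invisible(x)
}

check_step <- function(t, schedule) {
  if (length(t) != 1 || t < 1 || t > schedule$T || t != round(t))
    stop("step index t must be an integer in 1..T")
  as.integer(t)
}

#' One forward diffusion step
#'
#' Draws \eqn{y_t = \sqrt{\alpha_t}\, y_{t-1} + \sqrt{1-\alpha_t}\, z},
#' \eqn{z \sim N(0, I)}: a single increment of the Markov noising chain.
#'
#' @param y_prev image (matrix/array) at step t-1 (y0 for t = 1).
#' @param t step index in 1..T.
#' @param schedule a [noise_schedule()].
#' @param z optional noise draw (same shape); when `NULL` a fresh standard
#'   normal draw is taken from the current RNG stream.
#' @return image at step t, same shape.
#' @export
forward_step <- function(y_prev, t, schedule, z = NULL) {
  t <- check_step(t, schedule)
  if (is.null(z)) z <- array(stats::rnorm(length(y_prev)), dim = dim_or_len(y_prev))
  a <- schedule$alpha[t]
  sqrt(a) * y_prev + sqrt(1 - a) * z
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Closed-form forward marginal
#'
#' Jumps directly from the clean image to step t:
#' \eqn{y_t = \sqrt{\gamma_t}\, y_0 + \sqrt{1-\gamma_t}\, \epsilon}. This is
#' the marginal of iterating [forward_step()] t times and is what the
#' training objective uses.
#'
#' @param y0 clean image.
#' @param t step index in 1..T.
#' @param epsilon standard-normal noise, same shape as `y0`.
#' @param schedule a [noise_schedule()].
#' @return noisy image at step t.
#' @export
forward_marginal <- function(y0, t, epsilon, schedule) {
  t <- check_step(t, schedule)
  if (length(epsilon) != length(y0)) stop("epsilon must match y0 in shape")
  g <- schedule$gamma[t]
  sqrt(g) * y0 + sqrt(1 - g) * epsilon
}

#' One reverse (denoising) step
#'
#' Given the model's noise estimate, applies
#' \deqn{y_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big[y_t -
#'   \frac{1-\alpha_t}{\sqrt{1-\gamma_t}}\hat\epsilon\Big] +
#'   \sqrt{1-\alpha_t}\; z}
#' with \eqn{z \sim N(0,I)} when `inject_noise` is on and \eqn{z = 0} when
#' off; noise is never injected at t = 1. Optionally the implied one-step
#' estimate \eqn{\hat y_0 = (y_t - \sqrt{1-\gamma_t}\hat\epsilon)/\sqrt{\gamma_t}}
#' is clipped to \[-1, 1\] before the mean is formed (standard DDPM
#' stabilization of early, unreliable predictions).
#'
#' @param y_t image at step t.
#' @param t step index, >= 1.
#' @param epsilon_hat predicted noise field, same shape.
#' @param schedule a [noise_schedule()].
#' @param inject_noise add the \eqn{\sqrt{1-\alpha_t}} noise term (default
#'   TRUE; forced off at t = 1).
#' @param clip_y0 clip the implied clean-image estimate to \[-1, 1\]
#'   (default TRUE).
#' @param z optional noise draw for the injected term.
#' @return image at step t-1.
#' @export
reverse_step <- function(y_t, t, epsilon_hat, schedule,
                         inject_noise = TRUE, clip_y0 = TRUE, z = NULL) {
  t <- check_step(t, schedule)
  if (length(epsilon_hat) != length(y_t)) stop("epsilon_hat must match y_t in shape")
  a <- schedule$alpha[t]
  g <- schedule$gamma[t]
  if (clip_y0) {
    y0_hat <- (y_t - sqrt(1 - g) * epsilon_hat) / sqrt(g)
    y0_hat <- pmin(pmax(y0_hat, -1), 1)
    epsilon_hat <- (y_t - sqrt(g) * y0_hat) / sqrt(1 - g)
  }
  mean_t <- (y_t - (1 - a) / sqrt(1 - g) * epsilon_hat) / sqrt(a)
  if (inject_noise && t > 1L) {
    if (is.null(z)) z <- array(stats::rnorm(length(y_t)), dim = dim_or_len(y_t))
    mean_t <- mean_t + sqrt(1 - a) * z
  }
  mean_t
}

#' Sample a super-resolved image by iterative refinement
#'
#' Starts from pure Gaussian noise \eqn{y_T} and applies [reverse_step()]
#' down to t = 1, conditioning the denoiser on the low-resolution image at
#' every step. Inputs and outputs are on the normalized \[-1, 1\] scale;
#' see [infer_series()] for the full denormalized pipeline.
#'
#' @param x_lr conditioning LR image or an array `rows x cols x B` of a
#'   batch of LR images, normalized to \[-1, 1\].
#' @param model a `denoiser` (see [build_denoiser()]), or a function
#'   `(x_lr, y_t, gamma) -> epsilon_hat` for testing.
#' @param schedule a [noise_schedule()].
#' @param seed optional integer for a local RNG stream.
#' @param inject_noise,clip_y0 passed to [reverse_step()].
#' @return sampled image(s), same shape as `x_lr`, on the \[-1, 1\] scale.
#' @export
sample_sr <- function(x_lr, model, schedule, seed = NULL,
                      inject_noise = TRUE, clip_y0 = TRUE) {
  predict_fun <- if (inherits(model, "denoiser")) {
    function(x, y, g) predict_noise(model, x, y, g)
  } else if (is.function(model)) model else
    stop("model must be a denoiser or a function(x_lr, y_t, gamma)")
  with_local_seed(seed, {
    y <- array(stats::rnorm(length(x_lr)), dim = dim_or_len(x_lr))
    for (t in seq.int(schedule$T, 1L)) {
      eps_hat <- predict_fun(x_lr, y, schedule$gamma[t])
      y <- reverse_step(y, t, eps_hat, schedule,
                        inject_noise = inject_noise, clip_y0 = clip_y0)
    }
    y
  })
}

#' Noise-prediction training loss
#'
#' The L1 objective: corrupt the target with the closed-form forward
#' marginal at signal level `gamma`, ask the model for the noise, and take
#' the mean absolute deviation from the true noise,
#' \eqn{L = \|f_\theta(x, \sqrt{\gamma} y_0 + \sqrt{1-\gamma}\epsilon,
#' \gamma) - \epsilon\|_1 / N}.
#'
#' @param model a `denoiser` or a function `(x_lr, y_t, gamma)`.
#' @param x_lr conditioning LR image, \[-1, 1\].
#' @param y0 clean HR target, \[-1, 1\].
#' @param epsilon standard-normal draw, same shape as `y0`.
#' @param gamma signal level in (0, 1).
#' @return scalar loss >= 0.
#' @export
training_loss <- function(model, x_lr, y0, epsilon, gamma) {
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("gamma must lie in (0, 1)")
  if (length(epsilon) != length(y0)) stop("epsilon must match y0 in shape")
  y_t <- sqrt(gamma) * y0 + sqrt(1 - gamma) * epsilon
  predict_fun <- if (inherits(model, "denoiser")) {
    function(x, y, g) predict_noise(model, x, y, g)
  } else model
  mean(abs(predict_fun(x_lr, y_t, gamma) - epsilon))
}
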