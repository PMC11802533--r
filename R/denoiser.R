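#' Configuration of the conditional U-Net noise predictor
#'
#' Describes the denoiser \eqn{f_\theta(x, y_t, \gamma)}: a two-channel
#' input (LR conditioning image concatenated with the noisy image), a
#' one-channel noise output, an encoder/decoder with skip connections,
#' residual blocks (group norm + SiLU + additive noise-level embedding +
#' dropout), average-pool downsampling, nearest-neighbor + convolution
#' upsampling, and single-head convolutional self-attention interleaved
#' with the residual blocks at the bottleneck. The decoder runs
#' `res_blocks + 1` blocks per level, each consuming one stored encoder
#' feature by channel concatenation.
#'
#' The full-scale default (five levels, channels 64-128-256-512-512, two
#' residual blocks) has roughly 92 million trainable parameters.
#'
#' @param channels integer vector, channels per level (length = number of
#'   levels). Default `c(64, 128, 256, 512, 512)`.
#' @param res_blocks residual blocks per encoder level (default 2).
#' @param dropout dropout rate inside residual blocks (default 0.2).
#' @param attention logical, self-attention at the bottleneck (default TRUE).
#' @param emb_dim width of the noise-level embedding MLP; default
#'   `4 * channels[1]`. The embedding is a sinusoidal encoding of
#'   \eqn{\sqrt{\gamma}} passed through two linear layers and added into
#'   every residual block.
#' @return object of class `unet_config`.
#' @export
unet_config <- function(channels = c(64L, 128L, 256L, 512L, 512L),
                        res_blocks = 2L, dropout = 0.2,
                        attention = TRUE, emb_dim = NULL) {
  channels <- as.integer(channels)
  if (length(channels) < 1L || any(channels < 1L))
    stop("channels must be positive integers, one per level")
  if (any(channels %% 2L != 0L))
    stop("channel counts must be even (sinusoidal embedding width)")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (is.null(emb_dim)) emb_dim <- 4L * channels[1]
  structure(list(
    channels = channels, levels = length(channels),
    res_blocks = as.integer(res_blocks), dropout = dropout,
    attention = isTRUE(attention), emb_dim = as.integer(emb_dim),
    in_channels = 2L, out_channels = 1L
  ), class = "unet_config")
}

#' Instantiate the conditional U-Net denoiser
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization (and dropout stream).
#' @return object of class `denoiser` holding the network handle, its
#'   configuration and parameter count.
#' @export
build_denoiser <- function(config = unet_config(), seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  ptr <- .unet_create(config, as.integer(seed))
  structure(list(
    ptr = ptr, config = config, seed = as.integer(seed),
    n_params = .unet_n_params(ptr)
  ), class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("Conditional U-Net denoiser: %d levels [%s], %d+1 dec blocks/level, %s attention\n",
              x$config$levels, paste(x$config$channels, collapse = ", "),
              x$config$res_blocks, if (x$config$attention) "bottleneck" else "no"))
  cat(sprintf("  %.1fM trainable parameters, dropout %.2f\n",
              x$n_params / 1e6, x$config$dropout))
  invisible(x)
}

# minimum spatial divisibility for the encoder/decoder ladder
check_unet_input <- function(config, H, W) {
  f <- 2^(config$levels - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop("spatial size ", H, "x", W, " not divisible by 2^(levels-1) = ", f)
}

# Stack LR conditioning and noisy image into the (H, W, 2, B) network input.
# x_lr, y_t: matrices (single image) or arrays rows x cols x B.
stack_input <- function(x_lr, y_t) {
  if (is.matrix(x_lr)) x_lr <- array(x_lr, c(dim(x_lr), 1L))
  if (is.matrix(y_t)) y_t <- array(y_t, c(dim(y_t), 1L))
  if (!all(dim(x_lr) == dim(y_t))) stop("x_lr and y_t must have the same shape")
  d <- dim(x_lr)
  out <- array(0, c(d[1], d[2], 2L, d[3]))
  out[, , 1L, ] <- x_lr
  out[, , 2L, ] <- y_t
  out
}

#' Predict the noise field
#'
#' Runs the denoiser in evaluation mode (dropout off, deterministic):
#' \eqn{\hat\epsilon = f_\theta(x, y_t, \gamma)}.
#'
#' @param model a `denoiser`.
#' @param x_lr conditioning LR image (matrix) or batch (rows x cols x B),
#'   normalized to \[-1, 1\].
#' @param y_t noisy image(s), same shape as `x_lr`.
#' @param gamma noise level(s) in (0, 1]; scalar or one per batch item.
#' @param train logical; `TRUE` enables dropout (used by the training loop).
#' @return predicted noise, same shape as `y_t`.
#' @export
predict_noise <- function(model, x_lr, y_t, gamma, train = FALSE) {
  stopifnot(inherits(model, "denoiser"))
  single <- is.matrix(y_t)
  xin <- stack_input(x_lr, y_t)
  d <- dim(xin)
  check_unet_input(model$config, d[1], d[2])
  if (any(gamma <= 0) || any(gamma > 1)) stop("gamma must lie in (0, 1]")
  out <- .unet_forward(model$ptr, xin, as.numeric(gamma), isTRUE(train))
  if (single) out <- out[, , 1L]
  out
}

# One optimization step on a batch: forward, L1 loss vs the true noise,
# backprop, AdamW update. Returns the batch loss.
denoiser_train_step <- function(model, x_lr, y_t, epsilon, gamma,
                                lr, weight_decay = 1e-4, clipnorm = 1.0) {
  xin <- stack_input(x_lr, y_t)
  loss <- .unet_loss_grad(model$ptr, xin, as.numeric(epsilon),
                          as.numeric(gamma), TRUE)
  if (!is.finite(loss)) stop("training diverged: non-finite loss")
  .unet_adam_step(model$ptr, lr, weight_decay, clipnorm)
  loss
}

#' Extract / restore denoiser weights
#'
#' `denoiser_weights()` returns all trainable parameters as a list of
#' numeric matrices; `restore_denoiser()` rebuilds a denoiser from a
#' checkpoint produced by [save_checkpoint()].
#'
#' @param model a `denoiser`.
#' @return list of numeric matrices.
#' @export
denoiser_weights <- function(model) {
  stopifnot(inherits(model, "denoiser"))
  .unet_get_params(model$ptr)
}

#' @rdname denoiser_weights
#' @param weights list of matrices from [denoiser_weights()].
#' @export
set_denoiser_weights <- function(model, weights) {
  stopifnot(inherits(model, "denoiser"))
  .unet_set_params(model$ptr, weights)
  invisible(model)
}
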