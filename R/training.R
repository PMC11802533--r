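#' Assemble a paired LR/HR training set from dynamic series
#'
#' Splits subjects (whole series) into train and test groups — a subject
#' never contributes frames to both — then turns every frame of every
#' series into one conditioning/target pair via k-space phase-line
#' truncation, with the retained fraction drawn uniformly per pair from
#' `fraction_range` (degradation-strength augmentation). Each series is
#' normalized by its own global maximum so signal-time relationships
#' within a series survive normalization.
#'
#' @param series_list list of `perfusion_series`, one per subject (or per
#'   subject/slice; elements are the split unit).
#' @param fraction_range range of retained phase-line fractions, default
#'   `c(0.30, 0.50)`.
#' @param split train fraction of subjects (default 0.8).
#' @param crop_size matrix size of the pairs; defaults to the series size
#'   (use 96 on full-size data).
#' @param seed integer seed controlling the split and the fraction draws.
#' @return object of class `sr_dataset` with `train`, `test` (lists of
#'   `lrhr_pair`), `split_subjects`, and the frame provenance of every pair.
#' @export
assemble_dataset <- function(series_list, fraction_range = c(0.30, 0.50),
                             split = 0.8, crop_size = NULL, seed = 1L) {
  n_sub <- length(series_list)
  if (split < 1 && n_sub < 2L)
    stop("need at least 2 subjects for a train/test split")
  if (fraction_range[1] <= 0 || fraction_range[2] > 1 ||
      fraction_range[1] > fraction_range[2])
    stop("fraction_range must be increasing within (0, 1]")
  with_local_seed(seed, {
    n_train <- round(split * n_sub)
    perm <- sample.int(n_sub)
    train_ids <- sort(perm[seq_len(n_train)])
    test_ids <- setdiff(seq_len(n_sub), train_ids)
    build <- function(ids) {
      pairs <- list()
      prov <- list()
      for (s in ids) {
        ser <- series_list[[s]]
        stopifnot(inherits(ser, "perfusion_series"))
        nf <- dim(ser$frames)[1]
        cs <- if (is.null(crop_size)) dim(ser$frames)[2] else crop_size
        maxv <- max(ser$frames)
        for (i in seq_len(nf)) {
          f <- stats::runif(1, fraction_range[1], fraction_range[2])
          pairs[[length(pairs) + 1L]] <- make_lr_hr_pair(
            ser$frames[i, , ], fraction = f, crop_size = cs, norm_max = maxv)
          prov[[length(prov) + 1L]] <- c(subject = s, frame = i)
        }
      }
      attr(pairs, "provenance") <- do.call(rbind, prov)
      pairs
    }
    structure(list(
      train = build(train_ids), test = build(test_ids),
      split_subjects = list(train = train_ids, test = test_ids),
      fraction_range = fraction_range, seed = as.integer(seed)
    ), class = "sr_dataset")
  })
}

#' @export
print.sr_dataset <- function(x, ...) {
  cat(sprintf("SR dataset: %d training / %d test pairs (%d / %d subjects), fractions [%.2f, %.2f]\n",
              length(x$train), length(x$test),
              length(x$split_subjects$train), length(x$split_subjects$test),
              x$fraction_range[1], x$fraction_range[2]))
  invisible(x)
}

#' Training control parameters
#'
#' @param iterations optimizer steps (full-scale default 50000; the desk
#'   preset uses 2000).
#' @param learning_rate AdamW learning rate (full-scale default 3e-5).
#' @param batch_size images per step (full-scale default 128).
#' @param weight_decay decoupled weight decay (default 1e-4).
#' @param clipnorm global gradient-norm clip (default 1.0).
#' @param augment apply random joint flips per drawn pair (default TRUE).
#' @param ema track an exponential moving average of the weights and use
#'   it for sampling after training (default FALSE).
#' @param ema_decay EMA decay per iteration (default 0.999).
#' @param ema_start iteration at which EMA tracking begins (default half
#'   the run); early-training weights are too far from convergence to be
#'   worth averaging in short runs.
#' @param gamma_mode `"discrete"` draws t uniformly in 1..T and uses
#'   \eqn{\gamma_t}; `"continuous"` draws \eqn{\gamma} uniformly in
#'   \eqn{[\gamma_t, \gamma_{t-1}]} after drawing t (SR3-style).
#' @param lr_schedule `"constant"` (default) or `"cosine"`: cosine decay
#'   of the learning rate to zero over the run after a 5% linear warmup.
#' @param checkpoint_every iterations between checkpoints (0 = none).
#' @param checkpoint_dir directory for checkpoints.
#' @param seed integer seed for the training randomness.
#' @param verbose print progress every `verbose` iterations (0 = silent).
#' @return object of class `perfdiff_control`.
#' @export
perfdiff_control <- function(iterations = 50000L, learning_rate = 3e-5,
                             batch_size = 128L, weight_decay = 1e-4,
                             clipnorm = 1.0, augment = TRUE,
                             ema = FALSE, ema_decay = 0.999, ema_start = NULL,
                             gamma_mode = c("discrete", "continuous"),
                             lr_schedule = c("constant", "cosine"),
                             checkpoint_every = 0L, checkpoint_dir = tempdir(),
                             seed = 1L, verbose = 0L) {
  gamma_mode <- match.arg(gamma_mode)
  lr_schedule <- match.arg(lr_schedule)
  if (iterations < 1L) stop("iterations must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (is.null(ema_start)) ema_start <- as.integer(iterations %/% 2)
  structure(list(
    iterations = as.integer(iterations), learning_rate = learning_rate,
    batch_size = as.integer(batch_size), weight_decay = weight_decay,
    clipnorm = clipnorm, augment = isTRUE(augment),
    ema = isTRUE(ema), ema_decay = ema_decay,
    ema_start = as.integer(ema_start), gamma_mode = gamma_mode,
    lr_schedule = lr_schedule,
    checkpoint_every = as.integer(checkpoint_every),
    checkpoint_dir = checkpoint_dir, seed = as.integer(seed),
    verbose = as.integer(verbose)
  ), class = "perfdiff_control")
}

#' Desk-scale preset
#'
#' A small configuration for CPU-scale experiments: 32 x 32 phantoms,
#' channels 16-32-64 with one residual block per level and no dropout,
#' T = 100 diffusion steps with a quadratic beta ramp (linear in
#' \eqn{\sqrt{\beta}}, so reverse steps concentrate at low noise where
#' residual sampling error forms) whose terminal signal level is near
#' zero (\eqn{\gamma_T \approx 7 \times 10^{-4}}), and 2000 training
#' iterations at batch 16 with learning rate 3e-4.
#'
#' @param seed integer seed propagated to the control block.
#' @return list with elements `unet`, `schedule`, `control`, `matrix_size`.
#' @export
desk_preset <- function(seed = 1L) {
  list(
    unet = unet_config(channels = c(16L, 32L, 64L), res_blocks = 1L,
                       dropout = 0.0),
    schedule = noise_schedule(T = 100L, beta_start = 1e-4, beta_end = 0.2,
                              kind = "quadratic"),
    control = perfdiff_control(iterations = 2000L, learning_rate = 3e-4,
                               batch_size = 16L, seed = seed),
    matrix_size = 32L
  )
}

# draw the training signal level: discrete gamma_t, or continuous in the
# [gamma_t, gamma_{t-1}] band
draw_gamma <- function(schedule, mode, n) {
  t <- sample.int(schedule$T, n, replace = TRUE)
  g <- schedule$gamma[t]
  if (mode == "continuous") {
    hi <- ifelse(t > 1L, schedule$gamma[pmax(t - 1L, 1L)], 1)
    g <- stats::runif(n, g, hi)
  }
  g
}

#' Fit a conditional diffusion super-resolution model
#'
#' The main fitting function. Trains the conditional U-Net noise predictor
#' on paired LR/HR perfusion frames by stochastic optimization of the L1
#' noise-prediction objective: at each step a batch of pairs is drawn
#' (optionally flip-augmented), each target is corrupted to a random
#' signal level via the closed-form forward marginal, and AdamW updates
#' the network to predict the injected noise.
#'
#' @param dataset an `sr_dataset` from [assemble_dataset()], or a plain
#'   list of `lrhr_pair` objects used as the training pool.
#' @param unet a [unet_config()].
#' @param schedule a [noise_schedule()].
#' @param control a [perfdiff_control()].
#' @return object of class `perfdiff`: the trained `denoiser`, the
#'   configurations, and the per-iteration loss history.
#' @seealso [predict.perfdiff()], [infer_series()], [desk_preset()]
#' @export
perfdiff <- function(dataset, unet = unet_config(),
                     schedule = noise_schedule(),
                     control = perfdiff_control()) {
  pairs <- if (inherits(dataset, "sr_dataset")) dataset$train else dataset
  if (!length(pairs)) stop("no training pairs")
  stopifnot(inherits(pairs[[1]], "lrhr_pair"))
  d <- dim(pairs[[1]]$x)
  check_unet_input(unet, d[1], d[2])
  model <- build_denoiser(unet, seed = control$seed)
  history <- numeric(control$iterations)
  with_local_seed(control$seed, {
    for (it in seq_len(control$iterations)) {
      history[it] <- perfdiff_iteration(model, pairs, schedule, control,
                                        lr_now(control, it))
      if (control$ema && it >= control$ema_start)
        .unet_ema_update(model$ptr, control$ema_decay)
      if (control$verbose > 0 && it %% control$verbose == 0)
        message(sprintf("iter %d/%d  loss %.4f", it, control$iterations,
                        mean(history[max(1, it - 99):it])))
      if (control$checkpoint_every > 0 && it %% control$checkpoint_every == 0)
        save_checkpoint(
          file.path(control$checkpoint_dir, sprintf("checkpoint_%06d.rds", it)),
          model, unet, schedule, control, history[seq_len(it)], pairs = pairs)
    }
  })
  # sample from the averaged weights when EMA is on
  if (isTRUE(control$ema)) .unet_swap_ema(model$ptr)
  structure(list(
    model = model, unet = unet, schedule = schedule, control = control,
    loss_history = history, n_pairs = length(pairs)
  ), class = "perfdiff")
}

# learning rate at iteration it under the configured schedule
lr_now <- function(control, it) {
  base <- control$learning_rate
  if (is.null(control$lr_schedule) || control$lr_schedule == "constant")
    return(base)
  warm <- max(1L, as.integer(0.05 * control$iterations))
  if (it <= warm) return(base * it / warm)
  frac <- (it - warm) / max(1L, control$iterations - warm)
  base * 0.5 * (1 + cos(pi * frac))
}

# one optimization step (uses the current RNG stream)
perfdiff_iteration <- function(model, pairs, schedule, control,
                               lr = control$learning_rate) {
  d <- dim(pairs[[1]]$x)
  B <- control$batch_size
  idx <- sample.int(length(pairs), B, replace = length(pairs) < B)
  x <- array(0, c(d[1], d[2], B))
  y0 <- array(0, c(d[1], d[2], B))
  for (k in seq_len(B)) {
    p <- pairs[[idx[k]]]
    if (control$augment) p <- augment_pair(p)
    x[, , k] <- p$x
    y0[, , k] <- p$y0
  }
  g <- draw_gamma(schedule, control$gamma_mode, B)
  eps <- array(stats::rnorm(length(y0)), dim = dim(y0))
  gk <- rep(g, each = d[1] * d[2])
  y_t <- array(sqrt(gk) * y0 + sqrt(1 - gk) * eps, dim = dim(y0))
  denoiser_train_step(model, x, y_t, eps, g,
                      lr = lr,
                      weight_decay = control$weight_decay,
                      clipnorm = control$clipnorm)
}

#' Resume training from a checkpoint
#'
#' Continues a run saved by the in-loop checkpointing bit-exactly: weights,
#' optimizer moments, the network's internal RNG and the R-side RNG stream
#' are all restored before further iterations.
#'
#' @param path checkpoint file written during [perfdiff()] training.
#' @param extra_iterations additional optimizer steps to run.
#' @return a `perfdiff` object continuing the checkpointed run.
#' @export
resume_training <- function(path, extra_iterations) {
  ck <- readRDS(path)
  model <- build_denoiser(ck$unet, seed = ck$control$seed)
  set_denoiser_weights(model, ck$weights)
  .unet_set_state(model$ptr, ck$opt_state)
  history <- ck$history
  assign(".Random.seed", ck$r_rng, envir = globalenv())
  done <- length(ck$history)
  for (it in seq_len(extra_iterations))
    history <- c(history, perfdiff_iteration(model, ck$pairs, ck$schedule,
                                             ck$control,
                                             lr_now(ck$control, done + it)))
  structure(list(
    model = model, unet = ck$unet, schedule = ck$schedule,
    control = ck$control, loss_history = history, n_pairs = length(ck$pairs)
  ), class = "perfdiff")
}

save_checkpoint <- function(path, model, unet, schedule, control, history,
                            pairs = NULL) {
  saveRDS(list(
    weights = denoiser_weights(model), opt_state = .unet_get_state(model$ptr),
    unet = unet, schedule = schedule, control = control, history = history,
    r_rng = get(".Random.seed", globalenv()), pairs = pairs
  ), path)
  invisible(path)
}

#' @export
print.perfdiff <- function(x, ...) {
  cat("Conditional diffusion super-resolution model\n")
  print(x$model)
  print(x$schedule)
  n <- length(x$loss_history)
  cat(sprintf("  trained %d iterations on %d pairs; loss %.4f -> %.4f (last-100 mean)\n",
              n, x$n_pairs, mean(x$loss_history[seq_len(min(100, n))]),
              mean(x$loss_history[max(1, n - 99):n])))
  invisible(x)
}

#' @export
summary.perfdiff <- function(object, ...) {
  h <- object$loss_history
  out <- list(
    n_params = object$model$n_params,
    iterations = length(h),
    schedule_T = object$schedule$T,
    loss_initial = mean(h[seq_len(min(100, length(h)))]),
    loss_final = mean(h[max(1, length(h) - 99):length(h)]),
    control = object$control
  )
  class(out) <- "summary.perfdiff"
  out
}

#' @export
print.summary.perfdiff <- function(x, ...) {
  cat(sprintf("perfdiff model: %.1fM parameters, T = %d, %d iterations\n",
              x$n_params / 1e6, x$schedule_T, x$iterations))
  cat(sprintf("  smoothed loss: %.4f (first 100) -> %.4f (last 100)\n",
              x$loss_initial, x$loss_final))
  invisible(x)
}

#' @export
plot.perfdiff <- function(x, ...) {
  h <- x$loss_history
  graphics::plot(h, type = "l", col = "grey70", xlab = "iteration",
                 ylab = "L1 noise-prediction loss", ...)
  if (length(h) >= 50)
    graphics::lines(stats::filter(h, rep(1 / 50, 50)), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Super-resolve images with a fitted model
#'
#' `predict()` maps normalized LR frames to super-resolved frames by full
#' reverse-diffusion sampling; [infer_series()] is the end-to-end pipeline
#' for a `perfusion_series` (normalization, frame-by-frame sampling in one
#' batch, denormalization; frame times pass through untouched, so temporal
#' fidelity is preserved by construction).
#'
#' @param object a fitted `perfdiff` model.
#' @param newdata LR image (matrix), batch (rows x cols x B), or
#'   `perfusion_series`, on the normalized \[-1, 1\] scale unless it is a
#'   series (then normalization is handled internally).
#' @param seed integer seed for the sampling noise.
#' @param ... unused.
#' @return super-resolved data of the same form as `newdata`.
#' @export
predict.perfdiff <- function(object, newdata, seed = 1L, ...) {
  if (inherits(newdata, "perfusion_series"))
    return(infer_series(object, newdata, seed = seed))
  sample_sr(newdata, object$model, object$schedule, seed = seed)
}

#' Draw posterior super-resolution samples
#'
#' The sampler is stochastic: repeated draws conditioned on the same LR
#' frame explore the model's posterior over high-resolution images.
#'
#' @param object a fitted `perfdiff` model.
#' @param nsim number of draws.
#' @param seed integer seed; draw i uses `seed + i - 1`.
#' @param x_lr one normalized LR frame (matrix).
#' @param ... unused.
#' @return list of `nsim` sampled frames.
#' @export
simulate.perfdiff <- function(object, nsim = 1, seed = 1L, x_lr, ...) {
  lapply(seq_len(nsim), function(i)
    sample_sr(x_lr, object$model, object$schedule, seed = seed + i - 1L))
}

#' @rdname predict.perfdiff
#' @param fit a fitted `perfdiff` model.
#' @param lr_series a `perfusion_series` of low-resolution frames (a.u.).
#' @param norm_max intensity mapped to +1 during normalization; defaults
#'   to the series maximum.
#' @export
infer_series <- function(fit, lr_series, seed = 1L, norm_max = NULL) {
  stopifnot(inherits(fit, "perfdiff"), inherits(lr_series, "perfusion_series"))
  fr <- lr_series$frames
  nf <- dim(fr)[1]
  if (is.null(norm_max)) norm_max <- max(fr)
  x <- array(0, c(dim(fr)[2], dim(fr)[3], nf))
  for (i in seq_len(nf)) x[, , i] <- normalize_to_unit(fr[i, , ], norm_max)
  check_unet_input(fit$unet, dim(x)[1], dim(x)[2])
  y <- sample_sr(x, fit$model, fit$schedule, seed = seed)
  out <- fr
  for (i in seq_len(nf)) out[i, , ] <- denormalize_from_unit(y[, , i], norm_max)
  res <- lr_series
  res$frames <- out
  res$normalization <- list(type = "none",
                            note = "super-resolved; intensities on the input scale")
  res
}
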