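make_series_list <- function(n_subjects, n_frames = 8L) {
  lapply(seq_len(n_subjects), function(s)
    generate_series(fast_phantom(n_frames = n_frames, seed = s,
                                 noise_sigma = 0.02)))
}

test_that("dataset assembly splits by subject and counts frames correctly", {
  series <- make_series_list(10L)
  ds <- assemble_dataset(series, split = 0.8, seed = 3L)
  expect_length(ds$split_subjects$train, 8L)
  expect_length(ds$split_subjects$test, 2L)
  expect_length(intersect(ds$split_subjects$train, ds$split_subjects$test), 0L)
  # every frame of every training subject becomes one pair
  expect_length(ds$train, 8L * 8L)
  expect_length(ds$test, 2L * 8L)
  prov <- attr(ds$train, "provenance")
  expect_setequal(unique(prov[, "subject"]), ds$split_subjects$train)

  # per-pair fractions drawn inside the configured range
  fr <- vapply(ds$train, function(p) p$fraction, numeric(1))
  expect_true(all(fr >= 0.30 & fr <= 0.50))
  expect_gt(max(fr) - min(fr), 0.1)     # the draw actually varies

  # reproducibility of split and draws
  ds2 <- assemble_dataset(series, split = 0.8, seed = 3L)
  expect_identical(ds$split_subjects, ds2$split_subjects)
  expect_identical(vapply(ds2$train, function(p) p$fraction, numeric(1)), fr)

  expect_error(assemble_dataset(series[1], split = 0.8), "at least 2")
})

test_that("subject-level split exclusivity holds under many seeds", {
  series <- make_series_list(5L, n_frames = 6L)
  for (seed in 1:10) {
    ds <- assemble_dataset(series, split = 0.6, seed = seed)
    expect_length(intersect(ds$split_subjects$train, ds$split_subjects$test), 0L)
    expect_length(ds$split_subjects$train, 3L)
  }
})

test_that("short training runs are finite, loss-decreasing and reproducible", {
  series <- make_series_list(3L, n_frames = 8L)
  ds <- assemble_dataset(series, split = 2 / 3, crop_size = 16L, seed = 1L)
  cfg <- unet_config(channels = c(8L, 16L), res_blocks = 1L, dropout = 0.1,
                     emb_dim = 32L)
  sched <- noise_schedule(T = 50L, beta_start = 1e-3, beta_end = 0.2)
  ctl <- perfdiff_control(iterations = 120L, learning_rate = 1e-3,
                          batch_size = 8L, seed = 9L)
  fit <- perfdiff(ds, unet = cfg, schedule = sched, control = ctl)
  expect_s3_class(fit, "perfdiff")
  expect_true(all(is.finite(fit$loss_history)))
  expect_lt(mean(tail(fit$loss_history, 20)), mean(head(fit$loss_history, 20)))

  fit2 <- perfdiff(ds, unet = cfg, schedule = sched, control = ctl)
  expect_equal(fit$loss_history, fit2$loss_history, tolerance = 1e-10)
})

test_that("training resumes bit-exactly from a checkpoint", {
  series <- make_series_list(2L, n_frames = 6L)
  ds <- assemble_dataset(series, split = 0.5, crop_size = 16L, seed = 2L)
  cfg <- unet_config(channels = c(8L, 16L), res_blocks = 1L, dropout = 0.1,
                     emb_dim = 32L)
  sched <- noise_schedule(T = 50L, beta_start = 1e-3, beta_end = 0.2)
  ckdir <- tempfile(); dir.create(ckdir)
  ctl <- perfdiff_control(iterations = 40L, learning_rate = 1e-3,
                          batch_size = 4L, seed = 5L,
                          checkpoint_every = 20L, checkpoint_dir = ckdir)
  fit <- perfdiff(ds, unet = cfg, schedule = sched, control = ctl)
  resumed <- resume_training(file.path(ckdir, "checkpoint_000020.rds"),
                             extra_iterations = 20L)
  expect_equal(resumed$loss_history[21:40], fit$loss_history[21:40],
               tolerance = 1e-12)
  expect_equal(denoiser_weights(resumed$model), denoiser_weights(fit$model),
               tolerance = 1e-12)
})

test_that("series inference preserves frame times, scale and determinism", {
  series <- make_series_list(2L, n_frames = 10L)
  ds <- assemble_dataset(series, split = 0.5, crop_size = 16L, seed = 4L)
  cfg <- unet_config(channels = c(8L, 16L), res_blocks = 1L, dropout = 0,
                     emb_dim = 32L)
  sched <- noise_schedule(T = 20L, beta_start = 1e-3, beta_end = 0.3)
  ctl <- perfdiff_control(iterations = 30L, learning_rate = 1e-3,
                          batch_size = 4L, seed = 6L)
  fit <- perfdiff(ds, unet = cfg, schedule = sched, control = ctl)

  lr <- series[[2]]
  lr$frames <- lr$frames[, 9:24, 9:24]    # 16x16 crop for the tiny net
  for (i in 1:10) lr$frames[i, , ] <- perfdiff:::degrade_image(lr$frames[i, , ], 0.35)
  sr <- infer_series(fit, lr, seed = 11L)
  expect_equal(dim(sr$frames), dim(lr$frames))
  expect_identical(sr$frame_times, lr$frame_times)
  expect_true(all(sr$frames >= 0))        # back on the data scale
  sr2 <- infer_series(fit, lr, seed = 11L)
  expect_identical(sr$frames, sr2$frames)
  sr3 <- infer_series(fit, lr, seed = 12L)
  expect_false(identical(sr$frames, sr3$frames))
})

test_that("configuration validation rejects nonsense", {
  expect_error(perfdiff_control(iterations = 0), "iterations")
  expect_error(perfdiff_control(learning_rate = -1), "learning_rate")
  expect_error(perfdiff_control(batch_size = 0), "batch_size")
})
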