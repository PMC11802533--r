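test_that("nRMSE follows its closed forms and brute-force oracle", {
  set.seed(1)
  ref <- matrix(runif(64, 0, 2), 8, 8)
  expect_equal(nrmse(ref, ref), 0)
  # constant offset c against reference range r gives c / r
  r <- max(ref) - min(ref)
  expect_equal(nrmse(ref + 0.1, ref), 0.1 / r, tolerance = 1e-12)
  # scale covariance: joint rescaling leaves nRMSE unchanged
  pred <- ref + matrix(rnorm(64, 0, 0.1), 8, 8)
  expect_equal(nrmse(3.7 * pred, 3.7 * ref), nrmse(pred, ref), tolerance = 1e-12)
  expect_equal(nrmse(pred, ref), oracle_metrics(pred, ref)$nrmse, tolerance = 1e-12)
  expect_error(nrmse(ref, matrix(1, 8, 8)), "dynamic range")
})

test_that("PSNR follows the 255-peak formula exactly", {
  # an MSE of 1 on the 0..255 scale: 10*log10(255^2) ~ 48.13 dB
  ref <- matrix(c(0, 255), 16, 16)
  pred <- ref + 1                    # rescaling is anchored on the reference
  expect_equal(psnr(pred, ref), 10 * log10(255^2), tolerance = 1e-9)
  # halving the MSE adds exactly 10*log10(2) dB
  set.seed(2)
  noise <- matrix(rnorm(256), 16, 16)
  p1 <- psnr(ref + noise, ref)
  p2 <- psnr(ref + noise / sqrt(2), ref)
  expect_equal(p2 - p1, 10 * log10(2), tolerance = 1e-9)
  # identical images return the documented cap
  expect_equal(psnr(ref, ref), 200)
})

test_that("SSIM is 1 at identity, symmetric, negative for anti-correlation", {
  set.seed(3)
  ref <- matrix(runif(256), 16, 16)
  expect_equal(as.numeric(ssim(ref, ref)), 1, tolerance = 1e-9)
  pred <- ref + matrix(rnorm(256, 0, 0.2), 16, 16)
  expect_equal(as.numeric(ssim(pred, ref)), as.numeric(ssim(ref, pred)),
               tolerance = 1e-12)
  # anti-correlated pair with matched means and tiny stabilizers
  anti <- -ref + mean(ref) * 2
  expect_lt(as.numeric(ssim(anti, ref, c1 = 1e-8, c2 = 1e-8)), 0)
  # sliding-window variant stays in range and flags its mode
  s <- ssim(pred, ref, window = "sliding")
  expect_true(as.numeric(s) >= -1 && as.numeric(s) <= 1)
  expect_equal(attr(s, "window"), "sliding")
  expect_error(ssim(pred, ref, window = "sliding", window_size = 99L), "window")
})

test_that("all three metrics match independent brute-force evaluation on random pairs", {
  set.seed(4)
  for (i in 1:100) {
    ref <- matrix(runif(256, 0, 10), 16, 16)
    pred <- ref + matrix(rnorm(256, 0, 0.5), 16, 16)
    o <- oracle_metrics(pred, ref)
    expect_lt(abs(nrmse(pred, ref) - o$nrmse), 1e-10)
    expect_lt(abs(psnr(pred, ref) - o$psnr), 1e-10)
    expect_lt(abs(as.numeric(ssim(pred, ref)) - o$ssim), 1e-10)
  }
})

test_that("zero-padded LR error shrinks as more phase lines are retained", {
  ser <- generate_series(tiny_phantom(noise_sigma = 0))
  hr <- ser$frames[20, , ]
  errs <- sapply(c(0.30, 0.40, 0.50, 1.0), function(f)
    nrmse(perfdiff:::degrade_image(hr, f), hr))
  expect_true(all(diff(errs) <= 1e-12))
  expect_equal(errs[4], 0, tolerance = 1e-10)
})

test_that("signal-time curves and x-t profiles extract what was rendered", {
  ser <- generate_series(tiny_phantom(noise_sigma = 0))
  cur <- signal_time_curves(ser)
  expect_equal(dim(cur), c(30L, 3L))
  # constant series: constant curves
  flat <- ser
  flat$frames[] <- 2.5
  expect_true(all(signal_time_curves(flat) == 2.5))
  # missing masks is an error
  nom <- ser; nom$roi_masks <- NULL
  expect_error(signal_time_curves(nom), "masks")

  # x-t profile: lossless extraction, constant over time for a static series
  prof <- xt_profile(ser, 16L, axis = 1L)
  expect_equal(dim(prof), c(32L, 30L))
  expect_equal(prof[, 7], ser$frames[7, 16, ])
  prof_flat <- xt_profile(flat, 16L)
  expect_true(all(prof_flat == 2.5))
  expect_error(xt_profile(ser, 99L), "out of bounds")

  # temporal gradient through the LV line is larger during inflow than baseline
  d <- abs(diff(t(xt_profile(ser, 16L))))        # frames-1 x space
  inflow <- mean(d[12:20, ])                     # around LV arrival
  baseline <- mean(d[1:4, ])
  expect_gt(inflow, baseline)
})

test_that("paired comparisons behave at their degenerate and extreme cases", {
  a <- c(1, 2, 3, 4, 5)
  r <- compare_methods(a, a, "paired_t")
  expect_true(r$degenerate)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # constant positive difference: extreme one-sided Wilcoxon evidence
  set.seed(5)
  b <- rnorm(10)
  w <- compare_methods(b + 1, b, "wilcoxon")
  expect_true(w$significant)
  tt <- compare_methods(b + 1, b, "paired_t")
  expect_true(tt$degenerate)          # zero-variance difference is flagged
  expect_error(compare_methods(1:3, 1:4), "equal length")
})

test_that("the paired t-test holds its nominal type-I error under the null", {
  set.seed(6)
  n_rep <- 1000L; n <- 20L
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    a <- rnorm(n); b <- rnorm(n)      # identically distributed methods
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("nominal acceleration reproduces the protocol arithmetic", {
  expect_equal(nominal_acceleration(2, 0.35), 2 / 0.35)
  expect_gte(nominal_acceleration(2, 0.35), 5.7)
  expect_gte(nominal_acceleration(3, 0.35), 8.5)
  expect_equal(nominal_acceleration(1, 1.0), 1.0)
  expect_error(nominal_acceleration(0, 0.35), "grappa")
  expect_error(nominal_acceleration(2, 0), "phase_fraction")
})

test_that("metric reports aggregate frames and compare methods", {
  ser <- generate_series(fast_phantom(n_frames = 8L, noise_sigma = 0))
  lr <- ser
  for (i in 1:8) lr$frames[i, , ] <- perfdiff:::degrade_image(ser$frames[i, , ], 0.35)
  mid <- ser
  for (i in 1:8) mid$frames[i, , ] <- perfdiff:::degrade_image(ser$frames[i, , ], 0.7)
  rep <- metric_report(mid, ser, baseline = lr)
  expect_s3_class(rep, "metric_report")
  expect_equal(nrow(rep$per_frame), 8L)
  # the milder degradation wins on every aggregate
  expect_lt(rep$aggregate["nrmse_mean"], rep$baseline_aggregate["nrmse_mean"])
  expect_gt(rep$aggregate["psnr_mean"], rep$baseline_aggregate["psnr_mean"])
  expect_true(is.finite(rep$tests$psnr$p_value))
  f <- tempfile(fileext = ".json")
  write_metric_report(rep, f)
  expect_true(jsonlite::validate(paste(readLines(f, warn = FALSE), collapse = "")))
})
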