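test_that("k-space round trip is the identity and DC carries all constant energy", {
  set.seed(1)
  img <- matrix(runif(32 * 32), 32, 32)
  k <- to_kspace(img)
  expect_lt(max(abs(from_kspace(k) - img)), 1e-10 * max(img))

  # constant image: all energy at the centered DC index
  cimg <- matrix(3.5, 16, 16)
  kc <- unclass(to_kspace(cimg))
  expect_equal(Mod(kc[9, 9]), 16^2 * 3.5, tolerance = 1e-8)
  kc[9, 9] <- 0
  expect_lt(max(Mod(kc)), 1e-8)

  # all-zero grid maps to an all-zero image
  expect_equal(from_kspace(to_kspace(matrix(0, 8, 8))), matrix(0, 8, 8))
  expect_error(to_kspace(array(1, c(2, 2, 2))), "2-D")
})

test_that("forward transform matches a brute-force DFT on an 8x8 grid", {
  set.seed(2)
  img <- matrix(rnorm(64), 8, 8)
  expect_lt(max(Mod(unclass(to_kspace(img)) - dft2_centered(img))), 1e-9)

  # pure horizontal cosine of integer frequency: exactly two lines on the
  # phase-encode (row) axis
  kf <- 3
  cosimg <- matrix(rep(cos(2 * pi * kf * (0:7) / 8), 8), 8, 8)
  kc <- unclass(to_kspace(cosimg))
  mag <- Mod(kc)
  nz <- which(mag > 1e-8, arr.ind = TRUE)
  dc <- 5  # centered DC index for N = 8
  expect_equal(nrow(nz), 2L)
  expect_setequal(nz[, "row"], c(dc - kf, dc + kf))
  expect_true(all(nz[, "col"] == dc))
})

test_that("phase-line truncation keeps exactly round(fraction * N_pe) central lines", {
  set.seed(3)
  img <- matrix(rnorm(160 * 160), 160, 160)
  k <- to_kspace(img)
  kt <- truncate_phase_lines(k, 0.35)
  nonzero_rows <- which(rowSums(Mod(unclass(kt))) > 0)
  expect_length(nonzero_rows, 56L)                   # round(0.35 * 160)
  expect_true(all(diff(nonzero_rows) == 1L))         # contiguous
  dc <- 81L
  expect_true(dc %in% nonzero_rows)                  # DC retained
  # even count: extra line on the lower-index side
  expect_equal(dc - min(nonzero_rows), 28L)
  expect_equal(max(nonzero_rows) - dc, 27L)
  # readout axis untouched inside the band
  expect_equal(unclass(kt)[dc, ], unclass(k)[dc, ])

  # full retention is the identity; fraction validated
  expect_equal(unclass(truncate_phase_lines(k, 1.0)), unclass(k))
  expect_error(truncate_phase_lines(k, 0), "fraction")
  expect_error(truncate_phase_lines(k, 1.2), "fraction")
})

test_that("truncated impulse equals the closed-form Dirichlet kernel", {
  N <- 32; r0 <- 17; c0 <- 9
  img <- matrix(0, N, N); img[r0, c0] <- 1
  fraction <- 0.35
  lr <- perfdiff:::degrade_image(img, fraction)

  n_keep <- round(fraction * N)                      # 11 lines
  dc <- floor(N / 2) + 1
  freqs <- (dc - n_keep %/% 2):(dc - n_keep %/% 2 + n_keep - 1) - dc
  dirichlet <- function(d) Mod(sum(exp(2i * pi * freqs * d / N))) / N
  expected <- matrix(0, N, N)
  for (i in seq_len(N)) expected[i, c0] <- dirichlet(i - r0)
  expect_lt(max(abs(lr - expected)), 1e-8)
})

test_that("k-space truncation is idempotent, energy-contracting and linear", {
  set.seed(4)
  img1 <- matrix(rnorm(32 * 32), 32, 32)
  img2 <- matrix(rnorm(32 * 32), 32, 32)
  k1 <- to_kspace(img1)

  kt <- truncate_phase_lines(k1, 0.4)
  expect_equal(unclass(truncate_phase_lines(kt, 0.4)), unclass(kt))

  e_before <- sum(Mod(unclass(k1))^2)
  e_after <- sum(Mod(unclass(kt))^2)
  expect_lt(e_after, e_before)
  expect_equal(sum(Mod(unclass(truncate_phase_lines(k1, 1)))^2), e_before)

  # linearity before the magnitude step
  a <- 1.7; b <- -0.6
  mix <- unclass(truncate_phase_lines(to_kspace(a * img1 + b * img2), 0.4))
  sep <- a * unclass(truncate_phase_lines(to_kspace(img1), 0.4)) +
         b * unclass(truncate_phase_lines(to_kspace(img2), 0.4))
  expect_lt(max(Mod(mix - sep)), 1e-8)
})

test_that("round-trip identity at fraction 1 holds across 100 random images", {
  set.seed(5)
  for (i in 1:100) {
    img <- matrix(runif(16 * 16), 16, 16)
    expect_lt(max(abs(perfdiff:::degrade_image(img, 1) - img)), 1e-10)
  }
})

test_that("LR/HR pairs share crop, normalization and degeneracy properties", {
  ser <- generate_series(tiny_phantom(noise_sigma = 0))
  hr <- ser$frames[20, , ]

  # degenerate degradation: x equals y0
  p1 <- make_lr_hr_pair(hr, fraction = 1, crop_size = 32L)
  expect_lt(max(abs(p1$x - p1$y0)), 1e-9)

  p <- make_lr_hr_pair(hr, fraction = 0.35, crop_size = 32L)
  expect_equal(dim(p$x), dim(p$y0))
  expect_true(all(is.finite(p$x)) && all(is.finite(p$y0)))
  expect_true(max(p$y0) <= 1 + 1e-12 && min(p$y0) >= -1 - 1e-12)
  # lossy degradation
  expect_gt(nrmse(p$x, p$y0), 0)
  expect_lt(as.numeric(ssim(p$x, p$y0)), 1)

  # ringing is confined to the phase-encode axis: columns of the LR image
  # change, but within k-space the readout direction of retained lines is
  # untouched (checked in the truncation test); here check blur anisotropy
  lr_full <- perfdiff:::degrade_image(hr, 0.35)
  col_change <- mean(abs(lr_full - hr)[, 16])
  expect_gt(col_change, 0)

  expect_error(make_lr_hr_pair(hr, 0.35, crop_center = c(2, 2), crop_size = 32L),
               "out of bounds")
  expect_error(make_lr_hr_pair(hr[1:10, ], 0.35, crop_size = 32L), "smaller")
})

test_that("degrading then sub-sampling matches direct Dirichlet convolution", {
  # the LR image is (before magnitude) the HR image convolved along the
  # phase-encode axis with the periodic Dirichlet kernel
  set.seed(6)
  N <- 16
  img <- matrix(runif(N * N), N, N)
  fraction <- 0.5
  lr <- perfdiff:::degrade_image(img, fraction)

  n_keep <- round(fraction * N)
  dc <- floor(N / 2) + 1
  freqs <- (dc - n_keep %/% 2):(dc - n_keep %/% 2 + n_keep - 1) - dc
  kern <- sapply(0:(N - 1), function(d) sum(exp(2i * pi * freqs * d / N))) / N
  conv <- matrix(0 + 0i, N, N)
  for (i in seq_len(N)) for (j in seq_len(N))
    conv[i, j] <- sum(img[, j] * kern[((i - seq_len(N)) %% N) + 1])
  expect_lt(max(abs(lr - Mod(conv))), 1e-10)
})

test_that("joint flips are involutions, synchronized, and occur at rate 1/2", {
  ser <- generate_series(tiny_phantom(noise_sigma = 0))
  p <- make_lr_hr_pair(ser$frames[15, , ], 0.4, crop_size = 32L)
  # marker pixel to track orientation jointly
  p$x[1, 1] <- 99; p$y0[1, 1] <- 99

  # same draws twice = identity (flips are involutions)
  p2 <- augment_pair(augment_pair(p, seed = 8L), seed = 8L)
  expect_identical(p2$x, p$x)
  expect_identical(p2$y0, p$y0)

  nv <- 0L; nh <- 0L; n <- 10000L
  set.seed(123)
  sync_ok <- TRUE
  for (i in seq_len(n)) {
    q <- augment_pair(p)
    # marker must stay synchronized between x and y0
    sync_ok <- sync_ok && identical(which(q$x == 99), which(q$y0 == 99))
    flipped_v <- q$x[32, 1] == 99 || q$x[32, 32] == 99
    flipped_h <- q$x[1, 32] == 99 || q$x[32, 32] == 99
    nv <- nv + flipped_v; nh <- nh + flipped_h
  }
  expect_true(sync_ok)
  se3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(nv / n - 0.5), se3)
  expect_lt(abs(nh / n - 0.5), se3)
})
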