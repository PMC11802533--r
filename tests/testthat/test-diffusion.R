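test_that("noise schedules satisfy their defining identities", {
  s <- noise_schedule()                     # full-scale default
  expect_equal(s$T, 2000L)
  expect_true(all(s$alpha > 0 & s$alpha < 1))
  expect_equal(s$sigma2, 1 - s$alpha)
  expect_true(all(diff(s$gamma) < 0))       # strictly decreasing
  expect_true(all(s$gamma > 0))
  expect_lt(s$gamma[s$T], 1e-3)             # terminal state near pure noise

  # gamma is the cumulative product (independent loop)
  s2 <- noise_schedule(T = 10L, beta_start = 0.01, beta_end = 0.01)
  g <- 1
  for (t in 1:10) g <- g * 0.99
  expect_equal(s2$gamma[10], g, tolerance = 1e-12)
  expect_equal(s2$gamma[10], 0.99^10, tolerance = 1e-12)

  # near-zero beta limit: gamma stays at 1, forward process is the identity
  s0 <- noise_schedule(T = 50L, beta_start = 1e-12, beta_end = 1e-12)
  expect_gt(s0$gamma[50], 1 - 1e-9)
  y <- matrix(rnorm(16), 4, 4)
  expect_equal(forward_marginal(y, 50L, matrix(0, 4, 4), s0), y, tolerance = 1e-9)

  expect_error(noise_schedule(beta_start = 0), "beta")
  expect_error(noise_schedule(beta_start = 0.5, beta_end = 0.1), "beta")
})

test_that("forward step and marginal obey their closed forms", {
  s <- noise_schedule(T = 100L, beta_start = 1e-4, beta_end = 0.2)
  y0 <- matrix(seq(-1, 1, length.out = 64), 8, 8)
  z <- matrix(rnorm(64), 8, 8)

  expect_equal(forward_step(y0, 10L, s, z = 0 * z), sqrt(s$alpha[10]) * y0)
  expect_equal(forward_step(0 * y0, 10L, s, z = z), sqrt(1 - s$alpha[10]) * z)

  eps <- matrix(rnorm(64), 8, 8)
  yt <- forward_marginal(y0, 40L, eps, s)
  expect_equal(yt, sqrt(s$gamma[40]) * y0 + sqrt(1 - s$gamma[40]) * eps)
  # algebraic inverse recovers y0
  expect_equal((yt - sqrt(1 - s$gamma[40]) * eps) / sqrt(s$gamma[40]), y0,
               tolerance = 1e-10)
  # at t = T the state is essentially the injected noise
  yT <- forward_marginal(y0, s$T, eps, s)
  expect_lt(sqrt(sum((yT - eps)^2)) / sqrt(sum(eps^2)), 2 * sqrt(s$gamma[s$T]))

  expect_error(forward_marginal(y0, 40L, matrix(0, 2, 2), s), "shape")
  expect_error(forward_step(y0, 0L, s), "t must be")
  expect_error(forward_step(y0, 101L, s), "t must be")
})

# (the Monte-Carlo forward-kernel/marginal moment check lives in
# test-acceptance.R; it is not duplicated here)

test_that("a perfect denoiser inverts the diffusion exactly", {
  s <- noise_schedule(T = 100L, beta_start = 1e-4, beta_end = 0.2)
  set.seed(12)
  y0 <- matrix(runif(256, -1, 1), 16, 16)
  eps <- matrix(rnorm(256), 16, 16)
  y <- forward_marginal(y0, s$T, eps, s)
  for (t in seq.int(s$T, 1L)) {
    eps_t <- (y - sqrt(s$gamma[t]) * y0) / sqrt(1 - s$gamma[t])
    # the implied one-step estimate of y0 is exact at every step
    y0_hat <- (y - sqrt(1 - s$gamma[t]) * eps_t) / sqrt(s$gamma[t])
    expect_lt(max(abs(y0_hat - y0)), 1e-6)
    y <- reverse_step(y, t, eps_t, s, inject_noise = FALSE, clip_y0 = FALSE)
  }
  expect_lt(max(abs(y - y0)) / max(abs(y0)), 1e-4)
})

test_that("reverse step reduces to its closed forms and clips the y0 estimate", {
  s <- noise_schedule(T = 100L, beta_start = 1e-4, beta_end = 0.2)
  y <- matrix(rnorm(64), 8, 8)
  # zero predicted noise, no injection, no clipping: pure 1/sqrt(alpha) gain
  out <- reverse_step(y, 50L, 0 * y, s, inject_noise = FALSE, clip_y0 = FALSE)
  expect_equal(out, y / sqrt(s$alpha[50]))
  # determinism with a fixed injected draw
  z <- matrix(rnorm(64), 8, 8)
  o1 <- reverse_step(y, 50L, 0 * y, s, z = z, clip_y0 = FALSE)
  o2 <- reverse_step(y, 50L, 0 * y, s, z = z, clip_y0 = FALSE)
  expect_identical(o1, o2)
  # clipping caps the implied y0 at +/-1: with zero eps_hat the implied
  # y0 is y/sqrt(gamma); choose y large so clipping must bite
  big <- matrix(5, 8, 8)
  clipped <- reverse_step(big, 50L, 0 * big, s, inject_noise = FALSE, clip_y0 = TRUE)
  g <- s$gamma[50]; a <- s$alpha[50]
  eps_implied <- (big - sqrt(g) * 1) / sqrt(1 - g)   # y0 clipped to 1
  expect_equal(clipped, (big - (1 - a) / sqrt(1 - g) * eps_implied) / sqrt(a))
  expect_error(reverse_step(y, 0L, y, s), "t must be")
})

test_that("sampling with a zero model matches the closed-form linear recursion", {
  s <- noise_schedule(T = 50L, beta_start = 1e-3, beta_end = 0.1)
  x <- matrix(0, 8, 8)
  zero_model <- function(x_lr, y_t, g) 0 * y_t
  out <- sample_sr(x, zero_model, s, seed = 3L,
                   inject_noise = FALSE, clip_y0 = FALSE)
  yT <- perfdiff:::with_local_seed(3L, array(rnorm(64), c(8, 8)))
  expect_equal(out, yT / sqrt(s$gamma[s$T]), tolerance = 1e-10)
  # same seed, same draw
  out2 <- sample_sr(x, zero_model, s, seed = 3L,
                    inject_noise = FALSE, clip_y0 = FALSE)
  expect_identical(out, out2)
})

test_that("the L1 training objective measures noise-prediction error", {
  s <- noise_schedule(T = 10L, beta_start = 0.01, beta_end = 0.1)
  set.seed(13)
  x <- matrix(runif(64, -1, 1), 8, 8)
  y0 <- matrix(runif(64, -1, 1), 8, 8)
  eps <- matrix(rnorm(64), 8, 8)

  perfect <- function(x_lr, y_t, g) eps
  expect_equal(training_loss(perfect, x, y0, eps, 0.5), 0)
  offset <- function(x_lr, y_t, g) eps + 0.3
  expect_equal(training_loss(offset, x, y0, eps, 0.5), 0.3, tolerance = 1e-12)
  expect_error(training_loss(perfect, x, y0, eps, 1.5), "gamma")

  # invariance under joint flips for a flip-equivariant model
  flip <- function(m) m[rev(seq_len(nrow(m))), ]
  equivariant <- function(x_lr, y_t, g) 0.5 * x_lr + 0.1 * y_t
  l1 <- training_loss(equivariant, x, y0, eps, 0.7)
  l2 <- training_loss(equivariant, flip(x), flip(y0), flip(eps), 0.7)
  expect_equal(l1, l2, tolerance = 1e-12)
})
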