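# Shared tiny fixtures, built in code.

# smallest valid phantom at desk resolution
tiny_phantom <- function(n_frames = 30L, noise_sigma = 0.02, seed = 1L, ...) {
  phantom_config(matrix_size = 32L, n_frames = n_frames,
                 noise_sigma = noise_sigma, seed = seed, ...)
}

# phantom with compressed kinetics so short series still contain all peaks
fast_phantom <- function(n_frames = 12L, noise_sigma = 0.02, seed = 1L, ...) {
  phantom_config(
    matrix_size = 32L, n_frames = n_frames, noise_sigma = noise_sigma,
    bolus = list(
      rv  = list(onset = 1,   shape = 2, scale = 0.6, amplitude = 1.0,  baseline = 0.10),
      lv  = list(onset = 2,   shape = 2, scale = 0.7, amplitude = 0.95, baseline = 0.10),
      myo = list(onset = 3.2, shape = 2, scale = 0.9, amplitude = 0.45, baseline = 0.12)
    ),
    seed = seed, ...)
}

# minimal U-Net for shape/gradient tests (8x8 inputs)
tiny_unet <- function(dropout = 0) {
  unet_config(channels = c(4L, 8L), res_blocks = 1L, dropout = dropout,
              emb_dim = 16L)
}

# brute-force 2-D DFT with DC shifted to the center, independent of the
# package's fft-based path
dft2_centered <- function(img) {
  n <- nrow(img); m <- ncol(img)
  f1 <- seq_len(n) - (floor(n / 2) + 1)   # frequencies at shifted indices
  f2 <- seq_len(m) - (floor(m / 2) + 1)
  out <- matrix(0 + 0i, n, m)
  for (a in seq_len(n)) for (b in seq_len(m)) {
    s <- 0 + 0i
    for (i in seq_len(n)) for (j in seq_len(m))
      s <- s + img[i, j] * exp(-2i * pi * (f1[a] * (i - 1) / n + f2[b] * (j - 1) / m))
    out[a, b] <- s
  }
  out
}

# elementwise metric oracles (independent of the package implementations)
oracle_metrics <- function(pred, ref, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2) {
  lo <- min(ref); hi <- max(ref)
  s <- 255 / (hi - lo)
  a <- (pred - lo) * s
  b <- (ref - lo) * s
  n <- length(a)
  sq <- 0
  for (i in seq_len(n)) sq <- sq + (a[i] - b[i])^2
  mse <- sq / n
  mu_a <- sum(a) / n; mu_b <- sum(b) / n
  va <- 0; vb <- 0; cab <- 0
  for (i in seq_len(n)) {
    va <- va + (a[i] - mu_a)^2
    vb <- vb + (b[i] - mu_b)^2
    cab <- cab + (a[i] - mu_a) * (b[i] - mu_b)
  }
  va <- va / (n - 1); vb <- vb / (n - 1); cab <- cab / (n - 1)
  # SSIM uses the symmetric joint rescale (combined range to 0..255)
  lo2 <- min(c(pred, ref)); hi2 <- max(c(pred, ref))
  s2 <- 255 / (hi2 - lo2)
  a2 <- (pred - lo2) * s2; b2 <- (ref - lo2) * s2
  n2 <- length(a2)
  mu_a2 <- sum(a2) / n2; mu_b2 <- sum(b2) / n2
  va2 <- 0; vb2 <- 0; cab2 <- 0
  for (i in seq_len(n2)) {
    va2 <- va2 + (a2[i] - mu_a2)^2
    vb2 <- vb2 + (b2[i] - mu_b2)^2
    cab2 <- cab2 + (a2[i] - mu_a2) * (b2[i] - mu_b2)
  }
  va2 <- va2 / (n2 - 1); vb2 <- vb2 / (n2 - 1); cab2 <- cab2 / (n2 - 1)
  list(
    nrmse = sqrt(mse) / (max(b) - min(b)),
    psnr = 10 * log10(255^2 / mse),
    ssim = ((2 * mu_a2 * mu_b2 + c1) * (2 * cab2 + c2)) /
      ((mu_a2^2 + mu_b2^2 + c1) * (va2 + vb2 + c2))
  )
}
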