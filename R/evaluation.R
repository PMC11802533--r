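#' Image-quality metrics against a high-resolution reference
#'
#' All three metrics follow the conventions used for super-resolved
#' perfusion frames: before computation, both images are jointly rescaled
#' by one affine map chosen so the *reference* spans 0..255; nRMSE then
#' divides the RMSE by the reference dynamic range, PSNR uses the 255 peak,
#' and SSIM uses stabilizers c1 = (0.01*255)^2, c2 = (0.03*255)^2.
#'
#' @param pred evaluated image (super-resolved or zero-padded LR), matrix.
#' @param ref reference high-resolution image, same shape.
#' @name metrics
NULL

rescale_pair_255 <- function(pred, ref) {
  if (!all(dim(pred) == dim(ref))) stop("images must have identical shape")
  if (any(!is.finite(pred)) || any(!is.finite(ref))) stop("images must be finite")
  r <- range(ref)
  if (r[2] <= r[1]) stop("reference image has zero dynamic range")
  s <- 255 / (r[2] - r[1])
  list(pred = (pred - r[1]) * s, ref = (ref - r[1]) * s)
}

#' @describeIn metrics normalized root-mean-square error: RMSE divided by
#'   the reference dynamic range. Returned as a fraction; multiply by 100
#'   for percent. Invariant to joint affine rescaling of both images.
#' @export
nrmse <- function(pred, ref) {
  z <- rescale_pair_255(pred, ref)
  sqrt(mean((z$pred - z$ref)^2)) / (max(z$ref) - min(z$ref))
}

#' @describeIn metrics peak signal-to-noise ratio in dB on the 0..255
#'   convention, \eqn{10\log_{10}(255^2 / \mathrm{MSE})}. Identical images
#'   return the documented cap of 200 dB.
#' @param cap value returned for identical images (default 200 dB).
#' @export
psnr <- function(pred, ref, cap = 200) {
  z <- rescale_pair_255(pred, ref)
  mse <- mean((z$pred - z$ref)^2)
  if (mse == 0) return(cap)
  min(10 * log10(255^2 / mse), cap)
}

#' @describeIn metrics structural similarity. The default evaluates the
#'   SSIM formula once from global image statistics (means, variances,
#'   covariance over the whole frame); `window = "sliding"` instead
#'   averages a local SSIM map computed under an 11 x 11 Gaussian window
#'   (sigma 1.5), the common alternative convention. Unlike nRMSE/PSNR
#'   (whose formulas anchor on the reference), SSIM is symmetric in its
#'   arguments, so both images are rescaled by the joint map sending
#'   their combined range to 0..255. Reports which mode produced the
#'   value via the `"window"` attribute.
#' @param window `"global"` (default) or `"sliding"`.
#' @param c1,c2 stabilization constants (> 0).
#' @param window_size,window_sigma sliding-window size and Gaussian sigma.
#' @export
ssim <- function(pred, ref, window = c("global", "sliding"),
                 c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                 window_size = 11L, window_sigma = 1.5) {
  window <- match.arg(window)
  if (c1 <= 0 || c2 <= 0) stop("c1 and c2 must be positive")
  if (!all(dim(pred) == dim(ref))) stop("images must have identical shape")
  r <- range(c(pred, ref))
  if (r[2] <= r[1]) stop("images have zero joint dynamic range")
  s <- 255 / (r[2] - r[1])
  a <- (pred - r[1]) * s; b <- (ref - r[1]) * s
  val <- if (window == "global") {
    n <- length(a)
    mu_a <- mean(a); mu_b <- mean(b)
    va <- sum((a - mu_a)^2) / (n - 1)
    vb <- sum((b - mu_b)^2) / (n - 1)
    cab <- sum((a - mu_a) * (b - mu_b)) / (n - 1)
    ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  } else {
    if (window_size > min(dim(a))) stop("window larger than image")
    w <- gaussian_window(window_size, window_sigma)
    mu_a <- filter2_same(a, w); mu_b <- filter2_same(b, w)
    va  <- filter2_same(a * a, w) - mu_a^2
    vb  <- filter2_same(b * b, w) - mu_b^2
    cab <- filter2_same(a * b, w) - mu_a * mu_b
    mean(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
           ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
  }
  structure(val, window = window)
}

gaussian_window <- function(size, sigma) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'same' 2-D correlation with edge replication (padding by nearest pixel)
filter2_same <- function(img, w) {
  k <- nrow(w); half <- (k - 1) %/% 2
  n <- nrow(img); m <- ncol(img)
  ri <- pmin(pmax(seq(1 - half, n + half), 1), n)
  ci <- pmin(pmax(seq(1 - half, m + half), 1), m)
  pad <- img[ri, ci]
  out <- matrix(0, n, m)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    out <- out + w[i, j] * pad[(i - 1) + seq_len(n), (j - 1) + seq_len(m)]
  }
  out
}

#' ROI-mean signal-time curves
#'
#' One mean-intensity curve per ROI mask across the dynamic frames: the
#' standard first-pass readout whose shape encodes bolus arrival and
#' washout in each compartment.
#'
#' @param series a `perfusion_series` carrying `roi_masks`.
#' @return matrix `n_frames x n_rois`, columns named by ROI.
#' @export
signal_time_curves <- function(series) {
  stopifnot(inherits(series, "perfusion_series"))
  if (is.null(series$roi_masks)) stop("series carries no ROI masks")
  nf <- dim(series$frames)[1]
  out <- sapply(series$roi_masks, function(m) {
    idx <- which(m)
    vapply(seq_len(nf), function(i) mean(series$frames[i, , ][idx]), numeric(1))
  })
  out <- matrix(out, nrow = nf, dimnames = list(NULL, names(series$roi_masks)))
  out
}

#' Space-time (x-t) profile
#'
#' Extracts one fixed spatial line from every frame and stacks the lines
#' over time, the standard visualization of temporal fidelity.
#'
#' @param series a `perfusion_series`.
#' @param line_index row (axis = 1) or column (axis = 2) index of the line.
#' @param axis 1 to extract a row, 2 to extract a column.
#' @return matrix `line length x n_frames`.
#' @export
xt_profile <- function(series, line_index, axis = 1L) {
  stopifnot(inherits(series, "perfusion_series"))
  d <- dim(series$frames)
  if (line_index < 1 || line_index > d[axis + 1L])
    stop("line index out of bounds")
  if (axis == 1L) t(series$frames[, line_index, ]) else t(series$frames[, , line_index])
}

#' Paired comparison of per-frame metrics between two methods
#'
#' Two-sided paired t-test or Wilcoxon signed-rank test on per-frame metric
#' values from two methods evaluated on the same frames, with declaration
#' at alpha = 0.05. Zero-variance differences (all pairs identical) yield a
#' flagged non-result instead of an error.
#'
#' @param a,b numeric vectors of per-frame metric values, paired by frame.
#' @param test `"paired_t"` or `"wilcoxon"`.
#' @param alpha significance level for the declaration (default 0.05).
#' @return list with `statistic`, `p_value`, `significant`, `test` and a
#'   `degenerate` flag.
#' @export
compare_methods <- function(a, b, test = c("paired_t", "wilcoxon"), alpha = 0.05) {
  test <- match.arg(test)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                test = test, degenerate = TRUE))
  if (test == "paired_t" && stats::sd(d) <= 1e-10 * mean(abs(d)))
    return(list(statistic = sign(mean(d)) * Inf, p_value = NA_real_,
                significant = NA, test = test, degenerate = TRUE))
  res <- if (test == "paired_t") {
    h <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(h$statistic), p_value = h$p.value)
  } else {
    h <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
    list(statistic = unname(h$statistic), p_value = h$p.value)
  }
  c(res, list(significant = res$p_value < alpha, test = test, degenerate = FALSE))
}

#' Nominal protocol acceleration
#'
#' Fold speed-up of a low-resolution acquisition combined with parallel
#' imaging, relative to a fully sampled single-shot acquisition:
#' `grappa_factor / phase_fraction`. At 35% phase resolution this gives
#' 5.7-fold with GRAPPA-2 and 8.6-fold with GRAPPA-3; relative to a routine
#' GRAPPA-2 full-phase protocol the temporal-resolution gain is
#' `1 / phase_fraction` (2.86-fold at 35%).
#'
#' @param grappa_factor integer parallel-imaging factor >= 1.
#' @param phase_fraction acquired phase-resolution fraction in (0, 1].
#' @return nominal fold acceleration.
#' @export
nominal_acceleration <- function(grappa_factor, phase_fraction) {
  if (grappa_factor < 1 || grappa_factor != round(grappa_factor))
    stop("grappa_factor must be an integer >= 1")
  if (phase_fraction <= 0 || phase_fraction > 1)
    stop("phase_fraction must lie in (0, 1]")
  grappa_factor / phase_fraction
}

#' Per-frame metric report for a super-resolved series
#'
#' Computes nRMSE (%), PSNR (dB) and SSIM for every frame of an evaluated
#' series against the reference, with aggregates, and (optionally) paired
#' comparisons against a baseline method.
#'
#' @param pred evaluated series: `perfusion_series` or `frames` array.
#' @param ref reference HR series, same shape.
#' @param baseline optional second evaluated series (e.g. zero-padded LR).
#' @param ssim_window passed to [ssim()].
#' @return object of class `metric_report`: per-frame data frame,
#'   aggregates, and comparison tests when a baseline is given.
#' @export
metric_report <- function(pred, ref, baseline = NULL, ssim_window = "global") {
  fr <- function(x) if (inherits(x, "perfusion_series")) x$frames else x
  p <- fr(pred); r <- fr(ref)
  stopifnot(all(dim(p) == dim(r)))
  nf <- dim(p)[1]
  one <- function(a) data.frame(
    frame = seq_len(nf),
    nrmse = vapply(seq_len(nf), function(i) 100 * nrmse(a[i, , ], r[i, , ]), numeric(1)),
    psnr  = vapply(seq_len(nf), function(i) psnr(a[i, , ], r[i, , ]), numeric(1)),
    ssim  = vapply(seq_len(nf), function(i)
      as.numeric(ssim(a[i, , ], r[i, , ], window = ssim_window)), numeric(1))
  )
  per_frame <- one(p)
  agg <- function(df) c(nrmse_mean = mean(df$nrmse), nrmse_sd = stats::sd(df$nrmse),
                        psnr_mean = mean(df$psnr), psnr_sd = stats::sd(df$psnr),
                        ssim_mean = mean(df$ssim), ssim_sd = stats::sd(df$ssim))
  out <- list(per_frame = per_frame, aggregate = agg(per_frame),
              ssim_window = ssim_window, schema_version = "1.0")
  if (!is.null(baseline)) {
    bl <- one(fr(baseline))
    out$baseline_per_frame <- bl
    out$baseline_aggregate <- agg(bl)
    out$tests <- list(
      nrmse = compare_methods(per_frame$nrmse, bl$nrmse, "paired_t"),
      psnr  = compare_methods(per_frame$psnr, bl$psnr, "paired_t"),
      ssim  = compare_methods(per_frame$ssim, bl$ssim, "paired_t")
    )
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Metric report (%d frames, SSIM window: %s)\n",
              nrow(x$per_frame), x$ssim_window))
  cat(sprintf("  nRMSE %.2f +/- %.2f %% | PSNR %.2f +/- %.2f dB | SSIM %.3f +/- %.3f\n",
              a["nrmse_mean"], a["nrmse_sd"], a["psnr_mean"], a["psnr_sd"],
              a["ssim_mean"], a["ssim_sd"]))
  if (!is.null(x$baseline_aggregate)) {
    b <- x$baseline_aggregate
    cat(sprintf("  baseline: nRMSE %.2f %% | PSNR %.2f dB | SSIM %.3f\n",
                b["nrmse_mean"], b["psnr_mean"], b["ssim_mean"]))
    for (nm in names(x$tests))
      cat(sprintf("  paired t (%s): t = %.3f, p = %.3g\n",
                  nm, x$tests[[nm]]$statistic, x$tests[[nm]]$p_value))
  }
  invisible(x)
}

#' Write a metric report as JSON
#' @param report a `metric_report`.
#' @param path output path.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
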