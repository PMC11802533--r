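#' Forward FFT to a DC-centered k-space grid
#'
#' Applies the unnormalized 2-D discrete Fourier transform and shifts the
#' zero-frequency (DC) component to the central index, the conventional
#' k-space view with low spatial frequencies in the middle. Rows are the
#' phase-encoding axis by default.
#'
#' @param image 2-D real matrix (a magnitude MR image).
#' @param phase_encode_axis 1 (rows, default) or 2 (cols).
#' @return object of class `kspace`: the complex DC-centered grid with the
#'   phase-encode axis recorded as an attribute.
#' @export
to_kspace <- function(image, phase_encode_axis = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a 2-D numeric matrix")
  if (any(!is.finite(image))) stop("image must be finite")
  k <- fftshift(stats::fft(image))
  structure(k, phase_encode_axis = as.integer(phase_encode_axis), class = "kspace")
}

#' Inverse FFT back to a magnitude image
#'
#' Inverse of [to_kspace()] followed by taking the modulus, mirroring the
#' retrospective low-resolution synthesis pipeline. For an untruncated grid
#' of a non-negative image the round trip is the identity to floating-point
#' tolerance.
#'
#' @param k a `kspace` grid.
#' @return real non-negative matrix, same shape.
#' @export
from_kspace <- function(k) {
  if (!inherits(k, "kspace")) stop("k must be a kspace grid")
  g <- ifftshift(unclass(k))
  Mod(stats::fft(g, inverse = TRUE)) / length(g)
}

# DC-centering shifts. For even N the DC index after fftshift is N/2 + 1.
fftshift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, seq_len(floor(n1 / 2))),
    c((floor(n2 / 2) + 1):n2, seq_len(floor(n2 / 2)))]
}
ifftshift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, seq_len(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, seq_len(n2 - floor(n2 / 2)))]
}

# round-half-away-from-zero (base round() is round-half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Zero out all but the central phase-encoding lines
#'
#' Keeps `n_keep = round(fraction * N_pe)` contiguous lines (rounding half
#' away from zero) centered on DC and sets the rest to zero; the readout
#' axis is untouched. The retained band always contains DC; for even
#' `n_keep` the extra line falls on the lower-index side. Emulates a
#' low-resolution acquisition that measures only the center of k-space.
#'
#' @param k a `kspace` grid.
#' @param fraction fraction of phase-encoding lines to retain, in (0, 1].
#' @return truncated `kspace` grid, same shape.
#' @export
truncate_phase_lines <- function(k, fraction) {
  if (!inherits(k, "kspace")) stop("k must be a kspace grid")
  if (length(fraction) != 1 || !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  ax <- attr(k, "phase_encode_axis")
  n_pe <- if (ax == 1L) nrow(k) else ncol(k)
  n_keep <- max(1L, as.integer(round_half_away(fraction * n_pe)))
  if (n_keep >= n_pe) return(k)
  dc <- floor(n_pe / 2) + 1L
  lo <- dc - n_keep %/% 2L
  hi <- lo + n_keep - 1L
  keep <- seq.int(lo, hi)
  out <- unclass(k)
  if (ax == 1L) out[-keep, ] <- 0+0i else out[, -keep] <- 0+0i
  structure(out, phase_encode_axis = ax, class = "kspace")
}

# low-resolution synthesis on one magnitude image: FFT -> central lines ->
# zero-pad -> IFFT -> modulus
degrade_image <- function(image, fraction, phase_encode_axis = 1L) {
  from_kspace(truncate_phase_lines(to_kspace(image, phase_encode_axis), fraction))
}

crop_window <- function(dim_n, center, size) {
  half <- size %/% 2
  lo <- as.integer(round(center)) - half + (1L - size %% 2L)
  if (lo < 1L || lo + size - 1L > dim_n)
    stop("crop window out of bounds")
  seq.int(lo, lo + size - 1L)
}

#' Build one paired low/high-resolution training example
#'
#' Degrades the high-resolution frame by central phase-line truncation,
#' crops both the degraded and the original image to the same central
#' window, and normalizes both identically: division by `norm_max`
#' (typically the series-wide maximum, so signal-time relationships are
#' preserved across frames) followed by an affine map to \[-1, 1\].
#'
#' @param hr_image 2-D matrix, the high-resolution frame (a.u.).
#' @param fraction retained phase-line fraction in (0, 1].
#' @param crop_center c(row, col) center of the crop window (e.g. the heart
#'   center); default image center.
#' @param crop_size output matrix size (default 96).
#' @param norm_max intensity mapped to +1; defaults to `max(hr_image)`.
#'   Pass the series maximum when building pairs from a dynamic series.
#' @param phase_encode_axis axis carrying phase-encoding lines (1 = rows).
#' @return object of class `lrhr_pair`: list with `x` (conditioning LR
#'   image), `y0` (HR target), `fraction` and the shared `normalization`
#'   record.
#' @export
make_lr_hr_pair <- function(hr_image, fraction, crop_center = NULL,
                            crop_size = 96L, norm_max = NULL,
                            phase_encode_axis = 1L) {
  if (!is.matrix(hr_image)) stop("hr_image must be a matrix")
  crop_size <- as.integer(crop_size)
  if (nrow(hr_image) < crop_size || ncol(hr_image) < crop_size)
    stop("hr_image smaller than the crop size")
  if (is.null(crop_center))
    crop_center <- (dim(hr_image) + 1) / 2
  if (is.null(norm_max)) norm_max <- max(hr_image)
  if (norm_max <= 0) stop("norm_max must be positive")
  lr <- degrade_image(hr_image, fraction, phase_encode_axis)
  ri <- crop_window(nrow(hr_image), crop_center[1], crop_size)
  ci <- crop_window(ncol(hr_image), crop_center[2], crop_size)
  norm <- list(type = "affine-to-[-1,1]", max = norm_max)
  structure(list(
    x = normalize_to_unit(lr[ri, ci], norm_max),
    y0 = normalize_to_unit(hr_image[ri, ci], norm_max),
    fraction = fraction,
    normalization = norm
  ), class = "lrhr_pair")
}

# [0, max] -> [-1, 1] and back
normalize_to_unit <- function(img, maxv) 2 * img / maxv - 1
denormalize_from_unit <- function(img, maxv) pmax((img + 1) / 2 * maxv, 0)

#' Joint random flips of a training pair
#'
#' On-the-fly augmentation: a vertical and a horizontal flip, each applied
#' with probability 0.5, identically to the conditioning and target image.
#'
#' @param pair an `lrhr_pair`.
#' @param seed optional integer for a local RNG stream.
#' @return the augmented `lrhr_pair`.
#' @export
augment_pair <- function(pair, seed = NULL) {
  stopifnot(inherits(pair, "lrhr_pair"))
  flips <- with_local_seed(seed, stats::runif(2) < 0.5)
  flip <- function(m) {
    if (flips[1]) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (flips[2]) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    m
  }
  pair$x <- flip(pair$x)
  pair$y0 <- flip(pair$y0)
  pair
}
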