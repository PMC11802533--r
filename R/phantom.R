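#' Configuration for the synthetic first-pass perfusion phantom
#'
#' Parameterizes a short-axis cardiac phantom with three contrast-carrying
#' compartments: the right-ventricular (RV) blood pool (lateral ellipse),
#' the left-ventricular (LV) blood pool (central disk) and the LV
#' myocardium (annulus around the LV pool). Each compartment follows a
#' gamma-variate bolus curve so that contrast arrives in the physiological
#' order RV pool, then LV pool, then myocardium.
#'
#' Geometry defaults are expressed for a 96 x 96 matrix and scaled
#' linearly for other matrix sizes.
#'
#' @param matrix_size image matrix size in pixels (square).
#' @param n_frames number of dynamic frames.
#' @param frame_interval frame spacing in seconds (one frame per heartbeat).
#' @param center heart center c(row, col) in pixels; default image center.
#' @param lv_radius radius of the LV blood-pool disk, pixels (96-px scale).
#' @param myo_inner,myo_outer inner/outer radii of the myocardial annulus,
#'   pixels (96-px scale). `myo_inner` must be >= `lv_radius` so the
#'   annulus strictly contains the pool.
#' @param rv_center_offset offset c(row, col) of the RV ellipse center from
#'   the heart center, pixels (96-px scale).
#' @param rv_axes semi-axes c(row, col) of the RV ellipse, pixels (96-px scale).
#' @param bolus named list of per-compartment gamma-variate parameters
#'   (`onset` s, `shape`, `scale` s, `amplitude` a.u., `baseline` a.u.)
#'   for compartments `rv`, `lv`, `myo`.
#' @param background baseline intensity of non-cardiac tissue, a.u.
#' @param noise_sigma standard deviation of additive Gaussian noise, a.u.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param defect optional perfusion defect: list with `theta0`, `theta1`
#'   (radians, sector of the annulus) and `factor` in \[0,1\] multiplying the
#'   myocardial enhancement inside the sector. `NULL` for none.
#' @param motion logical; if `TRUE`, apply a random integer in-plane
#'   translation (uniform on -2..2 px per axis) per frame, emulating
#'   free breathing. Default off.
#' @param seed integer seed controlling noise (and motion) reproducibly.
#'
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(matrix_size = 96L,
                           n_frames = 60L,
                           frame_interval = 1,
                           center = NULL,
                           lv_radius = 10,
                           myo_inner = 11.5,
                           myo_outer = 19,
                           rv_center_offset = c(0, -28),
                           rv_axes = c(13, 7),
                           bolus = list(
                             rv  = list(onset = 6,  shape = 3, scale = 1.4, amplitude = 1.0,  baseline = 0.10),
                             lv  = list(onset = 12, shape = 3, scale = 1.6, amplitude = 0.95, baseline = 0.10),
                             myo = list(onset = 16, shape = 3, scale = 2.8, amplitude = 0.45, baseline = 0.12)
                           ),
                           background = 0.06,
                           noise_sigma = 0.02,
                           noise_model = c("gaussian", "rician"),
                           defect = NULL,
                           motion = FALSE,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  matrix_size <- as.integer(matrix_size)
  n_frames <- as.integer(n_frames)
  if (matrix_size < 8L) stop("matrix_size must be at least 8 pixels")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(center)) center <- rep((matrix_size + 1) / 2, 2)

  s <- matrix_size / 96                       # geometry stated at 96-px scale
  geom <- list(
    center = center,
    lv_radius = lv_radius * s,
    myo_inner = myo_inner * s,
    myo_outer = myo_outer * s,
    rv_center = center + rv_center_offset * s,
    rv_axes = rv_axes * s
  )
  if (geom$myo_inner < geom$lv_radius)
    stop("myocardial annulus must strictly contain the LV pool (myo_inner >= lv_radius)")
  if (geom$myo_inner >= geom$myo_outer)
    stop("myo_inner must be smaller than myo_outer")
  if (matrix_size < 2 * geom$myo_outer)
    stop("matrix_size must be at least twice the outer myocardial radius")
  for (nm in c("rv", "lv", "myo")) {
    b <- bolus[[nm]]
    if (is.null(b)) stop("bolus parameters required for compartment ", nm)
    if (b$shape <= 0 || b$scale <= 0 || b$amplitude <= 0)
      stop("bolus shape, scale and amplitude must be positive (compartment ", nm, ")")
  }
  if (!is.null(defect)) {
    if (is.null(defect$theta0) || is.null(defect$theta1) || is.null(defect$factor))
      stop("defect must supply theta0, theta1 and factor")
    if (defect$factor < 0 || defect$factor > 1) stop("defect factor must lie in [0, 1]")
  }

  structure(list(
    matrix_size = matrix_size, n_frames = n_frames,
    frame_interval = frame_interval, geom = geom, bolus = bolus,
    background = background, noise_sigma = noise_sigma,
    noise_model = noise_model, defect = defect, motion = isTRUE(motion),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Gamma-variate bolus curve
#'
#' The standard first-pass tracer-kinetic shape
#' \deqn{c(t) = b + A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'       \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right)}
#' for \eqn{t > t_0} and \eqn{c(t) = b} otherwise. The curve is continuous,
#' unimodal, peaks at exactly `onset + shape * scale` with peak height
#' `baseline + amplitude`, and relaxes back toward `baseline`.
#'
#' @param t time points, seconds.
#' @param onset bolus arrival time \eqn{t_0}, seconds.
#' @param shape shape parameter \eqn{\alpha > 0} (dimensionless).
#' @param scale scale parameter \eqn{\beta > 0}, seconds.
#' @param amplitude peak enhancement above baseline, a.u.
#' @param baseline pre-contrast signal level, a.u.
#' @return numeric vector of signal values, same length as `t`.
#' @export
gamma_variate_bolus <- function(t, onset, shape, scale, amplitude, baseline = 0) {
  if (shape <= 0 || scale <= 0 || amplitude <= 0)
    stop("shape, scale and amplitude must be positive")
  dt <- t - onset
  y <- rep(baseline, length(t))
  up <- dt > 0
  # normalized so the analytic mode (dt = shape*scale) has height `amplitude`
  y[up] <- baseline + amplitude *
    exp(shape * log(dt[up] / (shape * scale)) + shape - dt[up] / scale)
  y
}

# Boolean compartment masks on the pixel grid. Row/col indices are 1-based;
# masks are mutually disjoint by construction (annulus starts at myo_inner
# >= lv_radius, RV ellipse is checked against the annulus).
phantom_masks <- function(config) {
  n <- config$matrix_size
  g <- config$geom
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  d_lv <- sqrt((rows - g$center[1])^2 + (cols - g$center[2])^2)
  lv <- d_lv < g$lv_radius
  myo <- d_lv >= g$myo_inner & d_lv < g$myo_outer
  rv <- ((rows - g$rv_center[1]) / g$rv_axes[1])^2 +
        ((cols - g$rv_center[2]) / g$rv_axes[2])^2 < 1
  if (any(rv & (myo | lv)))
    stop("compartment geometry overlaps: RV ellipse intersects the LV/myocardium")
  list(`RV-pool` = rv, `LV-pool` = lv, `LV-myocardium` = myo)
}

# Angular-sector mask of the myocardial defect, if configured.
phantom_defect_mask <- function(config, myo_mask) {
  if (is.null(config$defect)) return(NULL)
  n <- config$matrix_size
  g <- config$geom
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  theta <- atan2(rows - g$center[1], cols - g$center[2])
  t0 <- config$defect$theta0; t1 <- config$defect$theta1
  insec <- if (t0 <= t1) theta >= t0 & theta <= t1 else theta >= t0 | theta <= t1
  myo_mask & insec
}

#' Render one phantom frame
#'
#' Paints each compartment with its instantaneous signal value, the rest of
#' the field of view with the background level, then adds noise. With
#' `noise_sigma = 0` the frame is an exact deterministic function of the
#' configuration.
#'
#' @param config a [phantom_config()].
#' @param signals named numeric vector/list with elements `rv`, `lv`, `myo`:
#'   the compartment signal values for this frame, a.u. (non-negative).
#' @param seed optional integer; when given, noise is drawn from a local RNG
#'   stream seeded with it (the global RNG state is untouched). When `NULL`
#'   the current RNG stream is used.
#' @return matrix `matrix_size x matrix_size`, a.u.
#' @export
render_frame <- function(config, signals, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  sg <- unlist(signals[c("rv", "lv", "myo")])
  if (any(sg < 0)) stop("compartment signals must be non-negative")
  masks <- phantom_masks(config)
  img <- matrix(config$background, config$matrix_size, config$matrix_size)
  img[masks[["RV-pool"]]] <- sg[["rv"]]
  img[masks[["LV-pool"]]] <- sg[["lv"]]
  img[masks[["LV-myocardium"]]] <- sg[["myo"]]
  if (!is.null(config$defect)) {
    dm <- phantom_defect_mask(config, masks[["LV-myocardium"]])
    base <- config$bolus$myo$baseline
    img[dm] <- base + config$defect$factor * (sg[["myo"]] - base)
  }
  if (config$noise_sigma > 0) {
    draw <- function() matrix(stats::rnorm(length(img), 0, config$noise_sigma),
                              nrow(img), ncol(img))
    noisy <- with_local_seed(seed, {
      if (config$noise_model == "rician") {
        sqrt((img + draw())^2 + draw()^2)
      } else {
        img + draw()
      }
    })
    img <- noisy
  }
  img
}

# Evaluate an expression under a temporary RNG state when seed is non-NULL.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a synthetic first-pass perfusion series
#'
#' Renders the full dynamic series from a [phantom_config()]: compartment
#' signal-time curves follow gamma-variate boluses whose onsets are ordered
#' RV pool < LV pool < myocardium, so ROI-mean curves peak in the
#' physiological order (baseline, peak RV, peak LV, peak myocardium).
#'
#' @param config a [phantom_config()].
#' @return a `perfusion_series`: list with `frames` (array
#'   `n_frames x rows x cols`), `frame_times` (s), `roi_masks` (list of
#'   boolean matrices `RV-pool`, `LV-pool`, `LV-myocardium`) and a
#'   `normalization` record (initially `"none"`).
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  b <- config$bolus
  if (!(b$rv$onset < b$lv$onset && b$lv$onset < b$myo$onset))
    stop("bolus onsets must be ordered RV < LV < myocardium")
  t <- (seq_len(config$n_frames) - 1) * config$frame_interval
  kinetics_free <- config$n_frames == 1L
  if (!kinetics_free) {
    t_end <- t[length(t)]
    peaks <- vapply(b, function(p) p$onset + p$shape * p$scale, numeric(1))
    if (any(peaks > t_end))
      stop("frame window too short: it must contain the RV, LV and myocardial peaks")
  }
  curves <- lapply(b, function(p)
    gamma_variate_bolus(t, p$onset, p$shape, p$scale, p$amplitude, p$baseline))
  frames <- array(0, c(config$n_frames, config$matrix_size, config$matrix_size))
  masks <- phantom_masks(config)
  shifts <- NULL
  out <- with_local_seed(config$seed, {
    if (config$motion)
      shifts <- matrix(sample(-2:2, 2 * config$n_frames, replace = TRUE),
                       ncol = 2)
    for (i in seq_len(config$n_frames)) {
      fr <- render_frame(config,
                         list(rv = curves$rv[i], lv = curves$lv[i],
                              myo = curves$myo[i]),
                         seed = NULL)
      if (config$motion) fr <- shift_image(fr, shifts[i, 1], shifts[i, 2])
      frames[i, , ] <- fr
    }
    frames
  })
  structure(list(
    frames = out, frame_times = t, roi_masks = masks,
    normalization = list(type = "none"),
    kinetics_free = kinetics_free,
    config = config
  ), class = "perfusion_series")
}

# Integer circular-free translation with edge replication-free zero fill.
shift_image <- function(img, dr, dc) {
  out <- matrix(min(img), nrow(img), ncol(img))
  n <- nrow(img); m <- ncol(img)
  r_src <- seq_len(n) - dr; c_src <- seq_len(m) - dc
  ok_r <- r_src >= 1 & r_src <= n; ok_c <- c_src >= 1 & c_src <= m
  out[ok_r, ok_c] <- img[r_src[ok_r], c_src[ok_c]]
  out
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Perfusion series: %d frames of %d x %d px, t = %.1f..%.1f s\n",
              d[1], d[2], d[3], x$frame_times[1], x$frame_times[d[1]]))
  cat(sprintf("  normalization: %s; ROI masks: %s\n",
              x$normalization$type,
              if (is.null(x$roi_masks)) "none" else paste(names(x$roi_masks), collapse = ", ")))
  invisible(x)
}

#' Write / read a perfusion series as NIfTI
#'
#' Frames are stored as the last dimension of a 3-D NIfTI volume
#' (rows x cols x frames); ROI masks go to a companion label map
#' (1 = RV pool, 2 = LV pool, 3 = LV myocardium) when present.
#'
#' @param series a `perfusion_series`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param masks_path optional path for the label map.
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path, masks_path = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  vol <- aperm(series$frames, c(2, 3, 1))
  img <- RNifti::asNifti(vol, pixdim = c(1, 1, mean(diff(c(0, series$frame_times)))))
  RNifti::writeNifti(img, path)
  if (!is.null(masks_path) && !is.null(series$roi_masks)) {
    lab <- matrix(0L, dim(vol)[1], dim(vol)[2])
    for (i in seq_along(series$roi_masks)) lab[series$roi_masks[[i]]] <- i
    RNifti::writeNifti(RNifti::asNifti(lab), masks_path)
  }
  invisible(path)
}

#' @rdname write_series_nifti
#' @param path path of a NIfTI series written by [write_series_nifti()].
#' @param frame_interval seconds between frames (NIfTI stores only spacing).
#' @export
read_series_nifti <- function(path, masks_path = NULL, frame_interval = 1) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) == 2L) dim(vol) <- c(dim(vol), 1L)
  frames <- aperm(vol, c(3, 1, 2))
  masks <- NULL
  if (!is.null(masks_path)) {
    lab <- as.array(RNifti::readNifti(masks_path))
    masks <- list(`RV-pool` = lab == 1, `LV-pool` = lab == 2,
                  `LV-myocardium` = lab == 3)
  }
  structure(list(
    frames = frames,
    frame_times = (seq_len(dim(frames)[1]) - 1) * frame_interval,
    roi_masks = masks, normalization = list(type = "none"),
    kinetics_free = dim(frames)[1] == 1L, config = NULL
  ), class = "perfusion_series")
}

#' Write or read a phantom configuration as YAML
#' @param config a [phantom_config()].
#' @param path file path.
#' @export
write_phantom_config <- function(config, path) {
  stopifnot(inherits(config, "phantom_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_phantom_config
#' @export
read_phantom_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(phantom_config, c(
    x[c("matrix_size", "n_frames", "frame_interval", "background",
        "noise_sigma", "noise_model", "motion", "seed")],
    list(bolus = x$bolus, defect = x$defect)
  ))
}
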