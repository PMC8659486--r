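#' Phantom generator configuration
#'
#' Defines a synthetic 4D DCE-MRI acquisition with exact ground truth. The
#' defaults emulate the acquisition the pipeline targets: 32 coronal slices
#' of 224 x 224 voxels at 1.25 x 1.25 x 3 mm, a six-minute-capped dynamic
#' series sampled densely (3.3 s) during the two-minute arterial phase and
#' sparsely (13 s) thereafter, and cortical enhancement that peaks well
#' before medullary enhancement. Intensities live on a [0, 255] scale.
#'
#' @param shape `(D, H, W)` voxel counts (slices, rows, columns).
#' @param n_frames number of frames `T`. `NULL` (default) derives the frame
#'   times from the two-rate acquisition protocol; an explicit value gives
#'   uniformly spaced frames over `duration`.
#' @param duration acquisition length in seconds.
#' @param spacing voxel spacing `(dz, dy, dx)` mm.
#' @param n_kidneys 0, 1 or 2.
#' @param cortex_thickness cortical shell thickness in voxels.
#' @param kinetics per-compartment enhancement parameters, each a list of
#'   `baseline`, `amplitude` (peak height above baseline), `ttp`
#'   (time-to-peak, seconds) and `washout` (exponential decay rate, 1/s).
#'   Cortex time-to-peak must precede medulla time-to-peak.
#' @param noise_sigma additive noise standard deviation (intensity units).
#' @param noise_model `"gaussian"` or `"rician"` (magnitude of complex
#'   Gaussian noise, the MR magnitude-image model).
#' @param streak_amplitude amplitude of the radial streak artefact pattern.
#' @param n_spokes angular frequency of the streak pattern.
#' @param blur_sigma Gaussian blur standard deviation in voxels (0 = none).
#' @param abnormality `"none"`, `"missing_kidney"` (left kidney absent) or
#'   `"dilated_pelvis"` (enlarged, poorly enhancing central collecting
#'   system).
#' @param kidney_axes optional ellipsoid semi-axes `(az, ay, ax)` in voxels;
#'   defaults to fractions of the volume shape.
#' @param seed integer fixing all randomness (lobe layout and noise).
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(32, 224, 224),
                           n_frames = NULL,
                           duration = 300,
                           spacing = c(3, 1.25, 1.25),
                           n_kidneys = 2,
                           cortex_thickness = 3,
                           kinetics = list(
                             cortex  = list(baseline = 60, amplitude = 120,
                                            ttp = 40, washout = 0.003),
                             medulla = list(baseline = 50, amplitude = 80,
                                            ttp = 90, washout = 0.002),
                             pelvis  = list(baseline = 30, amplitude = 15,
                                            ttp = 200, washout = 0.001)),
                           noise_sigma = 2,
                           noise_model = c("gaussian", "rician"),
                           streak_amplitude = 0,
                           n_spokes = 24,
                           blur_sigma = 0,
                           abnormality = c("none", "missing_kidney",
                                           "dilated_pelvis"),
                           kidney_axes = NULL,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  abnormality <- match.arg(abnormality)
  if (!n_kidneys %in% 0:2) stop("n_kidneys must be 0, 1 or 2", call. = FALSE)
  for (k in c("cortex", "medulla")) {
    p <- kinetics[[k]]
    if (is.null(p)) stop("kinetics must define ", k, call. = FALSE)
    if (p$amplitude < 0) stop("enhancement amplitude must be >= 0", call. = FALSE)
  }
  if (kinetics$cortex$ttp >= kinetics$medulla$ttp)
    stop("cortex time-to-peak must precede medulla time-to-peak", call. = FALSE)
  if (is.null(kidney_axes))
    kidney_axes <- c(0.28 * shape[1], 0.20 * shape[2], 0.11 * shape[3])
  if (any(2 * (kidney_axes + 2) > shape))
    stop("kidney does not fit in the requested shape", call. = FALSE)
  if (cortex_thickness >= min(kidney_axes))
    stop("cortical shell swallows the whole kidney", call. = FALSE)
  structure(list(shape = as.integer(shape), n_frames = n_frames,
                 duration = duration, spacing = spacing,
                 n_kidneys = as.integer(n_kidneys),
                 cortex_thickness = cortex_thickness, kinetics = kinetics,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 streak_amplitude = streak_amplitude, n_spokes = n_spokes,
                 blur_sigma = blur_sigma, abnormality = abnormality,
                 kidney_axes = kidney_axes, seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_times <- function(config) {
  if (!is.null(config$n_frames)) {
    n <- config$n_frames
    return(seq_len(n) * config$duration / n)
  }
  arterial_end <- min(120, config$duration)
  t1 <- seq(3.3, arterial_end, by = 3.3)
  t2 <- if (config$duration > arterial_end)
    seq(max(t1) + 13, config$duration, by = 13) else numeric(0)
  c(t1, t2)
}

#' Compartment contrast-enhancement curve
#'
#' Deterministic unimodal enhancement: the signal starts at `baseline`,
#' rises linearly to `baseline + amplitude` at the configured time-to-peak,
#' then washes out exponentially at rate `washout`. This reproduces the
#' qualitative shape of renal time-intensity curves, with the cortex peaking
#' earlier than the medulla.
#'
#' @param compartment `"cortex"`, `"medulla"` or `"pelvis"`.
#' @param t time(s) in seconds from injection, `t >= 0` (vectorised).
#' @param kinetics kinetics list as in [phantom_config()].
#' @return Intensity value(s); the maximum `baseline + amplitude` is attained
#'   exactly at `t = ttp`.
#' @export
enhancement_curve <- function(compartment, t, kinetics) {
  p <- kinetics[[compartment]]
  if (is.null(p)) stop("unknown compartment: ", compartment, call. = FALSE)
  if (p$amplitude < 0) stop("enhancement amplitude must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  f <- ifelse(t <= p$ttp, t / p$ttp, exp(-p$washout * (t - p$ttp)))
  p$baseline + p$amplitude * f
}

# Ellipsoid occupancy test on the voxel grid (1-based integer centres).
ellipsoid_mask <- function(shape, centre, axes) {
  z <- (seq_len(shape[1]) - centre[1]) / axes[1]
  y <- (seq_len(shape[2]) - centre[2]) / axes[2]
  x <- (seq_len(shape[3]) - centre[3]) / axes[3]
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= 1
}

# One kidney: whole = ellipsoid; medulla = union of spheroidal lobes strictly
# interior to the cortical shell; cortex = whole minus medulla (cortical
# columns fill inter-lobe space, so labels partition the kidney mask).
make_kidney <- function(shape, centre, axes, thickness, n_lobes, pelvis = FALSE) {
  whole <- ellipsoid_mask(shape, centre, axes)
  inner_axes <- pmax(axes - thickness, 0.8)
  interior <- ellipsoid_mask(shape, centre, inner_axes)
  # lobes scale with the kidney so the medulla stays a realistic (~1/3)
  # fraction of the parenchyma at any phantom size
  lobe_axes <- pmax(inner_axes * c(0.75, 1.6 / n_lobes, 0.75), 1.2)
  offs <- seq(-0.55, 0.55, length.out = n_lobes) * inner_axes[2]
  medulla <- array(FALSE, shape)
  for (o in offs) {
    medulla <- medulla | ellipsoid_mask(shape, centre + c(0, o, 0), lobe_axes)
  }
  medulla <- medulla & interior
  pelvis_m <- array(FALSE, shape)
  if (pelvis) {
    pelvis_m <- ellipsoid_mask(shape, centre, pmax(inner_axes * 0.55, 1)) & interior
    medulla <- medulla & !pelvis_m
  }
  list(whole = whole, medulla = medulla, cortex = whole & !medulla & !pelvis_m,
       pelvis = pelvis_m)
}

#' Generate a 4D DCE-MRI phantom with exact ground truth
#'
#' Places up to two ellipsoidal kidneys left/right of the sagittal midline;
#' each kidney is a bright cortical shell around darker medullary lobes.
#' Voxel intensities follow compartment-specific enhancement curves
#' ([enhancement_curve()]) plus optional seeded noise, then the configured
#' artefacts ([add_artefacts()]). The same configuration and seed always
#' yield a bit-identical phantom.
#'
#' @param config a [phantom_config()].
#' @return A list of class `phantom_truth`: `series` ([dce_series()]),
#'   `labels` ([compartment_labels()]), `left_mask`, `right_mask`
#'   ([kidney_mask()]), and the `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  set.seed(config$seed)
  shape <- config$shape
  times <- phantom_times(config)
  nT <- length(times)
  centre_z <- shape[1] / 2
  centre_y <- shape[2] / 2
  sides <- list()
  want <- config$n_kidneys
  if (config$abnormality == "missing_kidney") want <- 1L
  if (want >= 1) sides$right <- c(centre_z, centre_y, 0.30 * shape[3])
  if (want >= 2) sides$left <- c(centre_z, centre_y, 0.70 * shape[3])
  labels <- array(0L, shape)
  masks <- list(left = array(0L, shape), right = array(0L, shape))
  pelvis_all <- array(FALSE, shape)
  for (s in names(sides)) {
    n_lobes <- sample(2:4, 1)
    k <- make_kidney(shape, sides[[s]], config$kidney_axes,
                     config$cortex_thickness, n_lobes,
                     pelvis = (config$abnormality == "dilated_pelvis"))
    labels[k$medulla] <- 1L
    labels[k$cortex] <- 2L
    labels[k$pelvis] <- 1L  # dilated collecting system reported as medulla class
    pelvis_all <- pelvis_all | k$pelvis
    masks[[s]][k$whole] <- 1L
  }
  med_curve <- enhancement_curve("medulla", times, config$kinetics)
  cor_curve <- enhancement_curve("cortex", times, config$kinetics)
  pel_curve <- if (!is.null(config$kinetics$pelvis))
    enhancement_curve("pelvis", times, config$kinetics) else med_curve
  data <- array(0, c(nT, shape))
  med_idx <- which(labels == 1L & !pelvis_all)
  cor_idx <- which(labels == 2L)
  pel_idx <- which(pelvis_all)
  nvox <- prod(shape)
  for (t in seq_len(nT)) {
    frame <- array(0, shape)
    frame[med_idx] <- med_curve[t]
    frame[cor_idx] <- cor_curve[t]
    frame[pel_idx] <- pel_curve[t]
    if (config$noise_sigma > 0) {
      if (config$noise_model == "rician") {
        frame <- sqrt((frame + rnorm(nvox, 0, config$noise_sigma))^2 +
                        rnorm(nvox, 0, config$noise_sigma)^2)
      } else {
        frame <- frame + rnorm(nvox, 0, config$noise_sigma)
      }
    }
    data[t, , , ] <- frame
  }
  data[data < 0] <- 0
  series <- dce_series(data, times, config$spacing)
  if (config$streak_amplitude > 0 || config$blur_sigma > 0)
    series <- add_artefacts(series, config)
  structure(list(series = series,
                 labels = compartment_labels(labels),
                 left_mask = kidney_mask(masks$left, side = "left"),
                 right_mask = kidney_mask(masks$right, side = "right"),
                 config = config),
            class = "phantom_truth")
}

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array with replicate padding (approximately
# mean-preserving).
blur3d <- function(vol, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    d <- dim(vol)
    m <- aperm(vol, c(axis, setdiff(1:3, axis)))
    dm <- dim(m)
    mm <- matrix(m, nrow = dm[1])
    idx <- pmin(pmax(outer(seq_len(dm[1]), -r:r, `+`), 1L), dm[1])
    out <- matrix(0, dm[1], ncol(mm))
    for (j in seq_along(k)) out <- out + k[j] * mm[idx[, j], , drop = FALSE]
    vol <- aperm(array(out, dm), order(c(axis, setdiff(1:3, axis))))
  }
  vol
}

#' Add acquisition artefacts to a series
#'
#' Emulates the two dominant artefact types of fast radial DCE-MRI: streaking
#' from angular undersampling (a zero-mean radial spoke pattern of amplitude
#' `streak_amplitude`, random per-frame phase) and motion blur (per-frame
#' Gaussian blur of `blur_sigma` voxels). Zero amplitudes return the series
#' unchanged.
#'
#' @param series a [dce_series()].
#' @param config a [phantom_config()] carrying the artefact settings.
#' @export
add_artefacts <- function(series, config) {
  if (config$streak_amplitude <= 0 && config$blur_sigma <= 0) return(series)
  d <- series_dims(series)
  data <- series$data
  if (config$streak_amplitude > 0) {
    yc <- (d$H + 1) / 2; xc <- (d$W + 1) / 2
    theta <- outer(seq_len(d$H) - yc, seq_len(d$W) - xc,
                   function(y, x) atan2(y, x))
    for (t in seq_len(d$T)) {
      phase <- runif(1, 0, 2 * pi)
      pat <- config$streak_amplitude * sin(config$n_spokes * theta + phase)
      for (z in seq_len(d$D)) data[t, z, , ] <- data[t, z, , ] + pat
    }
  }
  if (config$blur_sigma > 0) {
    for (t in seq_len(d$T)) {
      data[t, , , ] <- blur3d(array(data[t, , , ], c(d$D, d$H, d$W)),
                              config$blur_sigma)
    }
  }
  data[data < 0] <- 0
  dce_series(data, series$times, series$spacing)
}

#' Write a phantom case to disk
#'
#' Emits the series (NIfTI + JSON sidecar), ground-truth labels, per-kidney
#' masks and a JSON truth manifest into `dir`.
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param dir output directory (created if needed).
#' @export
write_phantom <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- truth$series$spacing
  write_dce(truth$series, file.path(dir, "series.nii.gz"))
  write_volume3d(truth$labels, file.path(dir, "labels.nii.gz"), sp)
  write_volume3d(truth$left_mask, file.path(dir, "mask_left.nii.gz"), sp)
  write_volume3d(truth$right_mask, file.path(dir, "mask_right.nii.gz"), sp)
  cfg <- unclass(truth$config)
  cfg$kinetics <- lapply(cfg$kinetics, as.list)
  jsonlite::write_json(cfg, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
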