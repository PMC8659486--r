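#' 4D DCE-MRI series
#'
#' Container for a dynamic contrast-enhanced MRI acquisition: an ordered stack
#' of `T` 3D volumes with acquisition times and voxel spacing. The in-memory
#' axis order is `(t, z, y, x)` where `z` indexes coronal slices (the slice
#' depth `D`), so `data[t, d, , ]` is the d-th coronal slice of frame t.
#'
#' @param data 4D numeric array indexed `(t, z, y, x)`; all intensities must
#'   be non-negative.
#' @param times numeric vector of acquisition times in seconds from contrast
#'   injection, one per frame, strictly increasing.
#' @param spacing voxel spacing `(dz, dy, dx)` in millimetres.
#' @return An object of class `dce_series` with elements `data`, `times`,
#'   `spacing`.
#' @export
dce_series <- function(data, times, spacing = c(3, 1.25, 1.25)) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D (t, z, y, x) array", call. = FALSE)
  if (any(data < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (length(times) != dim(data)[1L])
    stop("length(times) must equal the number of frames", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (dz, dy, dx)", call. = FALSE)
  structure(list(data = data, times = as.numeric(times),
                 spacing = as.numeric(spacing)),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> T=%d frames, D=%d x H=%d x W=%d voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  times: %.1f .. %.1f s; spacing %s mm\n",
              min(x$times), max(x$times),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

series_dims <- function(series) {
  d <- dim(series$data)
  list(T = d[1], D = d[2], H = d[3], W = d[4])
}

#' Binary whole-kidney mask
#'
#' @param data 3D array over \{0, 1\} indexed `(z, y, x)`.
#' @param side which kidney the mask covers: `"left"`, `"right"` or `"both"`.
#' @export
kidney_mask <- function(data, side = c("both", "left", "right")) {
  side <- match.arg(side)
  if (length(dim(data)) != 3L) stop("mask must be a 3D array", call. = FALSE)
  if (!all(data %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  structure(list(data = array(as.integer(data), dim(data)), side = side),
            class = "kidney_mask")
}

#' Medulla/cortex label volume
#'
#' Fixed legend: 0 = background, 1 = medulla, 2 = cortex.
#'
#' @param data 3D array over \{0, 1, 2\} indexed `(z, y, x)`.
#' @export
compartment_labels <- function(data) {
  if (length(dim(data)) != 3L) stop("labels must be a 3D array", call. = FALSE)
  if (!all(data %in% c(0, 1, 2)))
    stop("labels must take values in {0, 1, 2}", call. = FALSE)
  structure(list(data = array(as.integer(data), dim(data))),
            class = "compartment_labels")
}

#' Axis-aligned 3D bounding box
#'
#' Inclusive 1-based voxel index ranges per axis. A degenerate single-voxel
#' box with `present = FALSE` encodes an absent kidney.
#'
#' @param zmin,zmax,ymin,ymax,xmin,xmax inclusive 1-based indices.
#' @param present logical; `FALSE` marks a missing kidney (the box must then
#'   be exactly one voxel).
#' @export
bbox3d <- function(zmin, zmax, ymin, ymax, xmin, xmax, present = TRUE) {
  v <- c(zmin, zmax, ymin, ymax, xmin, xmax)
  if (any(v < 1) || any(v != round(v))) stop("indices must be positive integers", call. = FALSE)
  if (zmin > zmax || ymin > ymax || xmin > xmax)
    stop("min index exceeds max index", call. = FALSE)
  if (!present && (zmin != zmax || ymin != ymax || xmin != xmax))
    stop("an absent-kidney box must be a single voxel", call. = FALSE)
  structure(list(zmin = as.integer(zmin), zmax = as.integer(zmax),
                 ymin = as.integer(ymin), ymax = as.integer(ymax),
                 xmin = as.integer(xmin), xmax = as.integer(xmax),
                 present = isTRUE(present)),
            class = "bbox3d")
}

#' @export
print.bbox3d <- function(x, ...) {
  if (!x$present) {
    cat("<bbox3d> kidney absent (single-voxel convention)\n")
  } else {
    cat(sprintf("<bbox3d> z %d..%d, y %d..%d, x %d..%d\n",
                x$zmin, x$zmax, x$ymin, x$ymax, x$xmin, x$xmax))
  }
  invisible(x)
}

bbox_shape <- function(box) {
  c(box$zmax - box$zmin + 1L, box$ymax - box$ymin + 1L, box$xmax - box$xmin + 1L)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a 4D DCE-MRI series from NIfTI
#'
#' Axes are reordered from the on-disk `(x, y, z, t)` convention to the
#' canonical in-memory `(t, z, y, x)`; spacing is taken from the NIfTI header.
#' Acquisition times are read from a JSON sidecar (same basename, `.json`)
#' when present; otherwise they default to uniform spacing `tr` seconds.
#'
#' @param path a 4D NIfTI file (`.nii` / `.nii.gz`), or a directory of
#'   per-timepoint 3D NIfTI files (sorted by name) with an optional
#'   `times.json` sidecar listing `times` (and `spacing`).
#' @param times optional explicit times (seconds), overriding any sidecar.
#' @param tr fallback uniform frame spacing in seconds when no time metadata
#'   exists.
#' @return A [dce_series()].
#' @export
read_dce <- function(path, times = NULL, tr = 6) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    if (length(files) == 0L)
      stop("no NIfTI files found in directory", call. = FALSE)
    vols <- lapply(files, read_volume3d)
    sh <- dim(vols[[1L]])
    data <- array(0, c(length(vols), sh))
    for (i in seq_along(vols)) {
      if (!all(dim(vols[[i]]) == sh))
        stop("per-timepoint volumes differ in shape", call. = FALSE)
      data[i, , , ] <- vols[[i]]
    }
    spacing <- c(3, 1.25, 1.25)
    sc <- file.path(path, "times.json")
    if (is.null(times) && file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      if (!is.null(meta$times)) times <- as.numeric(meta$times)
      if (!is.null(meta$spacing)) spacing <- as.numeric(meta$spacing)
    }
    if (is.null(times)) times <- seq_along(vols) * tr
    return(dce_series(data, times, spacing))
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 3L)
    stop("file is a single 3D volume, not a 4D series", call. = FALSE)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI series", call. = FALSE)
  pd <- RNifti::pixdim(img)
  spacing <- rev(pd[1:3])  # (dx,dy,dz) -> (dz,dy,dx)
  data <- aperm(arr, c(4, 3, 2, 1))
  tn <- dim(data)[1L]
  if (is.null(times)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      if (!is.null(meta$times)) times <- as.numeric(meta$times)
      if (!is.null(meta$spacing)) spacing <- as.numeric(meta$spacing)
    }
  }
  if (is.null(times)) times <- seq_len(tn) * tr
  dce_series(data, times, spacing)
}

#' Write a 4D DCE-MRI series to NIfTI plus a JSON time sidecar
#'
#' @param series a [dce_series()].
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_dce <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  arr <- aperm(series$data, c(4, 3, 2, 1))  # (x,y,z,t) on disk
  attr(arr, "pixdim") <- c(rev(series$spacing), 1)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(times = series$times, spacing = series$spacing),
                       sidecar_path(path), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read/write a 3D volume (mask or label map) as NIfTI
#'
#' Integer volumes round-trip bit-exactly (INT32 storage).
#' @param path NIfTI file path.
#' @export
read_volume3d <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  aperm(arr, c(3, 2, 1))
}

#' @rdname read_volume3d
#' @param vol 3D array indexed `(z, y, x)`.
#' @param spacing voxel spacing `(dz, dy, dx)` mm.
#' @export
write_volume3d <- function(vol, path, spacing = c(3, 1.25, 1.25)) {
  if (inherits(vol, "kidney_mask") || inherits(vol, "compartment_labels"))
    vol <- vol$data
  arr <- aperm(vol, c(3, 2, 1))
  dt <- if (is.integer(arr) || all(arr == round(arr))) "int" else "double"
  storage.mode(arr) <- if (dt == "int") "integer" else "double"
  attr(arr, "pixdim") <- rev(spacing)
  img <- RNifti::asNifti(arr, datatype = dt)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Minimum bounding box of a binary mask
#'
#' Returns the tightest inclusive box containing all foreground voxels. An
#' empty mask yields the missing-kidney convention: `present = FALSE` with a
#' one-voxel box at the origin.
#'
#' @param mask a [kidney_mask()] or 3D binary array.
#' @return A [bbox3d()].
#' @export
compute_bounding_box <- function(mask) {
  m <- if (inherits(mask, "kidney_mask")) mask$data else mask
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(bbox3d(1, 1, 1, 1, 1, 1, present = FALSE))
  bbox3d(min(idx[, 1]), max(idx[, 1]),
         min(idx[, 2]), max(idx[, 2]),
         min(idx[, 3]), max(idx[, 3]), present = TRUE)
}

clamp_box <- function(box, shape, pad = 0L) {
  bbox3d(max(1L, box$zmin - pad), min(shape[1], box$zmax + pad),
         max(1L, box$ymin - pad), min(shape[2], box$ymax + pad),
         max(1L, box$xmin - pad), min(shape[3], box$xmax + pad),
         present = box$present)
}

#' Crop a series to a bounding box
#'
#' The time axis is untouched. The (optionally padded) box is clamped to the
#' volume; the returned series records the effective box as attribute
#' `"box"` together with the original spatial shape (`"canvas"`), so results
#' computed on the crop can be pasted back with [paste_into()].
#'
#' @param series a [dce_series()].
#' @param box a [bbox3d()]. A `present = FALSE` box raises a condition of
#'   class `kidney_absent` — the caller is expected to skip segmentation.
#' @param pad padding in voxels added on every side before clamping.
#' @export
crop_series <- function(series, box, pad = 0L) {
  if (!box$present)
    stop(structure(class = c("kidney_absent", "error", "condition"),
                   list(message = "kidney absent: single-voxel bounding box",
                        call = sys.call())))
  d <- series_dims(series)
  b <- clamp_box(box, c(d$D, d$H, d$W), pad)
  out <- dce_series(series$data[, b$zmin:b$zmax, b$ymin:b$ymax, b$xmin:b$xmax,
                                drop = FALSE],
                    series$times, series$spacing)
  attr(out, "box") <- b
  attr(out, "canvas") <- c(d$D, d$H, d$W)
  out
}

#' @rdname crop_series
#' @param vol 3D array indexed `(z, y, x)`.
#' @export
crop_volume <- function(vol, box, pad = 0L) {
  if (inherits(vol, "kidney_mask") || inherits(vol, "compartment_labels"))
    vol <- vol$data
  b <- clamp_box(box, dim(vol), pad)
  out <- vol[b$zmin:b$zmax, b$ymin:b$ymax, b$xmin:b$xmax, drop = FALSE]
  attr(out, "box") <- b
  attr(out, "canvas") <- dim(vol)
  out
}

#' Paste a label/mask volume into a zero canvas at a box offset
#'
#' @param labels 3D array (or `kidney_mask` / `compartment_labels`) whose
#'   shape equals the box extent.
#' @param box target location, a [bbox3d()].
#' @param canvas_shape `(D, H, W)` of the output volume.
#' @return 3D array of `canvas_shape` with `labels` placed at the box offset
#'   and zeros elsewhere.
#' @export
paste_into <- function(labels, box, canvas_shape) {
  keep_class <- NULL
  if (inherits(labels, "kidney_mask")) { keep_class <- "mask"; labels <- labels$data }
  if (inherits(labels, "compartment_labels")) { keep_class <- "labels"; labels <- labels$data }
  if (!all(dim(labels) == bbox_shape(box)))
    stop("labels shape does not match the box extent", call. = FALSE)
  if (box$zmax > canvas_shape[1] || box$ymax > canvas_shape[2] ||
      box$xmax > canvas_shape[3])
    stop("box exceeds the canvas", call. = FALSE)
  canvas <- array(if (is.integer(labels)) 0L else 0, canvas_shape)
  canvas[box$zmin:box$zmax, box$ymin:box$ymax, box$xmin:box$xmax] <- labels
  if (identical(keep_class, "mask")) kidney_mask(canvas)
  else if (identical(keep_class, "labels")) compartment_labels(canvas)
  else canvas
}
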