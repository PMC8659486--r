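#' Resample a series to a uniform temporal grid
#'
#' Per-voxel linear interpolation onto `n_samples` uniformly spaced times
#' covering `(0, max_seconds]` (i.e. `k * max_seconds / n_samples`). Values
#' requested outside the acquired range are clamped to the nearest acquired
#' frame. Standardising the grid before PCA ensures that the time axis means
#' the same thing for every scan regardless of the acquisition protocol.
#'
#' @param series a [dce_series()] with at least two frames.
#' @param n_samples number of output frames.
#' @param max_seconds maximum acquisition time used (seconds).
#' @return A [dce_series()] with `n_samples` frames.
#' @export
resample_temporal <- function(series, n_samples = 50, max_seconds = 300) {
  d <- series_dims(series)
  if (d$T < 2) stop("temporal resampling needs at least 2 frames", call. = FALSE)
  grid <- seq_len(n_samples) * max_seconds / n_samples
  tin <- series$times
  out <- array(0, c(n_samples, d$D, d$H, d$W))
  for (k in seq_len(n_samples)) {
    tk <- grid[k]
    if (tk <= tin[1]) {
      out[k, , , ] <- series$data[1, , , ]
    } else if (tk >= tin[d$T]) {
      out[k, , , ] <- series$data[d$T, , , ]
    } else {
      i <- findInterval(tk, tin)
      w <- (tk - tin[i]) / (tin[i + 1] - tin[i])
      out[k, , , ] <- (1 - w) * series$data[i, , , ] + w * series$data[i + 1, , , ]
    }
  }
  dce_series(out, grid, series$spacing)
}

#' Reduce the temporal dimension by principal component analysis
#'
#' Each voxel's time course (a `T`-vector) is mean-centred over time and
#' projected onto the leading principal directions of the voxel-by-time
#' matrix, compressing the dynamic information of the scan into a handful of
#' channels ordered by decreasing explained variance. PCA is fitted per scan.
#' Component sign is fixed by making each direction's largest-magnitude
#' loading positive, so results are reproducible across eigensolvers.
#'
#' @param series a [dce_series()] with `T >= n_components` frames.
#' @param n_components number of retained components (channels).
#' @return A list of class `reduced_volume`: `data` — a 4D
#'   `(c, z, y, x)` array; `explained_variance_ratio` — non-increasing
#'   per-component variance fractions.
#' @export
pca_reduce <- function(series, n_components = 5) {
  d <- series_dims(series)
  if (d$T < n_components)
    stop("need at least as many frames as components", call. = FALSE)
  X <- matrix(aperm(series$data, c(2, 3, 4, 1)), ncol = d$T)  # voxels x T
  Xc <- X - rowMeans(X)
  S <- crossprod(Xc)                       # T x T scatter of time courses
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  ratio <- if (tot > 0) ev / tot else rep(0, length(ev))
  Wm <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(Wm[, j]))
    if (Wm[i, j] < 0) Wm[, j] <- -Wm[, j]
  }
  proj <- Xc %*% Wm                        # voxels x n_components
  data <- aperm(array(proj, c(d$D, d$H, d$W, n_components)), c(4, 1, 2, 3))
  structure(list(data = data,
                 explained_variance_ratio = ratio[seq_len(n_components)]),
            class = "reduced_volume")
}

#' Trilinear spatial downsampling of a channel volume
#'
#' Resamples every channel of a `(c, z, y, x)` array (or a plain 3D volume)
#' onto a `target` grid with pixel-centre alignment; when the input already
#' has the target size the values pass through unchanged.
#'
#' @param volume 4D `(c, z, y, x)` or 3D `(z, y, x)` numeric array.
#' @param target `(D, H, W)` output size.
#' @param mode `"linear"` or `"nearest"` (use nearest for label volumes).
#' @export
downsample_spatial <- function(volume, target = c(64, 64, 64),
                               mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  m <- if (mode == "linear") 0L else 1L
  if (length(dim(volume)) == 3L)
    return(resample3d(volume, as.integer(target), m))
  nC <- dim(volume)[1]
  out <- array(0, c(nC, target))
  for (c in seq_len(nC)) {
    out[c, , , ] <- resample3d(array(volume[c, , , ], dim(volume)[2:4]),
                               as.integer(target), m)
  }
  out
}

#' Linear rescale of a volume to [0, 255]
#'
#' Maps the observed `[min, max]` onto `[0, 255]`; a constant volume maps to
#' all zeros. The 255 scale is the reference scale of the gamma-correction
#' step of the compartment cascade.
#' @param volume numeric array.
#' @export
rescale_to_255 <- function(volume) {
  lo <- min(volume); hi <- max(volume)
  if (hi <= lo) return(array(0, dim(volume)))
  (volume - lo) / (hi - lo) * 255
}

#' Apply a fixed augmentation transform to a training sample
#'
#' Integer voxel translation plus isotropic zoom about the volume centre,
#' applied identically to the image channels (trilinear) and the label
#' volume (nearest neighbour). With `zoom = 1` the translation is an exact
#' integer shift.
#'
#' @param sample list with `x` (4D `(c, z, y, x)` array) and `y` (3D label
#'   array).
#' @param translation integer shift `(dz, dy, dx)` in voxels.
#' @param zoom isotropic scale factor (1 = none).
#' @export
apply_augmentation <- function(sample, translation = c(0, 0, 0), zoom = 1) {
  shift1 <- function(v, s) {
    # integer shift with zero fill, per axis
    d <- dim(v)
    out <- array(0, d)
    src <- lapply(1:3, function(a) {
      i <- seq_len(d[a]) - s[a]
      i
    })
    ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
    out[ok[[1]], ok[[2]], ok[[3]]] <-
      v[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
    out
  }
  zoom3 <- function(v, z, mode) {
    if (z == 1) return(v)
    d <- dim(v)
    # resample the central 1/z window onto the full grid (zoom in for z > 1)
    src_dim <- pmax(1L, as.integer(round(d / z)))
    off <- floor((d - src_dim) / 2)
    win <- v[off[1] + seq_len(src_dim[1]), off[2] + seq_len(src_dim[2]),
             off[3] + seq_len(src_dim[3]), drop = FALSE]
    resample3d(win, as.integer(d), if (mode == "linear") 0L else 1L)
  }
  x <- sample$x
  for (c in seq_len(dim(x)[1])) {
    v <- array(x[c, , , ], dim(x)[2:4])
    v <- zoom3(shift1(v, translation), zoom, "linear")
    x[c, , , ] <- v
  }
  y <- zoom3(shift1(sample$y, translation), zoom, "nearest")
  list(x = x, y = y)
}

#' Randomly augment a training sample (seeded)
#'
#' Draws a per-axis integer translation with magnitude in `[1, 4]` voxels
#' (random sign) and a zoom factor in `[0.96, 1.04]`, then applies them with
#' [apply_augmentation()]. The transform is a deterministic function of
#' `seed`.
#'
#' @inheritParams apply_augmentation
#' @param seed integer seed.
#' @param max_shift maximum translation magnitude (voxels).
#' @export
augment_sample <- function(sample, seed, max_shift = 4) {
  set.seed(seed)
  shift <- sample(seq_len(max_shift), 3, replace = TRUE) *
    sample(c(-1L, 1L), 3, replace = TRUE)
  zoom <- runif(1, 0.96, 1.04)
  out <- apply_augmentation(sample, shift, zoom)
  attr(out, "transform") <- list(translation = shift, zoom = zoom)
  out
}

#' Standard network preprocessing of a series
#'
#' The canonical order used for both networks: temporal resampling to a
#' uniform grid, per-scan PCA to `n_components` channels, trilinear spatial
#' resampling to `target`, then linear rescaling of each channel to
#' `[0, 255]`. Deterministic.
#'
#' @param series a [dce_series()].
#' @param n_samples,max_seconds see [resample_temporal()].
#' @param n_components see [pca_reduce()].
#' @param target see [downsample_spatial()].
#' @return A `reduced_volume` whose `data` is `(n_components, target)`.
#' @export
preprocess_series <- function(series, n_samples = 50, max_seconds = 300,
                              n_components = 5, target = c(64, 64, 64)) {
  rs <- resample_temporal(series, n_samples, max_seconds)
  red <- pca_reduce(rs, n_components)
  red$data <- downsample_spatial(red$data, target, "linear")
  for (c in seq_len(dim(red$data)[1])) {
    red$data[c, , , ] <- rescale_to_255(red$data[c, , , ])
  }
  red
}
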