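#' Parameters of the rule-based compartment segmentation
#'
#' Thresholding and range parameters of the contrast-maximisation cascade.
#' Defaults follow the experimentally validated settings: gain `delta = 2`,
#' sigmoid cut-off `mu = 1.5`, gamma correction `gamma = 1.5`, depth-range
#' fractions `r_f = 0.3`, `r_l = 0.7`, medulla-percentage bounds
#' `alpha = 30`, `beta = 60`, and a reference-time fraction `x` in
#' `[0.25, 0.5]` (default: the midpoint 0.375).
#'
#' @param delta sigmoid gain controlling the contrast boost.
#' @param mu sigmoid cut-off on the intensity scale normalised to `[0, 1]`.
#' @param gamma gamma-correction exponent applied to peripheral slices. The
#'   default 1.5 is the validated setting; much larger values (tens) are
#'   admissible and darken bright regions far more aggressively.
#' @param r_f,r_l fractions of the slice depth bounding the central slice
#'   range; `0 < r_f < r_l < 1`.
#' @param alpha,beta admissible medulla percentage (of kidney area) for a
#'   slice to contribute to the temporal fusion, `0 <= alpha < beta <= 100`.
#' @param x reference-time fraction in `[0.25, 0.5]`; the reference volume
#'   is frame `round(x * T)`.
#' @param closing_radius radius (pixels) of the disc used for morphological
#'   closing (followed by hole filling) of per-slice binary images.
#' @param rim_radius radius (pixels) of the cross used to build the cortical
#'   rim via dilation minus erosion of the whole-kidney slice.
#' @export
compartment_params <- function(delta = 2, mu = 1.5, gamma = 1.5,
                               r_f = 0.3, r_l = 0.7,
                               alpha = 30, beta = 60, x = 0.375,
                               closing_radius = 2L, rim_radius = 1L) {
  if (!(r_f > 0 && r_f < r_l && r_l < 1))
    stop("need 0 < r_f < r_l < 1", call. = FALSE)
  if (!(alpha >= 0 && alpha < beta && beta <= 100))
    stop("need 0 <= alpha < beta <= 100", call. = FALSE)
  if (x < 0.25 || x > 0.5)
    stop("the reference-time fraction x must lie in [0.25, 0.5]", call. = FALSE)
  list(delta = delta, mu = mu, gamma = gamma, r_f = r_f, r_l = r_l,
       alpha = alpha, beta = beta, x = x,
       closing_radius = as.integer(closing_radius),
       rim_radius = as.integer(rim_radius))
}

#' Central slice range of the contrast cascade
#'
#' The cascade treats central coronal slices (intensity shifting) and
#' peripheral slices (gamma darkening) differently. The central range is the
#' set of 1-based slice indices d with `r_f * D <= d <= r_l * D`, i.e.
#' `p_f = ceiling(r_f * D)` to `p_l = floor(r_l * D)`, clamped into
#' `[1, D]` with `p_f <= p_l` enforced.
#'
#' @param r_f,r_l depth-range fractions, `0 < r_f < r_l < 1`.
#' @param D number of slices (>= 1).
#' @return Integer vector `c(p_f, p_l)`, 1-based inclusive.
#' @export
depth_ranges <- function(r_f, r_l, D) {
  if (!(r_f > 0 && r_f < r_l && r_l < 1)) stop("need 0 < r_f < r_l < 1", call. = FALSE)
  if (D < 1) stop("D must be >= 1", call. = FALSE)
  p_f <- max(1L, min(as.integer(D), as.integer(ceiling(r_f * D))))
  p_l <- min(as.integer(D), as.integer(floor(r_l * D)))
  if (p_l < p_f) p_l <- p_f
  c(p_f = p_f, p_l = p_l)
}

slice_markers <- function(slice) {
  a <- sort(unique(slice[slice != 0]))
  list(a = a,
       a_min = if (length(a)) min(a) else NA_real_,
       a_max = if (length(a)) max(a) else NA_real_)
}

#' Intensity shifting of a central slice
#'
#' Subtracts the minimum non-zero intensity from every strictly interior
#' pixel (`a_min < s < a_max`); pixels at the extremes and background zeros
#' are untouched. This compresses the within-kidney dynamic range so the
#' subsequent sigmoid stretches medulla/cortex contrast instead of the
#' kidney/background gap.
#'
#' @param slice 2D numeric matrix.
#' @param markers optional precomputed markers (`slice_markers`).
#' @export
shift_intensities <- function(slice, markers = NULL) {
  if (is.null(markers)) markers <- slice_markers(slice)
  if (length(markers$a) < 2L) return(slice)
  interior <- slice > markers$a_min & slice < markers$a_max
  slice[interior] <- slice[interior] - markers$a_min
  slice
}

#' Gamma correction of a peripheral slice
#'
#' `s <- (s^gamma / 255^gamma) * 255` on non-zero pixels, darkening bright
#' regions for `gamma > 1`; zeros are preserved and `gamma = 1` is the
#' identity.
#'
#' @param slice 2D matrix with intensities in `[0, 255]`.
#' @param gamma positive exponent.
#' @export
gamma_correct <- function(slice, gamma) {
  if (any(slice < 0)) stop("gamma correction requires non-negative intensities",
                           call. = FALSE)
  nz <- slice != 0
  slice[nz] <- (slice[nz]^gamma / 255^gamma) * 255
  slice
}

#' Sigmoidal contrast enhancement
#'
#' Applies `E(s) = 1 / (1 + exp(delta * (mu - s)))` to intensities rescaled
#' to `[0, 1]` (division by 255) and returns the result rescaled back to
#' `[0, 255]`. Strictly monotone increasing in `s` for any `delta > 0`, so
#' intensity ordering — and hence the Otsu classes — is preserved while the
#' contrast around the cut-off is amplified.
#'
#' @param slice 2D matrix (or any numeric array) on the `[0, 255]` scale.
#' @param delta gain.
#' @param mu cut-off on the `[0, 1]` scale.
#' @export
sigmoid_enhance <- function(slice, delta, mu) {
  255 / (1 + exp(delta * (mu - slice / 255)))
}

#' Otsu's threshold over arbitrary (continuous) values
#'
#' Finds the threshold maximising the between-class variance
#' `sigma_b^2(tau) = w0 w1 (mu0 - mu1)^2`, where classes are `s <= tau`
#' versus `s > tau` and candidate thresholds are the sorted unique values
#' (excluding the maximum, which would leave an empty class). Ties are
#' broken towards the lowest maximising threshold. No histogram binning is
#' performed, so the result is exact for continuous data.
#'
#' @param values numeric vector with at least two distinct values.
#' @return The threshold, or `NA` for degenerate (constant) input.
#' @export
otsu_threshold <- function(values) {
  u <- sort(unique(values))
  K <- length(u)
  if (K < 2L) return(NA_real_)
  cnt <- tabulate(match(values, u), nbins = K)
  n <- length(values)
  csum <- cumsum(cnt)
  cmean <- cumsum(cnt * u)
  total <- cmean[K]
  w0 <- csum / n
  mu0 <- cmean / csum
  mu1 <- (total - cmean) / (n - csum)
  sb <- w0 * (1 - w0) * (mu0 - mu1)^2
  sb <- sb[seq_len(K - 1L)]
  u[which.max(sb)]
}

#' Binarise a slice with Otsu's method
#'
#' Pixels above the optimal threshold become 1 (cortex candidates), pixels
#' at or below it become 0 (medulla candidates). A constant slice cannot be
#' thresholded: an all-zero result is returned with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param slice 2D numeric matrix.
#' @return Binary matrix with attributes `threshold` and `degenerate`.
#' @export
otsu_binarise <- function(slice) {
  tau <- otsu_threshold(as.vector(slice))
  if (is.na(tau)) {
    warning("constant slice: Otsu threshold undefined, returning all zeros",
            call. = FALSE)
    out <- array(0L, dim(slice))
    attr(out, "threshold") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- array(as.integer(slice > tau), dim(slice))
  attr(out, "threshold") <- tau
  attr(out, "degenerate") <- FALSE
  out
}

# closing (disc) followed by hole filling — the "fully closed" binary slice
close_fill <- function(m, radius = 2L) {
  if (!any(m != 0)) return(array(0L, dim(m)))
  img <- array(as.numeric(m != 0), dim(m))
  if (radius > 0) {
    br <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
    img <- EBImage::closing(img, br)
  }
  img <- EBImage::fillHull(img)
  array(as.integer(img > 0), dim(m))
}

rim_slice <- function(m, radius = 1L) {
  img <- array(as.numeric(m != 0), dim(m))
  br <- EBImage::makeBrush(2L * radius + 1L, shape = "diamond")
  dil <- EBImage::dilate(img, br)
  ero <- EBImage::erode(img, br)
  array(as.integer(dil > 0 & !(ero > 0)), dim(m))
}

#' Label a binarised slice as medulla/cortex within the kidney mask
#'
#' False positives outside the fully closed mask slice are removed from the
#' binarised image; within the kidney mask, pixels that are 0 in the
#' binarised image are labelled medulla (1) and the rest cortex (2);
#' everything else is background (0).
#'
#' @param o_d binary slice from [otsu_binarise()].
#' @param b_d binary whole-kidney mask slice.
#' @param closing_radius disc radius for the mask closing.
#' @param b_close optional precomputed closed mask slice.
#' @return Integer label matrix over \{0, 1, 2\}.
#' @export
label_slice <- function(o_d, b_d, closing_radius = 2L, b_close = NULL) {
  if (!all(dim(o_d) == dim(b_d))) stop("slice shape mismatch", call. = FALSE)
  if (is.null(b_close)) b_close <- close_fill(b_d, closing_radius)
  o <- o_d
  o[b_close == 0L] <- 0L
  lab <- array(0L, dim(o_d))
  inside <- b_d == 1L
  lab[inside & o == 0L] <- 1L
  lab[inside & o == 1L] <- 2L
  lab
}

#' Per-slice medulla and cortex segmentation for every time frame
#'
#' For every frame t and coronal slice d: restrict the slice to the closed
#' kidney mask, apply intensity shifting (central slices, [shift_intensities()])
#' or gamma correction (peripheral slices, [gamma_correct()]), sigmoid
#' enhancement ([sigmoid_enhance()]), Otsu binarisation and the labelling
#' rule ([label_slice()]). The Otsu threshold is estimated from the pixels
#' inside the closed mask slice: the markers of the cascade are defined on
#' the kidney's non-zero intensities, and including the (dominant)
#' background would reduce the threshold to a trivial foreground split.
#'
#' @param series a [dce_series()].
#' @param mask a [kidney_mask()] for one kidney; must be non-empty.
#' @param params a [compartment_params()].
#' @return A list of class `label_series`: element `volumes` holds one
#'   integer label array `(D, H, W)` per frame.
#' @export
process2 <- function(series, mask, params = compartment_params()) {
  m <- if (inherits(mask, "kidney_mask")) mask$data else mask
  if (!any(m != 0)) stop("kidney absent: empty mask", call. = FALSE)
  d <- series_dims(series)
  pr <- depth_ranges(params$r_f, params$r_l, d$D)
  bclose <- lapply(seq_len(d$D), function(z)
    close_fill(array(m[z, , ], c(d$H, d$W)), params$closing_radius))
  volumes <- vector("list", d$T)
  for (t in seq_len(d$T)) {
    lab <- array(0L, c(d$D, d$H, d$W))
    for (z in seq_len(d$D)) {
      bc <- bclose[[z]]
      bd <- array(m[z, , ], c(d$H, d$W))
      s <- array(series$data[t, z, , ], c(d$H, d$W))
      s[bc == 0L] <- 0
      if (any(s != 0)) {
        central <- z >= pr[1] && z <= pr[2]
        s <- if (central) shift_intensities(s) else gamma_correct(s, params$gamma)
        inmask <- bc == 1L
        s[inmask] <- sigmoid_enhance(s[inmask], params$delta, params$mu)
        tau <- otsu_threshold(s[inmask])
        o <- if (is.na(tau)) array(0L, dim(s)) else
          array(as.integer(s > tau), dim(s))
      } else {
        o <- array(0L, dim(s))
      }
      lab[z, , ] <- label_slice(o, bd, params$closing_radius, b_close = bc)
    }
    volumes[[t]] <- lab
  }
  structure(list(volumes = volumes), class = "label_series")
}

#' Medulla fraction markers of a labelled slice
#'
#' @param l_d integer label matrix over \{0, 1, 2\}.
#' @return List with `area_d` (labelled pixels), `med_d` (medulla pixels)
#'   and `rMA` (percentage `100 * med_d / area_d`, `NA` when the slice has
#'   no labelled pixels).
#' @export
medulla_fraction <- function(l_d) {
  area <- sum(l_d > 0L)
  med <- sum(l_d == 1L)
  list(area_d = area, med_d = med,
       rMA = if (area > 0L) 100 * med / area else NA_real_)
}

#' Temporal fusion of the optimum medulla and cortex labels
#'
#' Starting from the reference volume at frame `t_x = round(x * T)`, every
#' frame's slice within the central depth range may promote reference
#' cortex pixels to medulla where that frame saw medulla, provided the
#' frame-slice's medulla percentage lies strictly inside `(alpha, beta)`.
#' Cortex is then refined: pixels inside the whole-kidney mask that are
#' background in the fully closed binarised reference slice but currently
#' medulla revert to cortex (this corrects peripheral slices with no
#' cortex/medulla contrast), and the rim of the kidney mask (dilation minus
#' erosion) is labelled cortex.
#'
#' @param L a `label_series` from [process2()].
#' @param series the originating [dce_series()] (kept for interface
#'   symmetry; the fusion operates on labels and mask only).
#' @param mask the whole-kidney [kidney_mask()].
#' @param params a [compartment_params()].
#' @return A [compartment_labels()] volume.
#' @export
process3 <- function(L, series, mask, params = compartment_params()) {
  if (length(L$volumes) == 0L) stop("empty label series", call. = FALSE)
  m <- if (inherits(mask, "kidney_mask")) mask$data else mask
  nT <- length(L$volumes)
  dm <- dim(L$volumes[[1L]])
  pr <- depth_ranges(params$r_f, params$r_l, dm[1])
  tx <- min(max(round(params$x * nT), 1L), nT)
  k <- L$volumes[[tx]]
  theta <- lapply(seq_len(dm[1]), function(z)
    close_fill(array(L$volumes[[tx]][z, , ] == 2L, dm[2:3]),
               params$closing_radius))
  for (t in seq_len(nT)) {
    if (t == tx) next
    for (z in pr[1]:pr[2]) {
      l <- array(L$volumes[[t]][z, , ], dm[2:3])
      mf <- medulla_fraction(l)
      if (is.na(mf$rMA)) next
      if (mf$rMA > params$alpha && mf$rMA < params$beta) {
        kd <- array(k[z, , ], dm[2:3])
        upd <- l == 1L & kd == 2L
        kd[upd] <- 1L
        k[z, , ] <- kd
      }
    }
  }
  for (z in seq_len(dm[1])) {
    Y <- array(m[z, , ], dm[2:3])
    kd <- array(k[z, , ], dm[2:3])
    flip <- Y == 1L & theta[[z]] == 0L & kd == 1L
    kd[flip] <- 2L
    rim <- rim_slice(Y, params$rim_radius)
    kd[rim == 1L] <- 2L
    k[z, , ] <- kd
  }
  compartment_labels(k)
}

#' Rule-based medulla/cortex segmentation of one or two kidneys
#'
#' Runs [process2()] and [process3()] independently per kidney and merges
#' the outputs (the masks are disjoint, so labels cannot clash). Empty
#' masks are skipped and reported in the `absent` attribute.
#'
#' @param series a [dce_series()].
#' @param masks named list of [kidney_mask()] (e.g. `right`, `left`);
#'   `NULL` entries allowed.
#' @param params a [compartment_params()].
#' @return A [compartment_labels()] covering all present kidneys.
#' @export
segment_compartments <- function(series, masks, params = compartment_params()) {
  d <- series_dims(series)
  out <- array(0L, c(d$D, d$H, d$W))
  absent <- character(0)
  for (side in names(masks)) {
    mk <- masks[[side]]
    if (is.null(mk)) next
    mdat <- if (inherits(mk, "kidney_mask")) mk$data else mk
    if (!any(mdat != 0)) {
      absent <- c(absent, side)
      next
    }
    L <- process2(series, mk, params)
    lab <- process3(L, series, mk, params)
    out <- pmax(out, lab$data)
  }
  res <- compartment_labels(out)
  attr(res, "absent") <- absent
  res
}
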