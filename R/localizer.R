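#' Configuration of the 3D residual U-Net localiser
#'
#' A U-Net with additive identity shortcuts in every convolutional block
#' (1x1x1 projections where channel counts differ), used for coarse
#' three-class segmentation of background / right kidney / left kidney on
#' PCA-reduced 64^3 input. Four encoder blocks (each two 3x3x3 conv + ReLU,
#' residual add, 2x2x2 max-pool, dropout), a two-conv bottleneck, four
#' upsampling decoder blocks (2x2x2 transpose conv, skip concatenation, two
#' convs, residual add) and a fifth full-resolution decoder block, then
#' batch normalisation and a 1x1x1 convolution to the three classes.
#'
#' @param in_channels input channels (PCA components).
#' @param n_classes output classes; fixed at 3.
#' @param base_filters filters of the first scale; doubled at each scale.
#' @param dropout_rate dropout fraction used during training.
#' @param n_samples,max_seconds,target preprocessing applied before the
#'   network (see [preprocess_series()]); `target` is the network input grid
#'   and must be divisible by 16 per axis.
#' @param init_seed seed for weight initialisation.
#' @export
rb_unet_config <- function(in_channels = 5, n_classes = 3, base_filters = 32,
                           dropout_rate = 0.2, n_samples = 50,
                           max_seconds = 300, target = c(64, 64, 64),
                           init_seed = 1L) {
  if (n_classes != 3)
    stop("the localiser predicts exactly 3 classes (background/right/left)",
         call. = FALSE)
  list(in_channels = in_channels, n_classes = n_classes,
       encoder_blocks = 4L, decoder_blocks = 5L,
       base_filters = base_filters, dropout_rate = dropout_rate,
       n_samples = n_samples, max_seconds = max_seconds,
       target = as.integer(target), init_seed = as.integer(init_seed))
}

rbunet_forward_factory <- function(cfg) {
  rate <- cfg$dropout_rate
  function(pm, x, training = FALSE) {
    sp <- dim(nd_val(x))[2:4]
    if (any(sp %% 16 != 0))
      stop("Rb-UNet input spatial size must be divisible by 16", call. = FALSE)
    h <- op_scale(x, 1 / 255)
    skips <- vector("list", 4L)
    for (i in 1:4) {
      c1 <- op_relu(ly_conv3(pm, sprintf("enc%d.c1", i), h))
      c2 <- op_relu(ly_conv3(pm, sprintf("enc%d.c2", i), c1))
      sc <- ly_conv3(pm, sprintf("enc%d.proj", i), h, k = 1L)
      blk <- op_add(c2, sc)
      skips[[i]] <- blk
      h <- op_dropout(op_maxpool(blk), rate, training)
    }
    b1 <- op_relu(ly_conv3(pm, "bott.c1", h))
    b1 <- op_dropout(b1, rate, training)
    h <- op_relu(ly_conv3(pm, "bott.c2", b1))
    for (j in 1:4) {
      lev <- 5L - j
      up <- ly_convt(pm, sprintf("dec%d.up", j), h, k = 2L, stride = 2L,
                     pad = 0L, opad = 0L)
      ct <- op_concat(list(up, skips[[lev]]))
      d1 <- op_relu(ly_conv3(pm, sprintf("dec%d.c1", j), ct))
      d1 <- op_dropout(d1, rate, training)
      d2 <- op_relu(ly_conv3(pm, sprintf("dec%d.c2", j), d1))
      h <- op_add(d2, ly_conv3(pm, sprintf("dec%d.proj", j), ct, k = 1L))
    }
    e1 <- op_relu(ly_conv3(pm, "dec5.c1", h))
    e1 <- op_dropout(e1, rate, training)
    e2 <- op_relu(ly_conv3(pm, "dec5.c2", e1))
    h <- op_add(e2, h)
    hn <- ly_norm(pm, "head.norm", h)
    op_softmax(ly_conv3(pm, "head.conv", hn, k = 1L))
  }
}

#' Build the 3D residual U-Net localiser
#'
#' @param config an [rb_unet_config()].
#' @return An `rs_model` (untrained, He-initialised with `init_seed`).
#' @export
build_rb_unet <- function(config = rb_unet_config()) {
  set.seed(config$init_seed)
  f <- config$base_filters * 2^(0:3)
  fb <- config$base_filters * 16
  params <- list()
  cin <- config$in_channels
  for (i in 1:4) {
    params <- conv_par(params, sprintf("enc%d.c1", i), cin, f[i], 3)
    params <- conv_par(params, sprintf("enc%d.c2", i), f[i], f[i], 3)
    params <- conv_par(params, sprintf("enc%d.proj", i), cin, f[i], 1)
    cin <- f[i]
  }
  params <- conv_par(params, "bott.c1", f[4], fb, 3)
  params <- conv_par(params, "bott.c2", fb, fb, 3)
  prev <- fb
  for (j in 1:4) {
    lev <- 5L - j
    params <- convt_par(params, sprintf("dec%d.up", j), prev, f[lev], 2)
    cat_ch <- 2L * f[lev]
    params <- conv_par(params, sprintf("dec%d.c1", j), cat_ch, f[lev], 3)
    params <- conv_par(params, sprintf("dec%d.c2", j), f[lev], f[lev], 3)
    params <- conv_par(params, sprintf("dec%d.proj", j), cat_ch, f[lev], 1)
    prev <- f[lev]
  }
  params <- conv_par(params, "dec5.c1", f[1], f[1], 3)
  params <- conv_par(params, "dec5.c2", f[1], f[1], 3)
  params <- norm_par(params, "head.norm", f[1])
  params <- conv_par(params, "head.conv", f[1], config$n_classes, 1)
  structure(list(type = "rb_unet", config = config, params = params,
                 forward = rbunet_forward_factory(config), history = NULL),
            class = "rs_model")
}

#' Train the localiser
#'
#' Optimises the three-class weighted cross-entropy with Adam (see
#' `optimizer_config` defaults: lr 1e-4 halved every 50 epochs, weight decay
#' 1e-8, mini-batch 4). Fully deterministic under `opt$seed`.
#'
#' @param dataset list of training pairs `list(x = (c, z, y, x) array,
#'   y = 3D labels over 0/1/2)`, e.g. from [make_localizer_dataset()].
#' @param config an [rb_unet_config()].
#' @param opt optimiser overrides (`lr`, `epochs`, `batch_size`, `seed`, ...).
#' @return The trained `rs_model` with a per-epoch `history` data frame.
#' @export
train_localizer <- function(dataset, config = rb_unet_config(), opt = list()) {
  model <- build_rb_unet(config)
  train_net(model, dataset, opt)
}

#' Split a whole-kidney mask into right/left classes
#'
#' Voxels in the half-volume with smaller x are labelled right kidney (class
#' 1), the rest left (class 2) — the radiological convention of the patient's
#' right appearing on the image left.
#' @param mask 3D binary array or [kidney_mask()].
#' @return 3D integer array over \{0, 1, 2\}.
#' @export
split_left_right <- function(mask) {
  m <- if (inherits(mask, "kidney_mask")) mask$data else mask
  W <- dim(m)[3]
  lab <- array(0L, dim(m))
  xs <- slice.index(m, 3)
  lab[m == 1 & xs <= W / 2] <- 1L
  lab[m == 1 & xs > W / 2] <- 2L
  lab
}

#' Build a localiser training set from phantom truths
#'
#' @param truths list of `phantom_truth` objects.
#' @param config an [rb_unet_config()].
#' @export
make_localizer_dataset <- function(truths, config = rb_unet_config()) {
  lapply(truths, function(tr) {
    red <- preprocess_series(tr$series, config$n_samples, config$max_seconds,
                             config$in_channels, config$target)
    lab <- array(0L, dim(tr$labels$data))
    lab[tr$right_mask$data == 1] <- 1L
    lab[tr$left_mask$data == 1] <- 2L
    y <- downsample_spatial(lab, config$target, "nearest")
    list(x = red$data, y = array(as.integer(y), config$target))
  })
}

#' Oracle localiser for pipeline testing
#'
#' Wraps ground-truth three-class labels as a drop-in replacement for a
#' trained localiser; [predict_boxes()] still performs the full
#' downsample/argmax/upmap round trip, so the geometric box logic is
#' exercised without network inference.
#'
#' @param labels 3D integer array over \{0, 1, 2\} (background/right/left)
#'   at the original resolution, e.g. from [split_left_right()].
#' @param config an [rb_unet_config()].
#' @export
oracle_localizer <- function(labels, config = rb_unet_config()) {
  structure(list(type = "oracle_localizer", config = config, labels = labels),
            class = c("rs_oracle_localizer", "rs_model"))
}

map_box_to_original <- function(lo, hi, n_small, n_orig) {
  s <- n_orig / n_small
  c(floor((lo - 1) * s) + 1, ceiling(hi * s))
}

#' Localise both kidneys as bounding boxes
#'
#' Preprocesses the series, runs the localiser, takes the per-voxel argmax
#' and maps each foreground class back to original-resolution coordinates
#' (the inverse of the downsampling scale), returning the minimum bounding
#' box per kidney. An empty class yields the missing-kidney convention
#' (`present = FALSE`, single-voxel box).
#'
#' @param model a trained localiser or [oracle_localizer()].
#' @param series a [dce_series()].
#' @return `list(right = bbox3d, left = bbox3d)`.
#' @export
predict_boxes <- function(model, series) {
  cfg <- model$config
  d <- series_dims(series)
  orig <- c(d$D, d$H, d$W)
  if (inherits(model, "rs_oracle_localizer")) {
    # occupancy downsampling: a coarse cell carries a class if any original
    # voxel inside it does, mirroring a coarse segmentation that fully
    # encloses the organ (point sampling could drop one-voxel extremes)
    lab64 <- array(0L, cfg$target)
    for (cls in c(1L, 2L)) {
      idx <- which(model$labels == cls, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      cell1 <- function(a)
        pmin(floor((idx[, a] - 0.5) * cfg$target[a] / orig[a]) + 1L,
             cfg$target[a])
      cells <- cbind(cell1(1), cell1(2), cell1(3))
      lab64[unique(cells[, 1] + (cells[, 2] - 1L) * cfg$target[1] +
                     (cells[, 3] - 1L) * cfg$target[1] * cfg$target[2])] <- cls
    }
  } else {
    red <- preprocess_series(series, cfg$n_samples, cfg$max_seconds,
                             cfg$in_channels, cfg$target)
    probs <- net_forward(model, red$data)
    C <- dim(probs)[1L]
    lab64 <- array(max.col(t(matrix(probs, nrow = C))) - 1L, cfg$target)
  }
  one_box <- function(class_id) {
    idx <- which(lab64 == class_id, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(bbox3d(1, 1, 1, 1, 1, 1, present = FALSE))
    z <- map_box_to_original(min(idx[, 1]), max(idx[, 1]), cfg$target[1], orig[1])
    y <- map_box_to_original(min(idx[, 2]), max(idx[, 2]), cfg$target[2], orig[2])
    x <- map_box_to_original(min(idx[, 3]), max(idx[, 3]), cfg$target[3], orig[3])
    bbox3d(z[1], min(z[2], orig[1]), y[1], min(y[2], orig[2]),
           x[1], min(x[2], orig[3]))
  }
  list(right = one_box(1L), left = one_box(2L))
}
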