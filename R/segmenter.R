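#' Configuration of the 3D fully convolutional DenseNet segmenter
#'
#' A Tiramisu-style FC-DenseNet for binary whole-kidney segmentation of
#' cropped, PCA-reduced regions. The downsampling path is an initial 3x3x3
#' convolution followed by six dense blocks of 4, 5, 7, 10, 12 and 15
#' layers; each of the first five blocks is followed by a transition-down
#' (batch norm, ReLU, 1x1x1 convolution with channel `reduction`, dropout,
#' 2x2x2 max-pool, stride 2). Every dense layer is batch norm, ReLU, a
#' 3x3x3 convolution producing `growth_rate` channels and dropout, with its
#' input concatenated to its output. The upsampling path is five
#' transition-up blocks (3x3x3 transpose convolution, stride 2) each
#' followed by a dense block of 12, 10, 7, 5 and 4 layers with skip
#' concatenation from the same-scale downsampling features; a 1x1x1
#' convolution and softmax predict kidney vs non-kidney.
#'
#' @param in_channels input channels (PCA components).
#' @param n_classes output classes; 2 (background/kidney).
#' @param down_block_layers layer counts of the six downsampling dense
#'   blocks (the sixth is the bottleneck).
#' @param up_block_layers layer counts of the five upsampling dense blocks.
#' @param growth_rate channels added per dense layer.
#' @param reduction transition-down channel compression factor.
#' @param init_filters channels of the initial convolution.
#' @param dropout_rate dropout fraction during training.
#' @param n_samples,max_seconds,target preprocessing of the cropped region;
#'   `target` must be divisible by 32 per axis.
#' @param init_seed weight-initialisation seed.
#' @export
fc_densenet_config <- function(in_channels = 5, n_classes = 2,
                               down_block_layers = c(4, 5, 7, 10, 12, 15),
                               up_block_layers = c(12, 10, 7, 5, 4),
                               growth_rate = 12, reduction = 0.8,
                               init_filters = 48, dropout_rate = 0.2,
                               n_samples = 50, max_seconds = 300,
                               target = c(64, 64, 64), init_seed = 1L) {
  if (length(down_block_layers) != 6L || length(up_block_layers) != 5L)
    stop("layout must have 6 down blocks and 5 up blocks", call. = FALSE)
  if (growth_rate <= 0) stop("growth_rate must be positive", call. = FALSE)
  list(in_channels = in_channels, n_classes = n_classes,
       down_block_layers = as.integer(down_block_layers),
       up_block_layers = as.integer(up_block_layers),
       growth_rate = growth_rate, reduction = reduction,
       init_filters = as.integer(init_filters), dropout_rate = dropout_rate,
       n_samples = n_samples, max_seconds = max_seconds,
       target = as.integer(target), init_seed = as.integer(init_seed))
}

# Channel arithmetic of the whole architecture; every builder and forward
# step reads its sizes from this plan.
fcdn_plan <- function(cfg) {
  g <- cfg$growth_rate
  down <- list()
  c_now <- cfg$init_filters
  for (i in 1:5) {
    n <- cfg$down_block_layers[i]
    out <- c_now + g * n
    td <- floor(cfg$reduction * out)
    down[[i]] <- list(n = n, in_ch = c_now, out = out, td = td)
    c_now <- td
  }
  nb <- cfg$down_block_layers[6]
  bott <- list(n = nb, in_ch = c_now, m = g * nb)
  up <- list()
  m_prev <- bott$m
  for (j in 1:5) {
    n <- cfg$up_block_layers[j]
    skip <- down[[6 - j]]$out
    in_ch <- m_prev + skip
    up[[j]] <- list(n = n, tu_in = m_prev, skip = skip, in_ch = in_ch,
                    m = g * n, full = in_ch + g * n)
    m_prev <- g * n
  }
  list(down = down, bott = bott, up = up, head_in = up[[5]]$full)
}

dense_layer_params <- function(params, prefix, cin, g) {
  params <- norm_par(params, paste0(prefix, ".n"), cin)
  conv_par(params, paste0(prefix, ".c"), cin, g, 3)
}

dense_block_params <- function(params, prefix, cin, n, g) {
  for (q in seq_len(n)) {
    params <- dense_layer_params(params, sprintf("%s.l%d", prefix, q), cin, g)
    cin <- cin + g
  }
  params
}

dense_block_fw <- function(pm, prefix, x, n, rate, training) {
  cur <- x
  newf <- vector("list", n)
  for (q in seq_len(n)) {
    h <- ly_norm(pm, sprintf("%s.l%d.n", prefix, q), cur)
    h <- op_relu(h)
    h <- ly_conv3(pm, sprintf("%s.l%d.c", prefix, q), h)
    h <- op_dropout(h, rate, training)
    newf[[q]] <- h
    cur <- op_concat(list(cur, h))
  }
  list(full = cur, new = if (n == 1L) newf[[1L]] else op_concat(newf))
}

fcdn_forward_factory <- function(cfg) {
  plan <- fcdn_plan(cfg)
  rate <- cfg$dropout_rate
  function(pm, x, training = FALSE) {
    sp <- dim(nd_val(x))[2:4]
    if (any(sp %% 32 != 0))
      stop("FC-DenseNet input spatial size must be divisible by 32", call. = FALSE)
    h <- op_scale(x, 1 / 255)
    h <- ly_conv3(pm, "init", h)
    skips <- vector("list", 5L)
    for (i in 1:5) {
      db <- dense_block_fw(pm, sprintf("down%d", i), h, plan$down[[i]]$n,
                           rate, training)
      skips[[i]] <- db$full
      t <- ly_norm(pm, sprintf("td%d.n", i), db$full)
      t <- op_relu(t)
      t <- ly_conv3(pm, sprintf("td%d.c", i), t, k = 1L)
      t <- op_dropout(t, rate, training)
      h <- op_maxpool(t)
    }
    bott <- dense_block_fw(pm, "bott", h, plan$bott$n, rate, training)
    m <- bott$new
    db <- NULL
    for (j in 1:5) {
      up <- ly_convt(pm, sprintf("up%d.tu", j), m, k = 3L, stride = 2L,
                     pad = 1L, opad = 1L)
      ct <- op_concat(list(up, skips[[6L - j]]))
      db <- dense_block_fw(pm, sprintf("up%d", j), ct, plan$up[[j]]$n,
                           rate, training)
      m <- db$new
    }
    op_softmax(ly_conv3(pm, "head", db$full, k = 1L))
  }
}

#' Build the 3D FC-DenseNet segmenter
#'
#' @param config an [fc_densenet_config()].
#' @return An `rs_model` (untrained).
#' @export
build_fc_densenet <- function(config = fc_densenet_config()) {
  set.seed(config$init_seed)
  plan <- fcdn_plan(config)
  g <- config$growth_rate
  params <- conv_par(list(), "init", config$in_channels, config$init_filters, 3)
  for (i in 1:5) {
    d <- plan$down[[i]]
    params <- dense_block_params(params, sprintf("down%d", i), d$in_ch, d$n, g)
    params <- norm_par(params, sprintf("td%d.n", i), d$out)
    params <- conv_par(params, sprintf("td%d.c", i), d$out, d$td, 1)
  }
  params <- dense_block_params(params, "bott", plan$bott$in_ch, plan$bott$n, g)
  for (j in 1:5) {
    u <- plan$up[[j]]
    params <- convt_par(params, sprintf("up%d.tu", j), u$tu_in, u$tu_in, 3)
    params <- dense_block_params(params, sprintf("up%d", j), u$in_ch, u$n, g)
  }
  params <- conv_par(params, "head", plan$head_in, config$n_classes, 1)
  structure(list(type = "fc_densenet", config = config, params = params,
                 forward = fcdn_forward_factory(config), plan = plan,
                 history = NULL),
            class = "rs_model")
}

#' Train the whole-kidney segmenter
#'
#' Optimises the two-class weighted cross-entropy on per-kidney crops; same
#' optimiser defaults and determinism guarantees as [train_localizer()].
#'
#' @param dataset list of `list(x, y)` crops from [make_segmenter_dataset()].
#' @param config an [fc_densenet_config()].
#' @param opt optimiser overrides.
#' @export
train_segmenter <- function(dataset, config = fc_densenet_config(),
                            opt = list()) {
  model <- build_fc_densenet(config)
  train_net(model, dataset, opt)
}

#' Build a segmenter training set of per-kidney crops from phantom truths
#'
#' Every present kidney is cropped with the bounding box of its ground-truth
#' mask (plus `pad` voxels), preprocessed to the network grid, and paired
#' with the nearest-neighbour-resampled binary mask.
#'
#' @param truths list of `phantom_truth` objects.
#' @param config an [fc_densenet_config()].
#' @param pad crop padding in voxels.
#' @export
make_segmenter_dataset <- function(truths, config = fc_densenet_config(),
                                   pad = 2L) {
  out <- list()
  for (tr in truths) {
    for (side in c("right", "left")) {
      mask <- tr[[paste0(side, "_mask")]]
      box <- compute_bounding_box(mask)
      if (!box$present) next
      cs <- crop_series(tr$series, box, pad)
      red <- preprocess_series(cs, config$n_samples, config$max_seconds,
                               config$in_channels, config$target)
      mc <- crop_volume(mask, box, pad)
      y <- downsample_spatial(mc, config$target, "nearest")
      out[[length(out) + 1L]] <- list(x = red$data,
                                      y = array(as.integer(y), config$target))
    }
  }
  out
}

#' Oracle segmenter for pipeline testing
#'
#' Wraps a ground-truth whole-kidney mask; [predict_kidney_mask()] still
#' performs the crop / resample-down / resample-up / paste round trip, so
#' only network inference is bypassed.
#' @param mask a [kidney_mask()] (or 3D binary array) at original resolution.
#' @param config an [fc_densenet_config()].
#' @export
oracle_segmenter <- function(mask, config = fc_densenet_config()) {
  m <- if (inherits(mask, "kidney_mask")) mask$data else mask
  structure(list(type = "oracle_segmenter", config = config, mask = m),
            class = c("rs_oracle_segmenter", "rs_model"))
}

#' Segment the whole kidney inside a bounding box
#'
#' Crops the series to the box, preprocesses the crop to the network grid,
#' runs the segmenter, takes the per-voxel argmax, resamples the binary
#' mask back to the crop's original size (nearest neighbour, preserving
#' binarity) and pastes it at the box offset. A `present = FALSE` box
#' returns an all-zero mask flagged with attribute `absent = TRUE`.
#'
#' @param model a trained segmenter or [oracle_segmenter()].
#' @param series a [dce_series()].
#' @param box a [bbox3d()] from [predict_boxes()] (or ground truth).
#' @param pad crop padding in voxels.
#' @return A [kidney_mask()] at the original series resolution.
#' @export
predict_kidney_mask <- function(model, series, box, pad = 2L) {
  cfg <- model$config
  d <- series_dims(series)
  canvas <- c(d$D, d$H, d$W)
  if (!box$present) {
    out <- kidney_mask(array(0L, canvas))
    attr(out, "absent") <- TRUE
    return(out)
  }
  b <- clamp_box(box, canvas, pad)
  if (inherits(model, "rs_oracle_segmenter")) {
    mc <- crop_volume(model$mask, box, pad)
    small <- downsample_spatial(mc, cfg$target, "nearest")
  } else {
    cs <- crop_series(series, box, pad)
    red <- preprocess_series(cs, cfg$n_samples, cfg$max_seconds,
                             cfg$in_channels, cfg$target)
    probs <- net_forward(model, red$data)
    C <- dim(probs)[1L]
    small <- array(max.col(t(matrix(probs, nrow = C))) - 1L, cfg$target)
  }
  mask_crop <- resample3d(array(as.double(small), dim(small)),
                          bbox_shape(b), 1L)
  full <- paste_into(array(as.integer(mask_crop > 0.5), bbox_shape(b)),
                     b, canvas)
  kidney_mask(full)
}
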