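test_that("localiser forward obeys the shape contract and rejects bad sizes", {
  cfg <- smoke_rb_config()
  m <- build_rb_unet(cfg)
  x <- array(runif(5 * 32^3, 0, 255), c(5, 32, 32, 32))
  p <- net_forward(m, x)
  expect_equal(dim(p), c(3, 32, 32, 32))
  expect_lt(max(abs(colSums(matrix(p, nrow = 3)) - 1)), 1e-9)

  bad <- array(0, c(5, 24, 24, 24))  # 24 not divisible by 16
  expect_error(net_forward(m, bad), "divisible by 16")
})

test_that("residual shortcuts are live paths through the network", {
  cfg <- rb_unet_config(base_filters = 4, dropout_rate = 0,
                        target = c(16, 16, 16), init_seed = 2)
  m <- build_rb_unet(cfg)
  x <- array(runif(5 * 16^3, 0, 255), c(5, 16, 16, 16))
  p1 <- net_forward(m, x)
  m2 <- m
  for (nm in grep("\\.proj\\.w$", names(m2$params), value = TRUE)) {
    m2$params[[nm]][] <- 0
  }
  p2 <- net_forward(m2, x)
  expect_gt(max(abs(p1 - p2)), 1e-6)
})

test_that("training is connected: gradients reach the first layer", {
  cfg <- rb_unet_config(base_filters = 2, dropout_rate = 0,
                        target = c(16, 16, 16), init_seed = 3)
  m <- build_rb_unet(cfg)
  x <- array(runif(5 * 16^3, 0, 255), c(5, 16, 16, 16))
  y <- array(sample(0:2, 16^3, TRUE), c(16, 16, 16))
  oh <- renalseg:::onehot_channels(y, 3)
  run <- renalseg:::with_tape({
    p <- renalseg:::model_forward_train(m, x, training = FALSE)
    renalseg:::op_wce(p, oh, array(1, c(3, 16, 16, 16)), 16^3)
  })
  grads <- renalseg:::tape_backward(run$tape, run$result)
  expect_gt(max(abs(grads[["enc1.c1.w"]])), 0)
})

test_that("weighted cross-entropy matches a hand-summed oracle", {
  # uniform p = 0.5 with unit weights: every (voxel, channel) term is log 2
  y <- array(sample(0:1, 8, TRUE), c(2, 2, 2))
  p <- array(0.5, c(2, 2, 2, 2))
  expect_equal(weighted_cross_entropy(p, y, c(1, 1)), 2 * log(2))

  # direct per-voxel summation on a random 2x2x2 tensor
  set.seed(8)
  praw <- array(runif(2 * 8, 0.05, 0.95), c(2, 2, 2, 2))
  w <- c(1, 3.5)
  manual <- 0
  for (z in 1:2) for (yy in 1:2) for (xx in 1:2) {
    truth <- y[z, yy, xx]
    for (ch in 1:2) {
      yi <- as.numeric(truth == ch - 1)
      pi <- praw[ch, z, yy, xx]
      manual <- manual - w[truth + 1] * (yi * log(pi) + (1 - yi) * log(1 - pi))
    }
  }
  manual <- manual / 8
  expect_equal(weighted_cross_entropy(praw, y, w), manual, tolerance = 1e-12)

  # doubling the minority-class weight doubles that class's contribution
  w1 <- weighted_cross_entropy(praw, y, c(0, 1))  # class-1 voxels only
  w2 <- weighted_cross_entropy(praw, y, c(0, 2))
  expect_equal(w2, 2 * w1, tolerance = 1e-12)
})

test_that("oracle localisation produces containing boxes and flags absences", {
  ph <- tiny_phantom(seed = 1)
  cfg <- rb_unet_config(base_filters = 4, target = c(32, 32, 32),
                        n_samples = 12)
  lab3 <- array(0L, dim(ph$labels$data))
  lab3[ph$right_mask$data == 1] <- 1L
  lab3[ph$left_mask$data == 1] <- 2L
  boxes <- predict_boxes(oracle_localizer(lab3, cfg), ph$series)
  for (side in c("right", "left")) {
    b <- boxes[[side]]
    expect_true(b$present)
    truth <- compute_bounding_box(ph[[paste0(side, "_mask")]])
    expect_true(b$zmin <= truth$zmin && b$zmax >= truth$zmax)
    expect_true(b$ymin <= truth$ymin && b$ymax >= truth$ymax)
    expect_true(b$xmin <= truth$xmin && b$xmax >= truth$xmax)
  }

  mk <- tiny_phantom(seed = 3, abnormality = "missing_kidney")
  lab1 <- array(0L, dim(mk$labels$data))
  lab1[mk$right_mask$data == 1] <- 1L
  lab1[mk$left_mask$data == 1] <- 2L
  boxes <- predict_boxes(oracle_localizer(lab1, cfg), mk$series)
  absent_side <- if (sum(mk$left_mask$data) == 0) "left" else "right"
  expect_false(boxes[[absent_side]]$present)
  b <- boxes[[absent_side]]
  expect_equal(c(b$zmin, b$zmax, b$ymin, b$ymax, b$xmin, b$xmax),
               c(1, 1, 1, 1, 1, 1))
})

test_that("coarse-to-original box mapping scales by the downsampling factor", {
  # labels occupy exactly one downsampled cell: original box = one factor
  cfg <- rb_unet_config(target = c(16, 16, 16))
  lab <- array(0L, c(32, 32, 32))  # factor 2 per axis
  lab[1:2, 3:4, 5:6] <- 1L
  s <- dce_series(array(runif(2 * 32^3, 1, 2), c(2, 32, 32, 32)), times = 1:2)
  boxes <- predict_boxes(oracle_localizer(lab, cfg), s)
  b <- boxes$right
  expect_equal(c(b$zmax - b$zmin, b$ymax - b$ymin, b$xmax - b$xmin) + 1,
               c(2, 2, 2))
  expect_true(b$zmin <= 1 && b$zmax >= 2 && b$ymin <= 3 && b$ymax >= 4 &&
              b$xmin <= 5 && b$xmax >= 6)
})

test_that("left/right class split follows the mid-x plane", {
  ph <- tiny_phantom(seed = 1)
  whole <- kidney_mask((ph$left_mask$data | ph$right_mask$data) * 1L)
  lab <- split_left_right(whole)
  expect_identical(lab == 1L, ph$right_mask$data == 1L)
  expect_identical(lab == 2L, ph$left_mask$data == 1L)
})
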