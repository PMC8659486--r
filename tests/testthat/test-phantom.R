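test_that("enhancement curves are baseline-anchored, peak on time, and order correctly", {
  kin <- phantom_config()$kinetics
  expect_equal(enhancement_curve("cortex", 0, kin), kin$cortex$baseline)
  expect_equal(enhancement_curve("cortex", kin$cortex$ttp, kin),
               kin$cortex$baseline + kin$cortex$amplitude)
  expect_equal(enhancement_curve("medulla", kin$medulla$ttp, kin),
               kin$medulla$baseline + kin$medulla$amplitude)

  grid <- seq(0, 360, by = 0.5)
  cor <- enhancement_curve("cortex", grid, kin)
  med <- enhancement_curve("medulla", grid, kin)
  expect_lt(grid[which.max(cor)], grid[which.max(med)])

  bad <- kin; bad$cortex$amplitude <- -1
  expect_error(enhancement_curve("cortex", 10, bad), "amplitude")
})

test_that("generated phantoms have consistent geometry and ground truth", {
  ph <- tiny_phantom(seed = 1)
  expect_setequal(unique(as.vector(ph$labels$data)), c(0L, 1L, 2L))
  expect_gt(sum(ph$left_mask$data), 0)
  expect_gt(sum(ph$right_mask$data), 0)

  union <- ph$left_mask$data | ph$right_mask$data
  expect_identical(ph$labels$data > 0, union == 1)

  # every medulla voxel has a cortex voxel within cortex_thickness + 1
  # (Chebyshev); spot-check a sample of medulla voxels
  r <- ph$config$cortex_thickness + 1
  med <- which(ph$labels$data == 1, arr.ind = TRUE)
  set.seed(9)
  d <- dim(ph$labels$data)
  for (i in sample(nrow(med), 50)) {
    v <- med[i, ]
    zz <- max(1, v[1] - r):min(d[1], v[1] + r)
    yy <- max(1, v[2] - r):min(d[2], v[2] + r)
    xx <- max(1, v[3] - r):min(d[3], v[3] + r)
    expect_true(any(ph$labels$data[zz, yy, xx] == 2))
  }
})

test_that("phantoms are bit-deterministic under a fixed seed", {
  cfg <- phantom_config(shape = c(12, 32, 32), n_frames = 6, noise_sigma = 1.5,
                        seed = 77)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$labels$data, b$labels$data)
})

test_that("cortex outshines medulla at the cortical peak in noise-free phantoms", {
  ph <- tiny_phantom(seed = 2)
  tpk <- which.min(abs(ph$series$times - ph$config$kinetics$cortex$ttp))
  frame <- ph$series$data[tpk, , , ]
  expect_gt(mean(frame[ph$labels$data == 2]), mean(frame[ph$labels$data == 1]))
})

test_that("abnormal variants alter the expected structures", {
  mk <- tiny_phantom(seed = 3, abnormality = "missing_kidney")
  empties <- c(left = sum(mk$left_mask$data) == 0,
               right = sum(mk$right_mask$data) == 0)
  expect_equal(sum(empties), 1L)

  dp <- generate_phantom(phantom_config(shape = c(16, 40, 40), n_frames = 6,
                                        noise_sigma = 0, seed = 4,
                                        abnormality = "dilated_pelvis"))
  expect_setequal(unique(as.vector(dp$labels$data)), c(0L, 1L, 2L))
})

test_that("artefacts behave as configured", {
  ph <- generate_phantom(phantom_config(shape = c(10, 24, 24), n_frames = 4,
                                        kidney_axes = c(3, 5, 3),
                                        cortex_thickness = 1.5,
                                        noise_sigma = 0, seed = 5))
  cfg0 <- ph$config
  expect_identical(add_artefacts(ph$series, cfg0)$data, ph$series$data)

  cfg_b <- ph$config
  cfg_b$blur_sigma <- 1
  blurred <- add_artefacts(ph$series, cfg_b)
  for (t in 1:4) {
    m0 <- mean(ph$series$data[t, , , ])
    expect_lt(abs(mean(blurred$data[t, , , ]) - m0) / m0, 0.01)
  }

  cfg_s <- cfg0
  cfg_s$streak_amplitude <- 5
  set.seed(1)
  streaked <- add_artefacts(ph$series, cfg_s)
  bg <- ph$labels$data == 0
  for (t in 1:4) {
    # streaks inject structured signal into the formerly uniform background
    expect_gt(var(streaked$data[t, , , ][bg]),
              var(ph$series$data[t, , , ][bg]))
    expect_gt(max(abs(streaked$data[t, , , ] - ph$series$data[t, , , ])), 1)
  }
})

test_that("phantom cases round-trip through disk", {
  ph <- generate_phantom(phantom_config(shape = c(10, 24, 24), n_frames = 4,
                                        kidney_axes = c(3, 5, 3),
                                        cortex_thickness = 1.5,
                                        noise_sigma = 0, seed = 6))
  dir <- tempfile()
  write_phantom(ph, dir)
  s <- read_dce(file.path(dir, "series.nii.gz"))
  expect_equal(s$data, ph$series$data)
  expect_identical(read_volume3d(file.path(dir, "labels.nii.gz")),
                   ph$labels$data)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
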