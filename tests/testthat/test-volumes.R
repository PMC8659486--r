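test_that("NIfTI round trip preserves data and reorders axes canonically", {
  arr <- array(as.double(seq_len(4 * 5 * 3 * 2)), c(2, 3, 4, 5)) # t,z,y,x
  s <- dce_series(arr, times = c(10, 20), spacing = c(3, 1.25, 1.25))
  f <- tempfile(fileext = ".nii.gz")
  write_dce(s, f)
  s2 <- read_dce(f)
  expect_identical(dim(s2$data), dim(s$data))
  expect_equal(s2$data, s$data)
  expect_equal(s2$times, s$times)
  expect_equal(s2$spacing, s$spacing)

  # on-disk (x,y,z,t) maps to in-memory (t,z,y,x)
  raw <- as.array(RNifti::readNifti(f))
  expect_equal(dim(raw), c(5, 4, 3, 2))
  expect_equal(raw[3, 2, 1, 2], s$data[2, 1, 2, 3])
})

test_that("single-voxel series and 3D files are handled", {
  s <- dce_series(array(7, c(1, 1, 1, 1)), times = 1)
  expect_equal(dim(s$data), c(1, 1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_volume3d(array(1L, c(2, 2, 2)), f)
  expect_error(read_dce(f), "3D")
})

test_that("series validation rejects malformed input", {
  expect_error(dce_series(array(-1, c(1, 2, 2, 2)), 1), ">= 0")
  expect_error(dce_series(array(1, c(2, 2, 2, 2)), c(2, 1)), "increasing")
  expect_error(dce_series(array(1, c(2, 2, 2, 2)), c(1)), "frames")
})

test_that("bounding boxes are tight and encode missing kidneys", {
  m <- array(0L, c(8, 8, 8))
  m[3, 5, 7] <- 1L
  b <- compute_bounding_box(m)
  expect_true(b$present)
  expect_equal(c(b$zmin, b$zmax, b$ymin, b$ymax, b$xmin, b$xmax),
               c(3, 3, 5, 5, 7, 7))

  full <- compute_bounding_box(array(1L, c(8, 8, 8)))
  expect_equal(c(full$zmin, full$zmax), c(1, 8))
  expect_equal(c(full$ymin, full$ymax), c(1, 8))
  expect_equal(c(full$xmin, full$xmax), c(1, 8))

  empty <- compute_bounding_box(array(0L, c(4, 4, 4)))
  expect_false(empty$present)
  expect_equal(c(empty$zmax - empty$zmin, empty$ymax - empty$ymin,
                 empty$xmax - empty$xmin), c(0, 0, 0))
})

test_that("crop and paste are mutually inverse on the foreground", {
  set.seed(42)
  arr <- array(runif(3 * 6 * 6 * 6), c(3, 6, 6, 6))
  s <- dce_series(arr, times = c(1, 2, 3))

  ident <- crop_series(s, bbox3d(1, 6, 1, 6, 1, 6))
  expect_equal(ident$data, s$data)

  b <- bbox3d(1, 2, 1, 2, 1, 2)
  cs <- crop_series(dce_series(array(runif(2 * 4 * 4 * 4), c(2, 4, 4, 4)),
                               times = 1:2), b)
  expect_equal(dim(cs$data), c(2, 2, 2, 2))

  # round trip: crop a mask, paste into zeros, foreground restored in place
  m <- array(0L, c(6, 6, 6))
  m[2:4, 3:5, 2:3] <- 1L
  box <- compute_bounding_box(m)
  cm <- crop_volume(m, box)
  back <- paste_into(cm, box, c(6, 6, 6))
  expect_identical(back, m)

  expect_error(crop_series(s, bbox3d(1, 1, 1, 1, 1, 1, present = FALSE)),
               class = "kidney_absent")
})

test_that("paste_into places labels at the box offset without spill", {
  lab <- array(5L, c(1, 1, 1))
  out <- paste_into(lab, bbox3d(1, 1, 1, 1, 1, 1), c(3, 3, 3))
  expect_equal(sum(out != 0), 1)
  expect_equal(out[1, 1, 1], 5L)

  # identity paste
  v <- array(1:8, c(2, 2, 2))
  expect_equal(paste_into(v, bbox3d(1, 2, 1, 2, 1, 2), c(2, 2, 2)), v)

  # two disjoint boxes build the union
  a <- array(1L, c(2, 2, 2)); b <- array(2L, c(2, 2, 2))
  canvas <- paste_into(a, bbox3d(1, 2, 1, 2, 1, 2), c(6, 6, 6)) +
    paste_into(b, bbox3d(5, 6, 5, 6, 5, 6), c(6, 6, 6))
  manual <- array(0L, c(6, 6, 6))
  manual[1:2, 1:2, 1:2] <- 1L
  manual[5:6, 5:6, 5:6] <- 2L
  expect_equal(canvas, manual)

  expect_error(paste_into(array(1, c(2, 2, 2)), bbox3d(1, 3, 1, 2, 1, 2),
                          c(4, 4, 4)), "extent")

  # bounding box of a pasted volume is contained in the paste box
  box <- bbox3d(2, 3, 3, 4, 1, 2)
  pasted <- paste_into(array(1L, c(2, 2, 2)), box, c(6, 6, 6))
  nb <- compute_bounding_box(pasted)
  expect_true(nb$zmin >= box$zmin && nb$zmax <= box$zmax &&
              nb$ymin >= box$ymin && nb$ymax <= box$ymax &&
              nb$xmin >= box$xmin && nb$xmax <= box$xmax)
})

test_that("a directory of per-timepoint volumes reads as one series", {
  dir <- tempfile(); dir.create(dir)
  set.seed(6)
  arr <- array(round(runif(3 * 2 * 3 * 4) * 100), c(3, 2, 3, 4))
  for (t in 1:3) {
    write_volume3d(array(arr[t, , , ], c(2, 3, 4)),
                   file.path(dir, sprintf("frame_%02d.nii.gz", t)))
  }
  jsonlite::write_json(list(times = c(5, 15, 40), spacing = c(3, 1, 1)),
                       file.path(dir, "times.json"), auto_unbox = FALSE)
  s <- read_dce(dir)
  expect_equal(s$data, arr)
  expect_equal(s$times, c(5, 15, 40))
  expect_equal(s$spacing, c(3, 1, 1))
})

test_that("integer label volumes round-trip bit-exactly through NIfTI", {
  lab <- array(sample(0:2, 4^3, TRUE), c(4, 4, 4))
  f <- tempfile(fileext = ".nii.gz")
  write_volume3d(lab, f)
  expect_identical(read_volume3d(f), array(as.integer(lab), dim(lab)))
})
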