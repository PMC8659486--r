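test_that("temporal resampling is exact for affine-in-time signals", {
  # constant series stays constant on any grid
  const <- dce_series(array(3, c(4, 2, 2, 2)), times = c(5, 30, 100, 200))
  rs <- resample_temporal(const, n_samples = 7, max_seconds = 250)
  expect_true(all(abs(rs$data - 3) < 1e-12))
  expect_equal(length(rs$times), 7)

  # linear voxel signal v(t) = 2 t is reproduced exactly inside the range
  times <- c(2, 9, 17, 40)
  arr <- array(0, c(4, 1, 1, 1))
  arr[, 1, 1, 1] <- 2 * times
  lin <- dce_series(arr, times = times)
  rs <- resample_temporal(lin, n_samples = 4, max_seconds = 40)
  expect_equal(rs$times, c(10, 20, 30, 40))
  expect_equal(as.vector(rs$data[1, 1, 1, 1]), 20)
  expect_equal(as.vector(rs$data[4, 1, 1, 1]), 80)

  # irregular acquisition standardised to 50 frames over 5 minutes
  set.seed(3)
  irr_times <- sort(runif(17, 1, 340))
  irr <- dce_series(array(runif(17 * 8), c(17, 2, 2, 2)), times = irr_times)
  rs <- resample_temporal(irr, n_samples = 50, max_seconds = 300)
  expect_equal(dim(rs$data)[1], 50)
  expect_equal(diff(rs$times), rep(6, 49))
  expect_equal(max(rs$times), 300)

  expect_error(resample_temporal(dce_series(array(1, c(1, 1, 1, 1)), 1), 5),
               "2 frames")
})

test_that("PCA reduction matches an independent SVD oracle", {
  set.seed(11)
  d <- c(8, 5, 6, 4)  # T=8
  arr <- array(rnorm(prod(d)), d)
  s <- dce_series(abs(arr), times = 1:8)
  red <- pca_reduce(s, n_components = 5)

  # oracle: singular values of the centred voxel x time matrix
  X <- matrix(aperm(s$data, c(2, 3, 4, 1)), ncol = 8)
  Xc <- X - rowMeans(X)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  evr_oracle <- sv^2 / sum(sv^2)
  expect_lt(max(abs(red$explained_variance_ratio - evr_oracle[1:5])), 1e-6)
  expect_true(all(diff(red$explained_variance_ratio) <= 1e-12))
})

test_that("rank-1 temporal structure is fully captured by one component", {
  pattern <- c(0, 1, 3, 2, 1, 0.5)
  set.seed(4)
  scale <- array(runif(4 * 4 * 4, 0.5, 2), c(4, 4, 4))
  arr <- array(0, c(6, 4, 4, 4))
  for (t in 1:6) arr[t, , , ] <- pattern[t] * scale
  s <- dce_series(arr, times = 1:6)
  red <- pca_reduce(s, n_components = 3)
  expect_gt(red$explained_variance_ratio[1], 1 - 1e-10)
})

test_that("degenerate zero-variance input does not crash PCA", {
  s <- dce_series(array(5, c(4, 3, 3, 3)), times = 1:4)
  red <- pca_reduce(s, n_components = 3)
  expect_equal(red$explained_variance_ratio, rep(0, 3))
  expect_true(all(is.finite(red$data)))
})

test_that("spatial resampling is identity at matching size and recovers shapes", {
  v <- array(runif(4^3), c(4, 4, 4))
  expect_equal(downsample_spatial(v, c(4, 4, 4)), v)
  expect_equal(unique(as.vector(downsample_spatial(array(2, c(6, 6, 6)),
                                                   c(3, 3, 3)))), 2)
  # ball survives a down/up round trip with high overlap
  n <- 48
  ball <- array(0, c(n, n, n))
  cc <- (n + 1) / 2
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  ball[(g$z - cc)^2 + (g$y - cc)^2 + (g$x - cc)^2 <= (n / 3)^2] <- 1
  down <- downsample_spatial(ball, c(n / 2, n / 2, n / 2))
  up <- downsample_spatial(down, c(n, n, n))
  expect_gte(dsc(ball > 0, up > 0.5), 0.9)
})

test_that("rescale_to_255 spans the full range and zeroes constants", {
  v <- array(runif(27, 10, 20), c(3, 3, 3))
  r <- rescale_to_255(v)
  expect_equal(min(r), 0)
  expect_equal(max(r), 255)
  expect_equal(rescale_to_255(array(7, c(2, 2, 2))), array(0, c(2, 2, 2)))
  keep <- array(seq(0, 255, length.out = 8), c(2, 2, 2))
  expect_equal(rescale_to_255(keep), keep)
})

test_that("augmentation shifts exactly, stays in range, and is seeded", {
  x <- array(0, c(1, 8, 8, 8))
  y <- array(0L, c(8, 8, 8))
  y[4, 4, 4] <- 1L
  x[1, 4, 4, 4] <- 1
  out <- apply_augmentation(list(x = x, y = y), translation = c(1, 0, 0))
  expect_equal(which(out$y == 1, arr.ind = TRUE)[1, ], c(dim1 = 5, dim2 = 4, dim3 = 4))
  expect_equal(out$x[1, 5, 4, 4], 1)

  smp <- list(x = array(runif(8^3), c(1, 8, 8, 8)), y = y)
  a <- augment_sample(smp, seed = 5)
  b <- augment_sample(smp, seed = 5)
  expect_identical(a, b)

  mags <- sapply(1:100, function(s)
    abs(attr(augment_sample(smp, seed = s), "transform")$translation))
  expect_true(all(mags >= 1 & mags <= 4))
})

test_that("full preprocessing emits the network input contract", {
  ph <- train_phantom(1)
  red <- preprocess_series(ph$series, n_samples = 10, max_seconds = 300,
                           n_components = 5, target = c(32, 32, 32))
  expect_equal(dim(red$data), c(5, 32, 32, 32))
  for (c in 1:5) {
    expect_equal(min(red$data[c, , , ]), 0)
    expect_equal(max(red$data[c, , , ]), 255)
  }
  expect_true(all(diff(red$explained_variance_ratio) <= 1e-12))
})
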