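test_that("depth cleaning repairs sentinel pixels by iterated 3x3 median", {
  cfg <- preprocess_config(depth_clip = c(0, 10), pad_to = c(6L, 6L))
  x <- matrix(3, 6, 6)
  expect_equal(clean_depth(x, cfg), x)              # identity case
  x1 <- x
  x1[3, 4] <- 0                                      # single no-return pixel
  expect_equal(clean_depth(x1, cfg), x)
  # checkerboard of sentinels over a constant: every pixel repaired to c
  cb <- matrix(5, 8, 8)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 0
  cfg8 <- preprocess_config(depth_clip = c(0, 10), pad_to = c(8L, 8L))
  expect_equal(clean_depth(cb, cfg8), matrix(5, 8, 8))
  expect_error(clean_depth(matrix(0, 4, 4), cfg), class = "afn_input_error")
  # clipping and crop/pad to the model input shape
  cfgp <- preprocess_config(depth_clip = c(2, 4), pad_to = c(10L, 10L))
  out <- clean_depth(matrix(6, 6, 6), cfgp)
  expect_equal(dim(out), c(10L, 10L))
  expect_true(all(out == 4))
})

test_that("pressure preprocessing preserves constants, matches a directly built Gaussian kernel on an impulse, and conserves block means", {
  cfg <- preprocess_config()
  cst <- matrix(2.5, 27, 64)
  expect_equal(preprocess_pressure(cst, cfg), cst, tolerance = 1e-12)
  # impulse response at the center equals the peak of the discrete kernel
  imp <- matrix(0, 27, 64)
  imp[14, 32] <- 1
  sm <- preprocess_pressure(imp, cfg)
  k1 <- attnfnet:::gaussian_kernel1d(1.4, radius = ceiling(4 * 1.4))
  expect_equal(sm[14, 32], max(k1)^2, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)   # interior mass is conserved
  # integer-factor area downscale equals brute-force block averaging
  set.seed(4)
  big <- matrix(runif(54 * 128), 54, 128)
  ds <- attnfnet:::area_resample(big, c(27, 64))
  brute <- matrix(0, 27, 64)
  for (i in 1:27) for (j in 1:64) {
    brute[i, j] <- mean(big[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(ds, brute, tolerance = 1e-12)
  expect_equal(sum(ds), sum(big) / 4, tolerance = 1e-9)
  expect_error(preprocess_pressure(matrix(-1, 27, 64)),
               class = "afn_input_error")
  # shape idempotence: a 27x64 input stays 27x64
  expect_equal(dim(preprocess_pressure(matrix(runif(27 * 64), 27, 64))),
               c(27L, 64L))
})

test_that("min-max normalization maps bounds to range ends, round-trips, and rejects non-train statistics", {
  set.seed(5)
  imgs <- lapply(1:3, function(i) matrix(runif(20, 1, 3), 4, 5))
  st <- compute_norm_stats(imgs)
  lo_img <- matrix(st$min, 2, 2)
  hi_img <- matrix(st$max, 2, 2)
  expect_true(all(normalize_image(lo_img, st, c(-1, 1)) == -1))
  expect_true(all(normalize_image(hi_img, st, c(-1, 1)) == 1))
  x <- imgs[[2]]
  expect_equal(denormalize_image(normalize_image(x, st, c(-1, 1)), st, c(-1, 1)),
               x, tolerance = 1e-6)
  st_bad <- compute_norm_stats(imgs, provenance = "val")
  expect_error(normalize_image(x, st_bad), class = "afn_leak_error")
  expect_error(compute_norm_stats(list(matrix(1, 2, 2))),
               class = "afn_value_error")
})

test_that("kPa calibration is elementwise and squares into the MSE scale", {
  set.seed(6)
  y <- matrix(runif(27 * 64), 27, 64)
  g <- matrix(runif(27 * 64), 27, 64)
  expect_equal(calibrate_to_kpa(y, 1), y, ignore_attr = TRUE)
  expect_equal(mse(calibrate_to_kpa(y, 2), calibrate_to_kpa(g, 2)),
               4 * mse(y, g), tolerance = 1e-12)
  z <- calibrate_to_kpa(matrix(0, 3, 3), 5)
  expect_true(all(z == 0))
  expect_identical(attr(z, "units"), "kPa")
  expect_error(calibrate_to_kpa(y, 0), class = "afn_value_error")
})

test_that("train-split statistics are reused unchanged for validation and test normalization", {
  ds <- generate_dataset(5, 3, seed = 8, grid_shape = c(32L, 24L))
  prep <- prepare_training_data(ds, preprocess_config(pad_to = c(32L, 24L)))
  expect_identical(prep$depth_stats$provenance, "train")
  expect_identical(prep$pressure_stats$provenance, "train")
  # train depth values span the full target range; val/test may exceed it
  rng <- range(unlist(prep$train$x))
  expect_equal(rng, c(-1, 1), tolerance = 1e-9)
  expect_true(all(vapply(prep$train$y, min, numeric(1)) >= 0))
})
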