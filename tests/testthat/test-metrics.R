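test_that("scalar metrics reproduce their hand-computed examples", {
  y <- c(0, 1, 2, 3)
  g <- c(0, 1.4, 2, 10)
  expect_equal(ppa(matrix(y, 1), matrix(g, 1), tol = 0.5), 0.75)
  expect_equal(ppa(matrix(y, 1), matrix(y, 1), tol = 0.5), 1)
  expect_equal(ppa(matrix(y, 1), matrix(y + 1, 1), tol = 0.5), 0)
  expect_equal(mse(matrix(c(1, 2, 3), 1), matrix(c(2, 2, 5), 1)), 5 / 3)
  expect_equal(mse(matrix(0, 2, 1), matrix(1, 2, 1)), 1)
  expect_equal(psnr(matrix(c(0, 0.2), 1), matrix(c(0.1, 0.3), 1), 1), 20)
  expect_equal(psnr(matrix(c(0, 1), 1), matrix(c(1, 2), 1), 1), 0)
  expect_true(is.infinite(psnr(matrix(1, 2, 2), matrix(1, 2, 2), 1)))
  # halving the mse adds 10 log10(2) dB
  y8 <- matrix(runif(64), 8, 8)
  g8 <- y8 + 0.1
  g4 <- y8 + 0.1 / sqrt(2)
  expect_equal(psnr(y8, g4, 1) - psnr(y8, g8, 1), 10 * log10(2),
               tolerance = 1e-9)
})

test_that("scalar metrics agree with naive loop oracles on random inputs", {
  set.seed(51)
  for (i in 1:20) {
    y <- matrix(runif(100), 10, 10)
    g <- matrix(runif(100), 10, 10)
    tol <- runif(1, 0.05, 0.5)
    expect_equal(ppa(y, g, tol), oracle_ppa(y, g, tol), tolerance = 1e-12)
    expect_equal(mse(y, g), oracle_mse(y, g), tolerance = 1e-12)
    expect_equal(psnr(y, g, 1), oracle_psnr(y, g, 1), tolerance = 1e-9)
    thr <- runif(1, 0.3, 0.7)
    expect_equal(as.numeric(posture_iou(y, g, thr)), oracle_iou(y, g, thr),
                 tolerance = 1e-12)
  }
})

test_that("posture IOU keeps only the largest 4-connected components and handles empty maps", {
  y <- matrix(0, 8, 8)
  y[3:4, 3:4] <- 2            # 2x2 component
  y[7, 7] <- 2                # smaller, must be discarded
  g <- matrix(0, 8, 8)
  g[3:4, 4:5] <- 2            # same square shifted one column
  expect_equal(as.numeric(posture_iou(y, g, 1)), 1 / 3)
  expect_equal(as.numeric(posture_iou(y, y, 1)), 1)
  g2 <- matrix(0, 8, 8)
  g2[1:2, 1:2] <- 2
  expect_equal(as.numeric(posture_iou(y, g2, 1)), 0)   # disjoint
  z <- matrix(0, 8, 8)
  r <- posture_iou(z, z, 1)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "empty"))
  expect_equal(as.numeric(posture_iou(y, z, 1)), 0)
  # diagonal touching is NOT 4-connected: two diagonal cells are separate
  dd <- matrix(0, 4, 4)
  dd[1, 1] <- 2
  dd[2, 2] <- 2
  dd[3:4, 3:4] <- 2
  comp <- attnfnet:::largest_component(dd > 1)
  expect_equal(sum(comp), 4)
  # invariance under monotone rescaling preserving the threshold crossings
  set.seed(52)
  a <- matrix(runif(64, 0, 2), 8, 8)
  b <- matrix(runif(64, 0, 2), 8, 8)
  i1 <- as.numeric(posture_iou(a, b, 1))
  i2 <- as.numeric(posture_iou(a^3, b^3, 1))   # x^3 crosses 1 where x does
  expect_equal(i1, i2)
})

test_that("Frechet distance is zero on identical sets, symmetric, and matches closed forms", {
  set.seed(53)
  imgs <- lapply(1:6, function(i) matrix(runif(27 * 64), 27, 64))
  emb <- random_projection_embedder()
  expect_lt(frechet_distance(imgs, imgs, emb), 1e-6)
  other <- lapply(imgs, function(m) m + 0.3)
  d12 <- frechet_distance(imgs, other, emb)
  expect_equal(d12, frechet_distance(other, imgs, emb), tolerance = 1e-6)
  expect_gt(d12, 0)
  # 1-d features with means 0 and 1, unit variances -> distance exactly 1
  f1 <- list(-1, 0, 1)   # mean 0, var 1
  f2 <- list(0, 1, 2)    # mean 1, var 1
  id_emb <- function(v) as.numeric(v)
  expect_equal(frechet_distance(lapply(f1, matrix), lapply(f2, matrix),
                                id_emb), 1, tolerance = 1e-9)
  # against the svd-based oracle on random feature sets
  fa <- lapply(1:8, function(i) matrix(runif(12), 3, 4))
  fb <- lapply(1:8, function(i) matrix(runif(12) + 0.2, 3, 4))
  emb4 <- function(m) as.vector(m[1:2, 1:2])
  expect_equal(frechet_distance(fa, fb, emb4),
               oracle_frechet(t(sapply(fa, emb4)), t(sapply(fb, emb4))),
               tolerance = 1e-6)
  expect_error(frechet_distance(imgs[1], imgs, emb), class = "afn_input_error")
})

test_that("weight estimation integrates calibrated pressure into kilograms", {
  u <- matrix(1, 27, 64)
  expect_equal(estimate_weight(u, 0.001), 1728 * 1000 * 0.001 / 9.81,
               tolerance = 1e-12)
  expect_equal(estimate_weight(u, 0.001), 176.1468, tolerance = 1e-4)
  expect_equal(estimate_weight(matrix(0, 27, 64)), 0)
  expect_equal(estimate_weight(2 * u, 0.001), 2 * estimate_weight(u, 0.001))
  expect_error(estimate_weight(matrix(-1, 2, 2)), class = "afn_value_error")
})

test_that("deviation maps average absolute errors per posture", {
  y1 <- matrix(1, 27, 64)
  g1 <- matrix(1.5, 27, 64)
  y2 <- matrix(2, 27, 64)
  expect_warning(
    dm <- deviation_maps(list(y1, y2), list(g1, y2), c("supine", "supine")),
    "no samples")
  expect_equal(dm$supine, matrix(0.25, 27, 64), ignore_attr = TRUE)
  expect_equal(attr(dm$supine, "clip_range"), c(0, 1.5))
  dm1 <- suppressWarnings(deviation_maps(list(y1), list(g1), "lateral_left"))
  expect_equal(dm1$lateral_left, abs(y1 - g1), ignore_attr = TRUE)
})

test_that("evaluation of a ground-truth oracle is perfect and aggregates are the per-sample means", {
  ms <- micro_setup(seed = 31)
  ds <- do.call(generate_dataset, ms$data_args)
  prep <- prepare_training_data(ds, ms$pp_config)
  n_test <- length(prep$test$x)
  ys <- prep$test$y
  k <- 0
  oracle <- function_generator(function(x) {
    k <<- k + 1
    ys[[k]]
  })
  rep <- evaluate_model(oracle, prep)
  expect_equal(nrow(rep$per_sample), n_test)
  expect_equal(rep$aggregates$mppa, 1)
  expect_equal(rep$aggregates$mssim, 1, tolerance = 1e-9)
  expect_equal(rep$aggregates$mse_kpa2, 0, tolerance = 1e-15)
  expect_equal(rep$aggregates$miou, 1)
  expect_equal(rep$aggregates$n_psnr_excluded, n_test)
  expect_lt(rep$aggregates$mfid, 1e-6)
  # aggregates are arithmetic means of the per-sample table
  k <- 0
  noisy <- function_generator(function(x) {
    k <<- k + 1
    pmin(pmax(ys[[k]] + 0.03, 0), 1)
  })
  rep2 <- evaluate_model(noisy, prep)
  expect_equal(rep2$aggregates$mppa, mean(rep2$per_sample$ppa))
  expect_equal(rep2$aggregates$mssim, mean(rep2$per_sample$ssim))
  expect_equal(rep2$aggregates$mse_kpa2, mean(rep2$per_sample$mse_kpa2))
  expect_equal(rep2$aggregates$miou, mean(rep2$per_sample$iou))
  expect_equal(rep2$aggregates$mean_abs_weight_diff_kg,
               mean(rep2$per_sample$weight_err_kg))
})
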