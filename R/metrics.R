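# Evaluation metrics: pixel prediction accuracy, MSE, PSNR, posture IOU
# (largest 4-connected super-threshold components), Frechet distance with a
# pluggable feature embedder, per-posture deviation maps, weight estimation
# from calibrated pressure, and test-set aggregation.

.check_same_shape <- function(y, g) {
  if (!all(dim(y) == dim(g))) afn_stop("shape mismatch", "afn_shape_error")
}

#' Pixel prediction accuracy
#'
#' Fraction of pixels whose absolute error is within `tol` (same units as
#' `y`).
#'
#' @param y ground-truth map
#' @param g predicted map
#' @param tol absolute tolerance defining a correct pixel
#' @return scalar in `[0, 1]`
#' @export
ppa <- function(y, g, tol) {
  .check_same_shape(y, g)
  if (tol <= 0) afn_stop("tol must be positive", "afn_value_error")
  mean(abs(y - g) <= tol)
}

#' Mean squared error over all pixels
#' @param y,g maps of identical shape
#' @return nonnegative scalar
#' @export
mse <- function(y, g) {
  .check_same_shape(y, g)
  mean((y - g)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 log10(max_val^2 / MSE)`; identical images give `Inf`, which
#' aggregation excludes from means (with a count note).
#'
#' @param y,g maps of identical shape
#' @param max_val maximum possible signal value
#' @return scalar in dB (possibly `Inf`)
#' @export
psnr <- function(y, g, max_val) {
  m <- mse(y, g)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

# label 4-connected components of a logical matrix; returns the cell mask of
# the largest component (all FALSE if the input has no TRUE cell)
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  best_size <- 0L
  best <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(256L)
    queue[1L] <- start
    qn <- 1L
    lab[start] <- cur
    size <- 0L
    while (qn > 0L) {
      p <- queue[qn]
      qn <- qn - 1L
      size <- size + 1L
      i <- (p - 1L) %% h + 1L
      j <- (p - 1L) %/% h + 1L
      for (nb in c(if (i > 1L) p - 1L, if (i < h) p + 1L,
                   if (j > 1L) p - h, if (j < w) p + h)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          qn <- qn + 1L
          if (qn > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qn] <- nb
        }
      }
    }
    if (size > best_size) {
      best_size <- size
      best <- cur
    }
  }
  lab == best & best > 0L
}

#' Posture intersection-over-union
#'
#' Both maps are binarized at `threshold`; the largest 4-connected component
#' of each is kept and their IOU returned. Two empty components give 1 (with
#' attribute `empty = TRUE`); exactly one empty gives 0.
#'
#' @param y,g maps of identical shape (calibrated kPa by convention)
#' @param threshold binarization threshold
#' @return scalar in `[0, 1]`
#' @export
posture_iou <- function(y, g, threshold = 1) {
  .check_same_shape(y, g)
  ay <- largest_component(y > threshold)
  ag <- largest_component(g > threshold)
  if (!any(ay) && !any(ag)) return(structure(1, empty = TRUE))
  u <- sum(ay | ag)
  if (u == 0) return(0)
  sum(ay & ag) / u
}

#' Deterministic random-projection feature embedder
#'
#' A fixed, seeded Gaussian random projection of the flattened image — a
#' weight-free stand-in feature extractor making the Frechet distance
#' runnable offline. Any pretrained embedder (e.g. an Inception network) can
#' be injected instead for comparability with published FID values; scores
#' from this embedder are on their own scale.
#'
#' @param input_dim flattened image length (default 27 * 64)
#' @param out_dim feature dimension
#' @param seed integer seed for the projection matrix
#' @return function mapping an image matrix to a feature vector
#' @export
random_projection_embedder <- function(input_dim = 27L * 64L, out_dim = 32L,
                                       seed = 42L) {
  P <- with_seed(derive_seed(seed, "fid_embedder"), {
    matrix(stats::rnorm(out_dim * input_dim, 0, 1 / sqrt(input_dim)),
           out_dim, input_dim)
  })
  function(img) as.vector(P %*% as.vector(img))
}

# symmetric PSD square root via eigendecomposition
.sqrtm_psd <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  scale <- max(abs(e$values), 1e-12)
  if (any(e$values < -tol * scale * 100)) {
    afn_stop("matrix is not positive semi-definite beyond tolerance",
             "afn_numeric_error")
  }
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two image sets under a feature embedding
#'
#' Fits a Gaussian (mean, covariance) to the embedded features of each set
#' and returns `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))` with a
#' symmetrized matrix square root.
#'
#' @param real_set,gen_set lists of image matrices (>= 2 each)
#' @param embed_fn image -> feature vector, e.g.
#'   [random_projection_embedder()]
#' @return nonnegative scalar
#' @export
frechet_distance <- function(real_set, gen_set,
                             embed_fn = random_projection_embedder()) {
  if (length(real_set) < 2 || length(gen_set) < 2) {
    afn_stop("both sets need at least 2 samples", "afn_input_error")
  }
  f1 <- do.call(rbind, lapply(real_set, function(m) as.numeric(embed_fn(m))))
  f2 <- do.call(rbind, lapply(gen_set, function(m) as.numeric(embed_fn(m))))
  mu1 <- colMeans(f1); mu2 <- colMeans(f2)
  s1 <- stats::cov(f1); s2 <- stats::cov(f2)
  r1 <- .sqrtm_psd(s1)
  mid <- .sqrtm_psd(r1 %*% s2 %*% r1)
  d <- sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(diag(mid))
  max(d, 0)
}

#' Estimate body weight from a calibrated pressure map
#'
#' Total normal force on the mattress divided by g:
#' `sum(p_kPa * 1000) * sensor_area_m2 / 9.81`.
#'
#' @param pressure_kpa pressure map in kPa (nonnegative)
#' @param sensor_area_m2 area of one sensor cell
#' @param g gravitational acceleration
#' @return estimated mass in kg
#' @export
estimate_weight <- function(pressure_kpa, sensor_area_m2 = default_sensor_area(),
                            g = 9.81) {
  if (any(pressure_kpa < 0)) {
    afn_stop("pressure must be nonnegative", "afn_value_error")
  }
  sum(pressure_kpa * 1000) * sensor_area_m2 / g
}

#' Per-posture mean absolute deviation maps
#'
#' For each posture, the pixelwise mean of `|y - g|` over its pairs, in kPa.
#' The attribute `clip_range = c(0, 1.5)` records the rendering convention.
#'
#' @param ys,gs lists of calibrated ground-truth / predicted maps
#' @param postures character vector of posture labels, one per pair
#' @return named list posture -> deviation matrix; empty groups are omitted
#'   with a warning
#' @export
deviation_maps <- function(ys, gs, postures) {
  out <- list()
  for (p in unique(postures)) {
    idx <- which(postures == p)
    if (length(idx) == 0) next
    acc <- Reduce(`+`, lapply(idx, function(i) abs(ys[[i]] - gs[[i]])))
    m <- acc / length(idx)
    attr(m, "clip_range") <- c(0, 1.5)
    out[[p]] <- m
  }
  missing <- setdiff(posture_labels(), names(out))
  if (length(missing) > 0) {
    warning("no samples for posture(s): ", paste(missing, collapse = ", "))
  }
  out
}

#' Evaluate a trained generator on the test split
#'
#' Predicts every test sample, converts prediction and preprocessed ground
#' truth to kPa with the per-subject calibration, computes per-sample PPA,
#' SSIM, MSE (raw and kPa^2), PSNR, posture IOU and estimated weight, and
#' aggregates the means (FID is set-level). PSNR means exclude infinite
#' values; `n_psnr_excluded` counts them.
#'
#' @param G trained generator
#' @param prepared output of [prepare_training_data()]
#' @param ppa_tol_frac PPA tolerance as a fraction of each ground-truth
#'   map's maximum
#' @param iou_threshold binarization threshold in kPa
#' @param sensor_area_m2 sensor cell area for weight estimation
#' @param embed_fn feature embedder for the Frechet distance
#' @param ssim_pars [ssim_params()] for the kPa-domain SSIM metric
#' @return a `metric_report`: list with `per_sample` (data frame),
#'   `aggregates` (named list), `deviation_maps`
#' @export
evaluate_model <- function(G, prepared, ppa_tol_frac = 0.05,
                           iou_threshold = 1,
                           sensor_area_m2 = default_sensor_area(),
                           embed_fn = random_projection_embedder(),
                           ssim_pars = NULL) {
  te <- prepared$test
  n <- length(te$x)
  if (n == 0) afn_stop("test split is empty", "afn_input_error")
  stats_p <- prepared$pressure_stats
  rng <- prepared$config$pressure_range
  ys_kpa <- vector("list", n)
  gs_kpa <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cal <- te$meta$calibration_kpa[i]
    g_raw <- predict_pressure(G, te$x[[i]], stats_p, rng)
    y_raw <- denormalize_image(te$y[[i]], stats_p, rng)
    g_kpa <- calibrate_to_kpa(g_raw, cal)
    y_kpa <- calibrate_to_kpa(pmax(y_raw, 0), cal)
    ys_kpa[[i]] <- y_kpa
    gs_kpa[[i]] <- g_kpa
    if (is.null(ssim_pars)) {
      sp <- ssim_params(L = max(max(y_kpa), 1e-8))
    } else sp <- ssim_pars
    rows[[i]] <- data.frame(
      sample = i,
      subject_id = te$meta$subject_id[i],
      posture = te$meta$posture[i],
      ppa = ppa(y_kpa, g_kpa, tol = ppa_tol_frac * max(y_kpa)),
      ssim = ssim(y_kpa, g_kpa, sp),
      mse_raw = mse(y_raw, g_raw),
      mse_kpa2 = mse(y_kpa, g_kpa),
      psnr = NA_real_,   # filled below with the set-level dynamic range
      iou = as.numeric(posture_iou(y_kpa, g_kpa, iou_threshold)),
      weight_true_kg = te$meta$mass_kg[i],
      weight_est_kg = estimate_weight(g_kpa, sensor_area_m2),
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, rows)
  max_val <- max(vapply(ys_kpa, max, numeric(1)))
  per_sample$psnr <- vapply(seq_len(n), function(i) {
    psnr(ys_kpa[[i]], gs_kpa[[i]], max_val)
  }, numeric(1))
  per_sample$weight_err_kg <- abs(per_sample$weight_est_kg -
                                    per_sample$weight_true_kg)
  finite_psnr <- per_sample$psnr[is.finite(per_sample$psnr)]
  aggregates <- list(
    mppa = mean(per_sample$ppa),
    mssim = mean(per_sample$ssim),
    mfid = frechet_distance(ys_kpa, gs_kpa, embed_fn),
    mse_raw = mean(per_sample$mse_raw),
    mse_kpa2 = mean(per_sample$mse_kpa2),
    mpsnr = mean(finite_psnr),
    n_psnr_excluded = n - length(finite_psnr),
    miou = mean(per_sample$iou),
    mean_abs_weight_diff_kg = mean(per_sample$weight_err_kg),
    n_test = n)
  structure(list(per_sample = per_sample, aggregates = aggregates,
                 deviation_maps = deviation_maps(ys_kpa, gs_kpa,
                                                 per_sample$posture)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("metric_report over %d test samples:\n", a$n_test))
  cat(sprintf("  MPPA %.4f  MSSIM %.4f  MSE %.6f (raw) %.4f (kPa^2)\n",
              a$mppa, a$mssim, a$mse_raw, a$mse_kpa2))
  cat(sprintf("  MPSNR %.2f dB  MIOU %.4f  MFID %.4f  mean |dW| %.2f kg\n",
              a$mpsnr, a$miou, a$mfid, a$mean_abs_weight_diff_kg))
  invisible(x)
}
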