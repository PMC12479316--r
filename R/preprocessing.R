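# Preprocessing: depth cleaning, pressure smoothing (27 x 64 downsample +
# Gaussian sigma = 1.4), min-max normalization with train-split statistics,
# and raw-to-kPa calibration.

#' Preprocessing configuration
#'
#' @param target_pressure_shape pressure grid after resampling; fixed at
#'   27 x 64 unless explicitly overridden
#' @param gaussian_sigma Gaussian smoothing sigma for pressure maps
#' @param depth_clip length-2 (low, high) clip range in depth units
#' @param depth_range,pressure_range normalization target ranges for the two
#'   modalities in model units
#' @param pad_to model input shape; depth images are cropped/edge-padded to
#'   this so the patch grid divides evenly
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(target_pressure_shape = c(27L, 64L),
                              gaussian_sigma = 1.4,
                              depth_clip = c(0.5, 2.5),
                              depth_range = c(-1, 1),
                              pressure_range = c(0, 1),
                              pad_to = c(128L, 56L)) {
  if (gaussian_sigma <= 0) afn_stop("gaussian_sigma must be > 0", "afn_value_error")
  if (depth_clip[1] >= depth_clip[2]) afn_stop("bad depth_clip", "afn_value_error")
  structure(list(target_pressure_shape = as.integer(target_pressure_shape),
                 gaussian_sigma = gaussian_sigma, depth_clip = depth_clip,
                 depth_range = depth_range, pressure_range = pressure_range,
                 pad_to = as.integer(pad_to)),
            class = "preprocess_config")
}

# center-crop or edge-pad a matrix to a target shape
crop_pad_to <- function(x, shape) {
  h <- nrow(x); w <- ncol(x)
  th <- shape[1]; tw <- shape[2]
  if (h > th) {
    off <- (h - th) %/% 2L
    x <- x[off + seq_len(th), , drop = FALSE]
  }
  if (w > tw) {
    off <- (w - tw) %/% 2L
    x <- x[, off + seq_len(tw), drop = FALSE]
  }
  h <- nrow(x); w <- ncol(x)
  if (h < th) {
    top <- (th - h) %/% 2L
    x <- rbind(matrix(rep(x[1, ], top), top, w, byrow = TRUE), x,
               matrix(rep(x[h, ], th - h - top), th - h - top, w, byrow = TRUE))
  }
  if (w < tw) {
    left <- (tw - w) %/% 2L
    x <- cbind(matrix(rep(x[, 1], left), th, left), x,
               matrix(rep(x[, w], tw - w - left), th, tw - w - left))
  }
  x
}

#' Clean a raw depth image
#'
#' No-return pixels (the sentinel value, NA or non-finite) are repaired by
#' the median of their valid 3 x 3 neighbourhood, iterated until none
#' remain; values are then clipped to `config$depth_clip` and the image is
#' center-cropped / edge-padded to `config$pad_to`.
#'
#' @param raw depth matrix
#' @param config a [preprocess_config()]
#' @param sentinel no-return sentinel value (camera convention: 0)
#' @return cleaned depth matrix of shape `config$pad_to`
#' @export
clean_depth <- function(raw, config = preprocess_config(), sentinel = 0) {
  x <- raw
  invalid <- !is.finite(x) | x == sentinel
  if (all(invalid)) {
    afn_stop("depth image is entirely sentinel/no-return", "afn_input_error")
  }
  h <- nrow(x); w <- ncol(x)
  while (any(invalid)) {
    idx <- which(invalid, arr.ind = TRUE)
    repaired <- FALSE
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      ri <- max(1, i - 1):min(h, i + 1)
      cj <- max(1, j - 1):min(w, j + 1)
      nb <- x[ri, cj]
      ok <- !invalid[ri, cj]
      if (any(ok)) {
        x[i, j] <- stats::median(nb[ok])
        invalid[i, j] <- FALSE
        repaired <- TRUE
      }
    }
    if (!repaired) break
  }
  x <- pmin(pmax(x, config$depth_clip[1]), config$depth_clip[2])
  crop_pad_to(x, config$pad_to)
}

#' Preprocess a pressure map (PPress)
#'
#' Area-average resampling to the target 27 x 64 grid followed by a Gaussian
#' blur (default sigma 1.4, truncated at 4 sigma, reflect boundary); output
#' clamped to be nonnegative.
#'
#' @param pressure nonnegative pressure matrix (raw or kPa units)
#' @param config a [preprocess_config()]
#' @return smoothed pressure matrix of shape `config$target_pressure_shape`
#' @export
preprocess_pressure <- function(pressure, config = preprocess_config()) {
  if (any(pressure < 0)) {
    afn_stop("pressure values must be nonnegative", "afn_input_error")
  }
  x <- area_resample(pressure, config$target_pressure_shape)
  x <- gaussian_blur(x, config$gaussian_sigma)
  pmax(x, 0)
}

#' Compute min-max normalization statistics
#'
#' Statistics must come from the training split only; the provenance tag is
#' checked by [normalize_image()] so validation/test leakage is impossible
#' by construction.
#'
#' @param images list of matrices
#' @param provenance split the statistics were computed on
#' @return a `norm_stats` list with `min`, `max`, `provenance`
#' @export
compute_norm_stats <- function(images, provenance = "train") {
  lo <- min(vapply(images, min, numeric(1)))
  hi <- max(vapply(images, max, numeric(1)))
  if (hi <= lo) afn_stop("constant data: max equals min", "afn_value_error")
  structure(list(min = lo, max = hi, provenance = provenance),
            class = "norm_stats")
}

#' Min-max normalize an image to a target range
#' @param img matrix
#' @param stats a `norm_stats` from [compute_norm_stats()] (train split)
#' @param range length-2 target range
#' @return normalized matrix
#' @export
normalize_image <- function(img, stats, range = c(0, 1)) {
  if (!identical(stats$provenance, "train")) {
    afn_stop("normalization statistics must come from the train split",
             "afn_leak_error")
  }
  (img - stats$min) / (stats$max - stats$min) * (range[2] - range[1]) + range[1]
}

#' Invert [normalize_image()]
#' @inheritParams normalize_image
#' @return matrix on the original scale
#' @export
denormalize_image <- function(img, stats, range = c(0, 1)) {
  (img - range[1]) / (range[2] - range[1]) * (stats$max - stats$min) + stats$min
}

#' Convert raw pressure-sensor units to kPa
#' @param pressure_raw pressure matrix in raw sensor units
#' @param calibration_kpa positive per-subject raw-to-kPa multiplier
#' @return pressure matrix in kPa (attribute `units` set to "kPa")
#' @export
calibrate_to_kpa <- function(pressure_raw, calibration_kpa) {
  if (!is.numeric(calibration_kpa) || calibration_kpa <= 0) {
    afn_stop("calibration factor must be positive", "afn_value_error")
  }
  out <- pressure_raw * calibration_kpa
  attr(out, "units") <- "kPa"
  out
}

#' Preprocess and normalize a dataset for training
#'
#' Cleans and pads every depth image, applies the pressure preprocessing,
#' computes min-max statistics on the train split only, and returns
#' normalized model-unit tensors for all three splits.
#'
#' @param dataset a `synthetic_dataset` (or any list with the same schema)
#' @param config a [preprocess_config()]
#' @return list with one element per split (`x`, `y`, `meta`) plus
#'   `depth_stats`, `pressure_stats`, `config`
#' @export
prepare_training_data <- function(dataset, config = preprocess_config()) {
  splits <- c("train", "val", "test")
  cleaned <- lapply(splits, function(sp) {
    ss <- split_samples(dataset, sp)
    list(
      x = lapply(ss, function(s) clean_depth(s$depth, config)),
      y = lapply(ss, function(s) preprocess_pressure(s$pressure, config)),
      meta = data.frame(
        subject_id = vapply(ss, `[[`, character(1), "subject_id"),
        posture = vapply(ss, `[[`, character(1), "posture"),
        calibration_kpa = vapply(ss, `[[`, numeric(1), "calibration_kpa"),
        mass_kg = vapply(ss, `[[`, numeric(1), "mass_kg"),
        stringsAsFactors = FALSE)
    )
  })
  names(cleaned) <- splits
  if (length(cleaned$train$x) == 0) {
    afn_stop("train split is empty", "afn_input_error")
  }
  depth_stats <- compute_norm_stats(cleaned$train$x)
  pressure_stats <- compute_norm_stats(cleaned$train$y)
  for (sp in splits) {
    cleaned[[sp]]$x <- lapply(cleaned[[sp]]$x, normalize_image,
                              stats = depth_stats, range = config$depth_range)
    cleaned[[sp]]$y <- lapply(cleaned[[sp]]$y, normalize_image,
                              stats = pressure_stats,
                              range = config$pressure_range)
  }
  c(cleaned, list(depth_stats = depth_stats, pressure_stats = pressure_stats,
                  config = config))
}
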