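# Synthetic body-on-mattress data generator.
#
# Emulates the structure of paired overhead-depth / bed-pressure recordings:
# a smooth body-height field built from elliptical Gaussian lobes (head,
# torso, pelvis, legs, arms) is rendered to a noisy depth image and to a
# 27 x 64 pressure-sensor map whose total normal force equals body weight
# exactly, with a per-subject raw-to-kPa calibration scalar. Ground-truth
# body mass is therefore recoverable from the pressure map, which closes the
# loop with the weight-estimation metric.
#
# Grid conventions (shared by all modules):
#   depth/template grids: rows = bed length (row 1 at the head end),
#     columns = bed width; default 128 x 56.
#   pressure grids: 27 rows (bed width) x 64 columns (bed length, column 1
#     at the head end).

POSTURES <- c("supine", "lateral_left", "lateral_right")

#' Posture labels recognized by the generator
#' @return character vector of the three posture labels
#' @export
posture_labels <- function() POSTURES

#' Construct a synthetic subject
#'
#' @param subject_id character identifier
#' @param mass_kg body mass in kilograms (must be positive)
#' @param length_scale body-length multiplier in `[0.8, 1.2]`
#' @param width_scale body-width multiplier in `[0.8, 1.2]`
#' @param seed integer seed owned by this subject
#' @return a `synthetic_subject` list
#' @export
synthetic_subject <- function(subject_id, mass_kg, length_scale = 1,
                              width_scale = 1, seed = 1L) {
  if (!is.numeric(mass_kg) || mass_kg <= 0) {
    afn_stop("mass_kg must be positive", "afn_value_error")
  }
  if (length_scale < 0.8 || length_scale > 1.2 ||
      width_scale < 0.8 || width_scale > 1.2) {
    afn_stop("length/width scale must lie in [0.8, 1.2]", "afn_value_error")
  }
  structure(list(subject_id = as.character(subject_id), mass_kg = mass_kg,
                 length_scale = length_scale, width_scale = width_scale,
                 seed = as.integer(seed)),
            class = "synthetic_subject")
}

# lobe tables: centers (u along length, v across width, both in [0,1]),
# axis sds, and peak height in metres; supine is left-right symmetric, the
# lateral tables are asymmetric and mirror images of each other
.lobes_supine <- function() {
  rbind(
    head    = c(0.09, 0.50, 0.050, 0.055, 0.16),
    torso   = c(0.30, 0.50, 0.130, 0.150, 0.22),
    pelvis  = c(0.50, 0.50, 0.080, 0.130, 0.24),
    leg_l   = c(0.75, 0.42, 0.170, 0.050, 0.14),
    leg_r   = c(0.75, 0.58, 0.170, 0.050, 0.14),
    arm_l   = c(0.32, 0.27, 0.120, 0.035, 0.10),
    arm_r   = c(0.32, 0.73, 0.120, 0.035, 0.10)
  )
}

.lobes_lateral_left <- function() {
  rbind(
    head    = c(0.09, 0.46, 0.050, 0.045, 0.18),
    torso   = c(0.30, 0.48, 0.130, 0.100, 0.26),
    pelvis  = c(0.50, 0.50, 0.080, 0.095, 0.28),
    leg_up  = c(0.72, 0.56, 0.150, 0.045, 0.16),
    leg_lo  = c(0.74, 0.47, 0.150, 0.040, 0.13),
    arm     = c(0.32, 0.60, 0.100, 0.030, 0.11),
    shoulder= c(0.22, 0.44, 0.050, 0.060, 0.20)
  )
}

#' Generate a body-height template for one posture
#'
#' Builds a smooth nonnegative height field (metres above the mattress) from
#' a fixed set of elliptical Gaussian lobes whose placement depends on the
#' posture and the subject's length/width scales. Background is exactly zero.
#'
#' @param posture one of [posture_labels()]
#' @param subject a [synthetic_subject()]
#' @param grid_shape integer (rows, cols) of the template grid
#' @param pose_shift length-2 numeric, small (du, dv) placement jitter in
#'   normalized body coordinates
#' @param amp_factor scalar multiplier on lobe heights (per-pose jitter)
#' @return a `grid_shape` matrix, zero outside the body
#' @export
generate_body_template <- function(posture, subject,
                                   grid_shape = c(128L, 56L),
                                   pose_shift = c(0, 0), amp_factor = 1) {
  if (!posture %in% POSTURES) {
    afn_stop(sprintf("unknown posture '%s' (expected one of %s)", posture,
                     paste(POSTURES, collapse = ", ")), "afn_posture_error")
  }
  lob <- switch(posture,
    supine = .lobes_supine(),
    lateral_left = .lobes_lateral_left(),
    lateral_right = {
      m <- .lobes_lateral_left()
      m[, 2] <- 1 - m[, 2]   # mirror across the bed midline
      m
    })
  h <- grid_shape[1]; w <- grid_shape[2]
  u <- (seq_len(h) - 0.5) / h
  v <- (seq_len(w) - 0.5) / w
  # lobe mass scales mildly with body mass (thickness ~ mass^(1/3))
  amp_scale <- amp_factor * (subject$mass_kg / 70)^(1 / 3)
  tmpl <- matrix(0, h, w)
  for (i in seq_len(nrow(lob))) {
    cu <- 0.45 + (lob[i, 1] - 0.45) * subject$length_scale + pose_shift[1]
    cv <- 0.5 + (lob[i, 2] - 0.5) * subject$width_scale + pose_shift[2]
    su <- lob[i, 3] * subject$length_scale
    sv <- lob[i, 4] * subject$width_scale
    g <- exp(-outer((u - cu)^2 / (2 * su^2), (v - cv)^2 / (2 * sv^2), "+"))
    tmpl <- tmpl + lob[i, 5] * amp_scale * g
  }
  pmax(tmpl - 0.02, 0)   # 2 cm floor gives an exactly-zero background
}

#' Render a depth image from a body template
#'
#' Depth is camera height minus body height plus additive Gaussian sensor
#' noise; a fraction of pixels is dropped to the no-return sentinel value 0
#' to emulate raw (un-cleaned) depth-camera output.
#'
#' @param template height-field matrix from [generate_body_template()]
#' @param camera_height camera distance above the mattress (same units as
#'   the template); must exceed the template maximum
#' @param noise_sd standard deviation of additive Gaussian noise
#' @param dropout_prob probability that a pixel is a no-return (sentinel 0)
#' @param seed integer seed
#' @return depth matrix, larger = farther from the camera
#' @export
render_depth <- function(template, camera_height = 2, noise_sd = 0.01,
                         dropout_prob = 0, seed = 1L) {
  if (camera_height <= max(template)) {
    afn_stop("camera_height must exceed the template maximum",
             "afn_value_error")
  }
  with_seed(seed, {
    depth <- camera_height - template
    if (noise_sd > 0) {
      depth <- depth + matrix(stats::rnorm(length(template), 0, noise_sd),
                              nrow(template))
    }
    if (dropout_prob > 0) {
      drop <- stats::runif(length(template)) < dropout_prob
      depth[drop] <- 0
    }
    depth
  })
}

#' Render a calibrated pressure map from a body template
#'
#' Local pressure grows as thickness^1.5 (giving bony-prominence-like peaks
#' at the pelvis and shoulders), is area-resampled to the sensor grid, and is
#' rescaled so the total normal force equals `mass_kg * g` exactly:
#' `sum(p_kPa * 1000) * sensor_area_m2 = mass_kg * g`.
#'
#' @param template height-field matrix (rows = bed length)
#' @param mass_kg subject body mass in kg
#' @param sensor_grid integer (rows, cols) of the sensor array, rows = bed
#'   width; default `c(27, 64)`
#' @param sensor_area_m2 area of one sensor cell in square metres
#' @param g gravitational acceleration (m/s^2)
#' @param exponent monotone thickness-to-pressure exponent
#' @return pressure matrix in kPa with dim `sensor_grid`
#' @export
render_pressure <- function(template, mass_kg, sensor_grid = c(27L, 64L),
                            sensor_area_m2 = default_sensor_area(),
                            g = 9.81, exponent = 1.5) {
  if (mass_kg <= 0) afn_stop("mass_kg must be positive", "afn_value_error")
  if (all(template <= 0)) {
    afn_stop("template has no contact (all zero)", "afn_value_error")
  }
  q <- template^exponent
  # template rows run along the bed length; sensor grid is width x length
  q64x27 <- area_resample(q, c(sensor_grid[2], sensor_grid[1]))
  q_sens <- t(q64x27)
  q_sens[q_sens < 0] <- 0
  scale <- (mass_kg * g) / (1000 * sensor_area_m2 * sum(q_sens))
  q_sens * scale
}

#' Default pressure-sensor cell area
#'
#' One cell of a 27 x 64 sensing mat covering a 0.84 m x 1.92 m bed.
#' @return area in square metres
#' @export
default_sensor_area <- function() (0.84 / 27) * (1.92 / 64)

#' Generate a full synthetic paired depth/pressure dataset
#'
#' Subject parameters (mass, body scales, calibration factor) are drawn
#' deterministically from the seed; subjects are split disjointly into
#' train/validation/test (floor rounding for validation and test, remainder
#' to train); each subject contributes `poses_per_subject` samples cycling
#' through the three postures with small seeded pose jitter.
#'
#' @param n_subjects number of subjects (>= 3)
#' @param poses_per_subject samples per subject
#' @param split_fractions length-3 numeric (train, val, test) summing to 1
#' @param seed master integer seed
#' @param grid_shape depth/template grid (rows, cols)
#' @param camera_height,noise_sd,dropout_prob depth rendering parameters
#' @param sensor_area_m2 sensor cell area
#' @return a `synthetic_dataset`: list with `samples` (list of
#'   `paired_sample`), `split` (named character vector subject -> split),
#'   `subjects`, and the generation parameters
#' @export
generate_dataset <- function(n_subjects, poses_per_subject = 6L,
                             split_fractions = c(0.6, 0.2, 0.2), seed = 1L,
                             grid_shape = c(128L, 56L), camera_height = 2,
                             noise_sd = 0.01, dropout_prob = 0.02,
                             sensor_area_m2 = default_sensor_area()) {
  if (n_subjects < 3) afn_stop("need at least 3 subjects", "afn_value_error")
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    afn_stop("split_fractions must sum to 1", "afn_value_error")
  }
  subjects <- with_seed(derive_seed(seed, "subjects"), {
    lapply(seq_len(n_subjects), function(i) {
      mass <- min(max(stats::rnorm(1, 70, 12), 45), 110)
      s <- synthetic_subject(
        subject_id = sprintf("S%03d", i), mass_kg = mass,
        length_scale = stats::runif(1, 0.85, 1.15),
        width_scale = stats::runif(1, 0.85, 1.15),
        seed = derive_seed(seed, paste0("subject", i)))
      s$calibration_kpa <- stats::runif(1, 0.04, 0.12)
      s
    })
  })
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  n_val <- floor(split_fractions[2] * n_subjects)
  n_test <- floor(split_fractions[3] * n_subjects)
  n_train <- n_subjects - n_val - n_test
  ord <- with_seed(derive_seed(seed, "split"), sample.int(n_subjects))
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  names(split) <- ids[ord]
  split <- split[ids]   # reorder to subject order

  samples <- list()
  for (si in seq_len(n_subjects)) {
    subj <- subjects[[si]]
    for (p in seq_len(poses_per_subject)) {
      posture <- POSTURES[(p - 1L) %% 3L + 1L]
      jit <- with_seed(derive_seed(seed, paste0("pose_", si, "_", p)), {
        list(shift = stats::runif(2, -0.03, 0.03),
             amp = stats::runif(1, 0.95, 1.05))
      })
      tmpl <- generate_body_template(posture, subj, grid_shape,
                                     pose_shift = jit$shift,
                                     amp_factor = jit$amp)
      depth <- render_depth(tmpl, camera_height, noise_sd, dropout_prob,
                            seed = derive_seed(seed, paste0("depth_", si, "_", p)))
      p_kpa <- render_pressure(tmpl, subj$mass_kg,
                               sensor_area_m2 = sensor_area_m2)
      samples[[length(samples) + 1L]] <- structure(list(
        depth = depth,
        pressure = p_kpa / subj$calibration_kpa,   # raw sensor units
        posture = posture,
        subject_id = subj$subject_id,
        calibration_kpa = subj$calibration_kpa,
        mass_kg = subj$mass_kg,
        template = tmpl
      ), class = "paired_sample")
    }
  }
  structure(list(samples = samples, split = split, subjects = subjects,
                 params = list(n_subjects = n_subjects,
                               poses_per_subject = poses_per_subject,
                               split_fractions = split_fractions,
                               grid_shape = grid_shape,
                               camera_height = camera_height,
                               noise_sd = noise_sd,
                               dropout_prob = dropout_prob,
                               sensor_area_m2 = sensor_area_m2),
                 seed = as.integer(seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d samples, %d subjects (train %d / val %d / test %d), seed %d\n",
              length(x$samples), length(x$subjects),
              sum(x$split == "train"), sum(x$split == "val"),
              sum(x$split == "test"), x$seed))
  invisible(x)
}

# samples belonging to one split
split_samples <- function(dataset, which) {
  keep <- vapply(dataset$samples,
                 function(s) dataset$split[[s$subject_id]] == which,
                 logical(1))
  dataset$samples[keep]
}
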