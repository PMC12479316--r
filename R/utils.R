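# shared helpers: seeded RNG substreams, parameter init, resampling kernels

afn_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "attnfnet_error")))
}

#' Derive a named RNG substream seed from a master seed
#'
#' All randomness in the package flows from one integer seed; substreams for
#' data generation, weight initialization and per-epoch shuffling are derived
#' deterministically so reruns are bit-identical.
#'
#' @param seed master integer seed
#' @param stream short string naming the substream
#' @return an integer seed below 2^31
#' @export
derive_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) %% 1000003) * 2039 + h) %% 2147483629L + 1L
}

# evaluate code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# truncated-normal initializer: values beyond 2 sd are redrawn
truncnorm_init <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# area-weighted resampling matrix: output cell i averages the input cells it
# covers, weighted by overlap; rows sum to one (conserves a constant field)
area_resample_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  w <- n_in / n_out
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * w
    hi <- i * w
    j0 <- floor(lo) + 1L
    j1 <- ceiling(hi)
    for (j in j0:min(j1, n_in)) {
      ov <- min(hi, j) - max(lo, j - 1)
      if (ov > 0) R[i, j] <- ov / w
    }
  }
  R
}

# area-average resample of a matrix to a target shape
area_resample <- function(x, out_shape) {
  Rh <- area_resample_matrix(nrow(x), out_shape[1])
  Rw <- area_resample_matrix(ncol(x), out_shape[2])
  Rh %*% x %*% t(Rw)
}

gaussian_kernel1d <- function(sigma, radius = ceiling(4 * sigma)) {
  stopifnot(sigma > 0)
  t <- (-radius):radius
  k <- exp(-t^2 / (2 * sigma^2))
  k / sum(k)
}

# fold out-of-range indices back into 1..n (reflect-with-edge-repeat)
.reflect_fold <- function(idx, n) {
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

# separable Gaussian blur, truncated at 4 sigma, reflect boundary
gaussian_blur <- function(x, sigma, radius = ceiling(4 * sigma)) {
  k <- gaussian_kernel1d(sigma, radius)
  blur_rows <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- .reflect_fold(seq_len(n) + (j - 1L - radius), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_rows(t(blur_rows(x))))
}
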