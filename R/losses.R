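# Losses: SSIM with a Gaussian window, the mixed SSIM + MSE perceptual loss,
# and the label-smoothed conditional-GAN discriminator/generator objectives.
#
# Each loss exists in two forms sharing the same arithmetic: a plain numeric
# function (exported, used for evaluation) and an autodiff counterpart
# (internal, used during training).

#' SSIM parameters
#'
#' @param window_size odd Gaussian window size in pixels
#' @param window_sigma Gaussian window standard deviation
#' @param L dynamic range of the image values
#' @param C1,C2 stabilizing constants; defaults `(0.01 L)^2` and `(0.03 L)^2`
#' @return an `ssim_params` list
#' @export
ssim_params <- function(window_size = 11L, window_sigma = 1.5, L = 1,
                        C1 = (0.01 * L)^2, C2 = (0.03 * L)^2) {
  if (window_size %% 2L == 0L) afn_stop("window_size must be odd", "afn_value_error")
  if (C1 <= 0 || C2 <= 0) afn_stop("C1, C2 must be positive", "afn_value_error")
  structure(list(window_size = as.integer(window_size),
                 window_sigma = window_sigma, L = L, C1 = C1, C2 = C2),
            class = "ssim_params")
}

#' Loss configuration for conditional-GAN training
#'
#' @param lambda weight of the perceptual term in the generator loss
#' @param alpha weight of the (1 - SSIM) term
#' @param beta weight of the mean-squared-error term
#' @param y_real,y_gen smoothed discriminator targets for real and generated
#'   maps
#' @param ssim an [ssim_params()]
#' @return a `loss_config` list
#' @export
loss_config <- function(lambda = 100, alpha = 300, beta = 1,
                        y_real = 0.9, y_gen = 0.1, ssim = ssim_params()) {
  if (lambda < 0 || alpha < 0 || beta < 0) {
    afn_stop("lambda, alpha, beta must be nonnegative", "afn_value_error")
  }
  if (!(y_gen >= 0 && y_gen < y_real && y_real <= 1)) {
    afn_stop("need 0 <= y_gen < y_real <= 1", "afn_value_error")
  }
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 y_real = y_real, y_gen = y_gen, ssim = ssim),
            class = "loss_config")
}

# normalized 2-d Gaussian window
ssim_window <- function(params) {
  r <- (params$window_size - 1L) %/% 2L
  k <- gaussian_kernel1d(params$window_sigma, radius = r)
  outer(k, k)
}

# valid-mode single-channel 2-d correlation via im2col
.conv_valid <- function(x, kern) {
  kh <- nrow(kern)
  xm <- array(x, c(nrow(x), ncol(x), 1L))
  cols <- im2col(xm, kh, ncol(kern), 1L)
  out <- cols %*% as.vector(kern)
  matrix(out, nrow(x) - kh + 1L)
}

#' Structural similarity index between two images
#'
#' Local means, variances and covariance are computed with a Gaussian window
#' ('valid' windowing: only fully supported positions contribute); the SSIM
#' map is averaged over positions. For images smaller than the window a
#' single global window is used.
#'
#' @param a,b matrices of identical shape
#' @param params an [ssim_params()]
#' @return scalar in `[-1, 1]`
#' @export
ssim <- function(a, b, params = ssim_params()) {
  if (!all(dim(a) == dim(b))) afn_stop("shape mismatch", "afn_shape_error")
  if (min(dim(a)) < params$window_size) {
    # degenerate case: one global uniform window
    mu_a <- mean(a); mu_b <- mean(b)
    va <- mean((a - mu_a)^2); vb <- mean((b - mu_b)^2)
    cab <- mean((a - mu_a) * (b - mu_b))
    return(((2 * mu_a * mu_b + params$C1) * (2 * cab + params$C2)) /
             ((mu_a^2 + mu_b^2 + params$C1) * (va + vb + params$C2)))
  }
  w <- ssim_window(params)
  mu_a <- .conv_valid(a, w)
  mu_b <- .conv_valid(b, w)
  s_aa <- .conv_valid(a * a, w) - mu_a^2
  s_bb <- .conv_valid(b * b, w) - mu_b^2
  s_ab <- .conv_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + params$C1) * (2 * s_ab + params$C2)
  den <- (mu_a^2 + mu_b^2 + params$C1) * (s_aa + s_bb + params$C2)
  mean(num / den)
}

# autodiff SSIM on matrix nodes (same arithmetic as ssim())
ssim_ad <- function(a, b, params) {
  d <- dim_of(a$value)
  a3 <- ad_reshape(a, c(d[1], d[2], 1L))
  b3 <- ad_reshape(b, c(d[1], d[2], 1L))
  w <- ssim_window(params)
  kern <- ad_const(array(w, c(nrow(w), ncol(w), 1L, 1L)))
  zb <- ad_const(0)
  cv <- function(x) ad_conv2d(x, kern, zb, 1L, 0L)
  mu_a <- cv(a3); mu_b <- cv(b3)
  s_aa <- ad_sub(cv(ad_mul(a3, a3)), ad_mul(mu_a, mu_a))
  s_bb <- ad_sub(cv(ad_mul(b3, b3)), ad_mul(mu_b, mu_b))
  s_ab <- ad_sub(cv(ad_mul(a3, b3)), ad_mul(mu_a, mu_b))
  num <- ad_mul(ad_addc(ad_scale(ad_mul(mu_a, mu_b), 2), params$C1),
                ad_addc(ad_scale(s_ab, 2), params$C2))
  den <- ad_mul(ad_addc(ad_add(ad_mul(mu_a, mu_a), ad_mul(mu_b, mu_b)), params$C1),
                ad_addc(ad_add(s_aa, s_bb), params$C2))
  ad_mean(ad_div(num, den))
}

#' Mixed SSIM + MSE perceptual loss
#'
#' `alpha * (1 - SSIM(y, g)) + beta * MSE(y, g)`. The squared-error term is
#' the mean over pixels, matching the MSE evaluation metric and the stated
#' alpha/beta balance.
#'
#' @param y ground-truth map
#' @param g generated map
#' @param cfg a [loss_config()]
#' @return nonnegative scalar
#' @export
ssiml2_loss <- function(y, g, cfg = loss_config()) {
  if (!all(dim(y) == dim(g))) afn_stop("shape mismatch", "afn_shape_error")
  cfg$alpha * (1 - ssim(y, g, cfg$ssim)) + cfg$beta * mean((y - g)^2)
}

ssiml2_ad <- function(y, g, cfg) {
  mse_t <- ad_mean(ad_square(ad_sub(y, g)))
  ssim_t <- ad_addc(ad_neg(ssim_ad(y, g, cfg$ssim)), 1)
  ad_add(ad_scale(ssim_t, cfg$alpha), ad_scale(mse_t, cfg$beta))
}

.clamp01 <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Label-smoothed discriminator loss
#'
#' Binary cross-entropy of the discriminator's real/fake probabilities
#' against smoothed targets `y_real` / `y_gen`. Probabilities may be vectors
#' (patch maps / batches); the loss is their mean.
#'
#' @param d_real discriminator probability(ies) on real pairs, in `[0, 1]`
#' @param d_fake discriminator probability(ies) on generated pairs
#' @param cfg a [loss_config()]
#' @return nonnegative scalar
#' @export
discriminator_loss <- function(d_real, d_fake, cfg = loss_config()) {
  if (any(d_real < 0 | d_real > 1) || any(d_fake < 0 | d_fake > 1)) {
    afn_stop("probabilities must lie in [0, 1]", "afn_value_error")
  }
  dr <- .clamp01(d_real)
  df <- .clamp01(d_fake)
  -mean(cfg$y_real * log(dr) + (1 - cfg$y_real) * log(1 - dr) +
          cfg$y_gen * log(df) + (1 - cfg$y_gen) * log(1 - df))
}

#' Generator loss: adversarial term plus weighted perceptual loss
#'
#' `-log D(x | G(x)) + lambda * ssiml2_loss(y, G(x))`. The adversarial term
#' uses the plain (unsmoothed) log-probability.
#'
#' @param d_fake discriminator probability on the generated pair
#' @param y ground-truth map
#' @param g generated map
#' @param cfg a [loss_config()]
#' @return scalar
#' @export
generator_loss <- function(d_fake, y, g, cfg = loss_config()) {
  if (any(d_fake < 0 | d_fake > 1)) {
    afn_stop("probabilities must lie in [0, 1]", "afn_value_error")
  }
  -mean(log(.clamp01(d_fake))) + cfg$lambda * ssiml2_loss(y, g, cfg)
}
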