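# Independent brute-force oracles. These deliberately share no code with the
# package implementations: plain loops and textbook formulas only.

# SSIM by an explicit double loop over fully supported Gaussian windows
oracle_ssim <- function(a, b, window_size = 11L, window_sigma = 1.5,
                        C1 = 0.01^2, C2 = 0.03^2) {
  r <- (window_size - 1L) %/% 2L
  t <- (-r):r
  k1 <- exp(-t^2 / (2 * window_sigma^2))
  k1 <- k1 / sum(k1)
  w <- outer(k1, k1)
  vals <- c()
  for (i in (1 + r):(nrow(a) - r)) {
    for (j in (1 + r):(ncol(a) - r)) {
      wa <- a[(i - r):(i + r), (j - r):(j + r)]
      wb <- b[(i - r):(i + r), (j - r):(j + r)]
      mu_a <- sum(w * wa)
      mu_b <- sum(w * wb)
      va <- sum(w * wa^2) - mu_a^2
      vb <- sum(w * wb^2) - mu_b^2
      cab <- sum(w * wa * wb) - mu_a * mu_b
      vals <- c(vals, ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
                  ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# scalar metrics by explicit per-pixel loops
oracle_ppa <- function(y, g, tol) {
  n_ok <- 0L
  for (i in seq_along(y)) if (abs(y[i] - g[i]) <= tol) n_ok <- n_ok + 1L
  n_ok / length(y)
}

oracle_mse <- function(y, g) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - g[i])^2
  s / length(y)
}

oracle_psnr <- function(y, g, max_val) {
  m <- oracle_mse(y, g)
  10 * log10(max_val^2 / m)
}

# 4-connected largest component by repeated neighbourhood dilation; ties on
# size resolve to the component discovered first in column-major order (the
# same convention the package uses)
oracle_largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    comp <- matrix(FALSE, h, w)
    comp[i, j] <- TRUE
    repeat {
      grown <- comp
      for (ii in seq_len(h)) for (jj in seq_len(w)) {
        if (comp[ii, jj]) next
        if (!mask[ii, jj]) next
        if ((ii > 1 && comp[ii - 1, jj]) || (ii < h && comp[ii + 1, jj]) ||
            (jj > 1 && comp[ii, jj - 1]) || (jj < w && comp[ii, jj + 1])) {
          grown[ii, jj] <- TRUE
        }
      }
      if (identical(grown, comp)) break
      comp <- grown
    }
    lab[comp] <- nxt
  }
  if (nxt == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

oracle_iou <- function(y, g, threshold) {
  ay <- oracle_largest_component(y > threshold)
  ag <- oracle_largest_component(g > threshold)
  if (!any(ay) && !any(ag)) return(1)
  sum(ay & ag) / sum(ay | ag)
}

# Frechet distance by the closed form, with the matrix square root computed
# through svd (different route than the package's eigendecomposition)
oracle_frechet <- function(f1, f2) {
  mu1 <- colMeans(f1); mu2 <- colMeans(f2)
  s1 <- cov(f1); s2 <- cov(f2)
  sq <- function(S) {
    sv <- svd((S + t(S)) / 2)
    sv$u %*% diag(sqrt(pmax(sv$d, 0)), nrow = length(sv$d)) %*% t(sv$v)
  }
  r1 <- sq(s1)
  mid <- sq(r1 %*% s2 %*% r1)
  sum((mu1 - mu2)^2) + sum(diag(s1)) + sum(diag(s2)) - 2 * sum(diag(mid))
}

# self-attention (single residual after concat + projection) by three nested
# loops over tokens/heads
oracle_attention <- function(Z, p, n_heads) {
  n <- nrow(Z); d <- ncol(Z); dk <- d %/% n_heads
  Q <- Z %*% p$wq + matrix(p$bq, n, d, byrow = TRUE)
  K <- Z %*% p$wk + matrix(p$bk, n, d, byrow = TRUE)
  V <- Z %*% p$wv + matrix(p$bv, n, d, byrow = TRUE)
  H <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    for (i in seq_len(n)) {
      sc <- numeric(n)
      for (j in seq_len(n)) sc[j] <- sum(Q[i, idx] * K[j, idx]) / sqrt(dk)
      a <- exp(sc - max(sc))
      a <- a / sum(a)
      for (j in seq_len(n)) H[i, idx] <- H[i, idx] + a[j] * V[j, idx]
    }
  }
  Z + H %*% p$wo + matrix(p$bo, n, d, byrow = TRUE)
}

# random attention parameter set for a given width
random_attention_params <- function(d) {
  list(wq = matrix(rnorm(d * d, 0, 0.2), d), bq = rnorm(d, 0, 0.1),
       wk = matrix(rnorm(d * d, 0, 0.2), d), bk = rnorm(d, 0, 0.1),
       wv = matrix(rnorm(d * d, 0, 0.2), d), bv = rnorm(d, 0, 0.1),
       wo = matrix(rnorm(d * d, 0, 0.2), d), bo = rnorm(d, 0, 0.1))
}

# micro model/data configuration used across training tests
micro_setup <- function(seed = 1L) {
  list(
    data_args = list(n_subjects = 5L, poses_per_subject = 3L, seed = seed,
                     grid_shape = c(32L, 24L), dropout_prob = 0.01),
    gen_spec = generator_spec(input_shape = c(32L, 24L), patch_size = 8L,
                              embed_dim = 16L, n_blocks = 3L, n_heads = 2L,
                              skip_blocks = c(1L, 2L, 3L),
                              decoder_channels = c(8L, 6L, 4L),
                              skip_proj_channels = 2L),
    disc_spec = discriminator_spec(n_layers = 3L, base_channels = 4L),
    pp_config = preprocess_config(pad_to = c(32L, 24L)),
    loss_cfg = loss_config()
  )
}

# a generator stand-in whose forward returns fn(image); lets tests feed the
# evaluation pipeline an oracle (e.g. the ground truth itself)
function_generator <- function(fn) {
  structure(list(fn = fn, params = list()), class = "function_generator")
}
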