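# small spec shared by the model unit tests (structure identical to the
# full-scale default, minutes -> milliseconds)
small_spec <- function(variant = "conv") {
  generator_spec(input_shape = c(32L, 24L), patch_size = 8L, embed_dim = 16L,
                 n_blocks = 4L, n_heads = 2L, ff_variant = variant,
                 skip_blocks = c(1L, 2L, 3L), decoder_channels = c(8L, 6L, 4L),
                 skip_proj_channels = 2L)
}

test_that("patch embedding produces the arithmetic token grid and is patch-local", {
  spec <- generator_spec()
  expect_equal(spec$grid_shape, c(16L, 7L))
  expect_equal(prod(spec$grid_shape), 112)
  sp <- small_spec()
  G <- init_generator(sp, seed = 3)
  zero <- matrix(0, 32, 24)
  p0 <- G$params
  p0$patch_b <- numeric(sp$embed_dim)
  tk <- patch_embed(zero, sp, p0)
  expect_equal(dim(tk), c(12L, 16L))
  expect_true(all(tk == 0))
  # perturbing one patch changes exactly one token
  x1 <- matrix(rnorm(32 * 24), 32, 24)
  x2 <- x1
  x2[9:16, 9:16] <- x2[9:16, 9:16] + 1   # patch (row 2, col 2)
  t1 <- patch_embed(x1, sp, G$params)
  t2 <- patch_embed(x2, sp, G$params)
  changed <- which(rowSums(abs(t1 - t2)) > 1e-12)
  expect_equal(changed, 4L + 2L)   # token (r=2, c=2) -> (c-1)*h_p + r
  expect_error(patch_embed(matrix(0, 30, 24), sp, G$params),
               class = "afn_shape_error")
})

test_that("sinusoidal positions start at (0, 1), stay within [-1, 1], and are pairwise distinct", {
  pe <- sinusoidal_positions(c(16L, 7L), 64L)
  expect_equal(dim(pe), c(112L, 64L))
  expect_true(all(pe[1, seq(1, 63, by = 2)] == 0))   # sin channels at t = 0
  expect_true(all(pe[1, seq(2, 64, by = 2)] == 1))   # cos channels at t = 0
  expect_true(all(pe >= -1 & pe <= 1))
  expect_equal(nrow(unique(round(pe, 10))), nrow(pe))
  expect_error(sinusoidal_positions(c(4L, 4L), 7L), class = "afn_spec_error")
})

test_that("self-attention matches the three-nested-loop oracle and its degenerate cases", {
  set.seed(41)
  d <- 8L
  p <- random_attention_params(d)
  Z <- matrix(rnorm(6 * d), 6, d)
  expect_equal(self_attention(Z, p, 2L), oracle_attention(Z, p, 2L),
               tolerance = 1e-5)
  expect_equal(self_attention(Z, p, 4L), oracle_attention(Z, p, 4L),
               tolerance = 1e-5)
  # one token: softmax over a single key is 1, output = Z + proj(V)
  z1 <- matrix(rnorm(d), 1, d)
  v1 <- z1 %*% p$wv + p$bv
  expect_equal(self_attention(z1, p, 2L),
               z1 + (v1 %*% p$wo + matrix(p$bo, 1, d, byrow = TRUE)),
               tolerance = 1e-10)
  # identical value vectors: pre-residual output independent of Q and K
  Zv <- Z
  pv <- p
  pv$wv <- matrix(0, d, d)             # V = bv for every token
  out1 <- self_attention(Zv, pv, 2L) - Zv
  pv$wq <- matrix(rnorm(d * d), d)     # different queries
  out2 <- self_attention(Zv, pv, 2L) - Zv
  expect_equal(out1, out2, tolerance = 1e-10)
  expect_error(self_attention(matrix(NaN, 2, d), p, 2L),
               class = "afn_value_error")
})

test_that("transformer blocks preserve token-grid shape and reduce to the residual under zero feed-forward", {
  set.seed(42)
  for (variant in c("conv", "mlp")) {
    sp <- small_spec(variant)
    G <- init_generator(sp, seed = 4)
    tk <- matrix(rnorm(12 * 16), 12, 16)
    out <- transformer_block(tk, G, 2L)
    expect_equal(dim(out), dim(tk))
    # zero the feed-forward weights: block output = attention output only
    Gz <- G
    Gz$params$b2_fw1[] <- 0
    Gz$params$b2_fb1[] <- 0
    Gz$params$b2_fw2[] <- 0
    Gz$params$b2_fb2[] <- 0
    att_only <- local({
      x1 <- attnfnet:::ad_layernorm(attnfnet:::ad_const(tk),
                                    attnfnet:::ad_const(G$params$b2_ln1_g),
                                    attnfnet:::ad_const(G$params$b2_ln1_b))
      attnfnet:::ad_value(attnfnet:::ad_add(
        attnfnet:::ad_const(tk),
        attnfnet:::.attention_core(x1, G$params, sp$n_heads, "b2_")))
    })
    expect_equal(transformer_block(tk, Gz, 2L), att_only, tolerance = 1e-12)
  }
})

test_that("the convolutional feed-forward mixes only within its 3x3 receptive field once attention is frozen", {
  sp <- small_spec("conv")
  G <- init_generator(sp, seed = 5)
  # freeze attention to the identity: zero V so MHA adds nothing
  G$params$b1_wv[] <- 0
  G$params$b1_bv[] <- 0
  G$params$b1_wo[] <- 0
  G$params$b1_bo[] <- 0
  tk <- matrix(rnorm(12 * 16), 12, 16)
  tk2 <- tk
  tk2[1, ] <- tk2[1, ] + 10        # token (row 1, col 1) of the 4 x 3 grid
  d1 <- abs(transformer_block(tk2, G, 1L) - transformer_block(tk, G, 1L))
  moved <- which(rowSums(d1) > 1e-9)
  # two stacked 3x3 convolutions: 5x5 footprint around (1, 1) on a 4x3 grid
  grid_rc <- expand.grid(r = 1:4, c = 1:3)
  reach <- which(abs(grid_rc$r - 1) <= 2 & abs(grid_rc$c - 1) <= 2)
  expect_true(all(moved %in% reach))
  expect_true(1L %in% moved)
})

test_that("the encoder records exactly the configured skips and block order is causal", {
  sp <- small_spec()
  G <- init_generator(sp, seed = 6)
  x <- matrix(rnorm(32 * 24), 32, 24)
  enc <- encode_image(x, G)
  expect_setequal(names(enc$skips), c("1", "2", "3"))
  expect_true(all(vapply(enc$skips, function(s)
    all(dim(s) == c(12L, 16L)), logical(1))))
  expect_equal(dim(enc$latent), c(12L, 16L))
  # perturbing the last block's weights changes the latent but no skip
  G2 <- G
  G2$params$b4_wo <- G2$params$b4_wo + 0.5
  enc2 <- encode_image(x, G2)
  expect_gt(max(abs(enc2$latent - enc$latent)), 1e-8)
  for (k in names(enc$skips)) {
    expect_equal(enc2$skips[[k]], enc$skips[[k]], tolerance = 1e-14)
  }
})

test_that("the decoder emits a bounded 27x64 map and its skip inputs are load-bearing", {
  sp <- small_spec()
  G <- init_generator(sp, seed = 7)
  x <- matrix(rnorm(32 * 24), 32, 24)
  enc <- encode_image(x, G)
  out <- decode_latent(enc$latent, enc$skips, G)
  expect_equal(dim(out), c(27L, 64L))
  expect_true(all(out > 0 & out < 1))
  skz <- enc$skips
  skz[["3"]] <- skz[["3"]] * 0
  out2 <- decode_latent(enc$latent, skz, G)
  expect_gt(max(abs(out2 - out)), 1e-9)
  expect_error(decode_latent(enc$latent, enc$skips[c("1", "2")], G),
               class = "afn_shape_error")
  expect_equal(generator_forward(G, x), out, tolerance = 1e-12)
})

test_that("both feed-forward variants are shape-interchangeable", {
  x <- matrix(rnorm(32 * 24), 32, 24)
  outs <- lapply(c("conv", "mlp"), function(v) {
    G <- init_generator(small_spec(v), seed = 8)
    enc <- encode_image(x, G)
    list(latent = dim(enc$latent), skips = lapply(enc$skips, dim),
         out = dim(generator_forward(G, x)),
         tok = dim(transformer_block(matrix(0, 12, 16), G, 1L)))
  })
  expect_identical(outs[[1]], outs[[2]])
})

test_that("the patch discriminator emits a logit map whose probed receptive field matches the analytic one", {
  dsp <- discriminator_spec(n_layers = 3L, base_channels = 8L)
  expect_equal(dsp$receptive_field, 22L)
  D <- init_discriminator(dsp, seed = 9)
  depth <- matrix(rnorm(32 * 24), 32, 24)
  press <- matrix(runif(27 * 64), 27, 64)
  fw <- discriminator_forward(D, depth, press)
  expect_true(length(dim(fw$logits)) == 2 && all(dim(fw$logits) >= 1))
  expect_true(fw$prob > 0 && fw$prob < 1)
  # perturbation probe vs closed-form receptive-field arithmetic: the corner
  # logit covers pixels 1..15 (c_3 = 3 unpadded taps, c_l = 2 c_{l+1} + 1
  # through two more k=4, s=2, p=1 layers: 3 -> 7 -> 15); the interior
  # receptive field is the spec's 22
  base <- fw$logits[1, 1]
  probe <- function(i, j) {
    p2 <- press
    p2[i, j] <- p2[i, j] + 5
    discriminator_forward(D, depth, p2)$logits[1, 1]
  }
  expect_true(abs(probe(2, 2) - base) > 1e-12)         # inside
  expect_true(abs(probe(1, 15) - base) > 1e-12)        # inside, last column
  expect_true(abs(probe(1, 16) - base) < 1e-12)        # outside
  expect_true(abs(probe(27, 40) - base) < 1e-12)       # far outside
  expect_error(discriminator_forward(D, depth, matrix(0, 10, 10)),
               class = "afn_shape_error")
})

test_that("the U-Net baseline honours the shared generator contract", {
  U <- init_unet(input_shape = c(32L, 24L), base_channels = 4L, seed = 10)
  expect_gt(count_params(U), 0)
  x <- matrix(rnorm(32 * 24), 32, 24)
  out <- unet_forward(U, x)
  expect_equal(dim(out), c(27L, 64L))
  expect_true(all(out > 0 & out < 1))
  U2 <- init_unet(input_shape = c(32L, 24L), base_channels = 4L, seed = 10)
  expect_identical(U$params, U2$params)
})

test_that("generator-loss gradients reach the first transformer block", {
  sp <- small_spec()
  G <- init_generator(sp, seed = 11)
  x <- matrix(rnorm(32 * 24), 32, 24)
  y <- matrix(runif(27 * 64), 27, 64)
  ad <- getNamespace("attnfnet")
  gg <- ad$generator_graph(G, x)
  loss <- ad$ssiml2_ad(ad$ad_const(y), gg$out, loss_config())
  ad$ad_backward(loss)
  for (nm in c("b1_wq", "b1_wv", "b1_fw1", "patch_w")) {
    expect_gt(max(abs(ad$ad_grad(gg$pnodes[[nm]]))), 0)
  }
})
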