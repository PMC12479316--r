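# The depth-to-pressure generator: a hybrid vision-transformer encoder
# (patch embedding, sinusoidal positions, 12 pre-norm blocks whose
# feed-forward stage is either a token-wise MLP or a pair of 3x3
# convolutions over the token grid) and a lightweight deconvolutional
# decoder fed by skip connections from intermediate blocks (defaults 6, 8,
# 10). Token grids are (n_tokens x embed_dim) matrices with column-major
# token order: token t = (col-1)*h_p + row of the patch grid.

#' Generator architecture specification
#'
#' @param input_shape padded model input (rows, cols); must be divisible by
#'   `patch_size`
#' @param patch_size patch edge in pixels (convolutional patch embedding
#'   uses kernel = stride = `patch_size`)
#' @param embed_dim token embedding dimension (default 712)
#' @param n_blocks number of transformer blocks
#' @param n_heads attention heads; must divide `embed_dim`
#' @param ff_variant `"conv"` (3x3 convolutional projections over the token
#'   grid) or `"mlp"` (token-wise two-layer perceptron)
#' @param skip_blocks indices of the three blocks feeding decoder skips,
#'   shallowest first
#' @param decoder_channels channels of the three stride-2 deconvolution
#'   stages
#' @param skip_proj_channels channels each skip is 1x1-projected to before
#'   concatenation
#' @param ff_hidden hidden width of the feed-forward stage (conv channels or
#'   MLP units); default `embed_dim %/% 4` for conv, `2 * embed_dim` for mlp
#' @param output_shape generated pressure map shape
#' @param output_activation `"sigmoid"` (bounded nonnegative model units)
#' @return a `generator_spec` list
#' @export
generator_spec <- function(input_shape = c(128L, 56L), patch_size = 8L,
                           embed_dim = 712L, n_blocks = 12L, n_heads = 8L,
                           ff_variant = c("conv", "mlp"),
                           skip_blocks = c(6L, 8L, 10L),
                           decoder_channels = c(256L, 128L, 64L),
                           skip_proj_channels = 32L,
                           ff_hidden = NULL,
                           output_shape = c(27L, 64L),
                           output_activation = "sigmoid") {
  ff_variant <- match.arg(ff_variant)
  if (embed_dim %% n_heads != 0L) {
    afn_stop("embed_dim must be divisible by n_heads", "afn_spec_error")
  }
  if (any(input_shape %% patch_size != 0L)) {
    afn_stop("input_shape must be divisible by patch_size", "afn_spec_error")
  }
  if (any(skip_blocks < 1L | skip_blocks > n_blocks) ||
      length(skip_blocks) != 3L) {
    afn_stop("skip_blocks must be three indices within [1, n_blocks]",
             "afn_spec_error")
  }
  if (is.null(ff_hidden)) {
    ff_hidden <- if (ff_variant == "conv") max(8L, embed_dim %/% 4L)
                 else 2L * embed_dim
  }
  structure(list(input_shape = as.integer(input_shape),
                 patch_size = as.integer(patch_size),
                 embed_dim = as.integer(embed_dim),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 head_dim = embed_dim %/% n_heads,
                 ff_variant = ff_variant,
                 skip_blocks = as.integer(sort(skip_blocks)),
                 decoder_channels = as.integer(decoder_channels),
                 skip_proj_channels = as.integer(skip_proj_channels),
                 ff_hidden = as.integer(ff_hidden),
                 grid_shape = as.integer(input_shape %/% patch_size),
                 output_shape = as.integer(output_shape),
                 output_activation = output_activation),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("generator_spec: %dx%d input, patch %d -> %dx%d tokens, d=%d, %d blocks (%s ff), heads %d, skips {%s}, out %dx%d\n",
              x$input_shape[1], x$input_shape[2], x$patch_size,
              x$grid_shape[1], x$grid_shape[2], x$embed_dim, x$n_blocks,
              x$ff_variant, x$n_heads,
              paste(x$skip_blocks, collapse = ", "),
              x$output_shape[1], x$output_shape[2]))
  invisible(x)
}

.init_mat <- function(...) {
  d <- c(...)
  array(truncnorm_init(prod(d)), dim = d)
}

#' Initialize generator parameters
#'
#' Truncated-normal (sd 0.02) weights, zero biases, unit layer-norm scales.
#'
#' @param spec a [generator_spec()]
#' @param seed integer seed
#' @return an `attnfnet_generator` list with `spec`, `params`, `seed`
#' @export
init_generator <- function(spec, seed = 1L) {
  with_seed(derive_seed(seed, "generator_init"), {
    d <- spec$embed_dim
    p <- spec$patch_size
    params <- list(patch_w = .init_mat(p, p, 1L, d), patch_b = numeric(d))
    for (i in seq_len(spec$n_blocks)) {
      blk <- list(ln1_g = rep(1, d), ln1_b = numeric(d),
                  wq = .init_mat(d, d), bq = numeric(d),
                  wk = .init_mat(d, d), bk = numeric(d),
                  wv = .init_mat(d, d), bv = numeric(d),
                  wo = .init_mat(d, d), bo = numeric(d),
                  ln2_g = rep(1, d), ln2_b = numeric(d))
      if (spec$ff_variant == "conv") {
        blk$fw1 <- .init_mat(3L, 3L, d, spec$ff_hidden)
        blk$fb1 <- numeric(spec$ff_hidden)
        blk$fw2 <- .init_mat(3L, 3L, spec$ff_hidden, d)
        blk$fb2 <- numeric(d)
      } else {
        blk$fw1 <- .init_mat(d, spec$ff_hidden)
        blk$fb1 <- numeric(spec$ff_hidden)
        blk$fw2 <- .init_mat(spec$ff_hidden, d)
        blk$fb2 <- numeric(d)
      }
      names(blk) <- paste0("b", i, "_", names(blk))
      params <- c(params, blk)
    }
    dc <- spec$decoder_channels
    sc <- spec$skip_proj_channels
    in_ch <- c(d + sc, dc[1] + sc, dc[2] + sc)
    for (i in 1:3) {
      params[[paste0("skip", i, "_w")]] <- .init_mat(1L, 1L, d, sc)
      params[[paste0("skip", i, "_b")]] <- numeric(sc)
      params[[paste0("dec", i, "_w")]] <- .init_mat(4L, 4L, dc[i], in_ch[i])
      params[[paste0("dec", i, "_b")]] <- numeric(dc[i])
    }
    params$out_w <- .init_mat(1L, 1L, dc[3], 1L)
    params$out_b <- numeric(1L)
    structure(list(spec = spec, params = params, seed = as.integer(seed)),
              class = "attnfnet_generator")
  })
}

#' @export
print.attnfnet_generator <- function(x, ...) {
  cat(sprintf("attnfnet_generator: %s ff variant, %s parameters\n",
              x$spec$ff_variant, format(count_params(x), big.mark = ",")))
  print(x$spec)
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a generator, discriminator or U-Net object
#' @return integer parameter count
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Sinusoidal positional embeddings
#'
#' Fixed (non-learned) sine/cosine encoding of the flattened token index:
#' channel pairs (2i-1, 2i) hold `sin(t / 10000^(2(i-1)/d))` and the
#' matching cosine for 0-based token index t.
#'
#' @param grid_shape (rows, cols) of the patch grid
#' @param d embedding dimension; must be even
#' @return an `(n_tokens x d)` matrix with entries in `[-1, 1]`
#' @export
sinusoidal_positions <- function(grid_shape, d) {
  if (d %% 2L != 0L) afn_stop("embedding dimension must be even", "afn_spec_error")
  n <- prod(grid_shape)
  t <- seq_len(n) - 1
  i <- seq_len(d %/% 2L) - 1
  freq <- 1 / 10000^(2 * i / d)
  ang <- outer(t, freq)
  pe <- matrix(0, n, d)
  pe[, 2 * seq_len(d %/% 2L) - 1] <- sin(ang)
  pe[, 2 * seq_len(d %/% 2L)] <- cos(ang)
  pe
}

#' Convolutional patch embedding
#'
#' Strided convolution with kernel = stride = patch size projecting each
#' patch to `embed_dim` channels; the result is flattened to a token grid.
#'
#' @param image input matrix of shape `spec$input_shape` (or an `ad_node`)
#' @param spec a [generator_spec()]
#' @param params generator parameter list (uses `patch_w`, `patch_b`)
#' @return token matrix `(n_tokens x embed_dim)`; an `ad_node` when the
#'   inputs are nodes
#' @export
patch_embed <- function(image, spec, params) {
  img <- if (inherits(image, "ad_node")) image else ad_const(image)
  if (!all(dim_of(img$value) == spec$input_shape)) {
    afn_stop("image shape does not match spec$input_shape", "afn_shape_error")
  }
  w <- if (inherits(params$patch_w, "ad_node")) params$patch_w else ad_const(params$patch_w)
  b <- if (inherits(params$patch_b, "ad_node")) params$patch_b else ad_const(params$patch_b)
  x3 <- ad_reshape(img, c(spec$input_shape, 1L))
  y <- ad_conv2d(x3, w, b, stride = spec$patch_size, pad = 0L)
  tokens <- ad_reshape(y, c(prod(spec$grid_shape), spec$embed_dim))
  if (inherits(image, "ad_node")) tokens else ad_value(tokens)
}

# wrap plain arrays in constant nodes, pass nodes through
.nd <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

# multi-head self-attention core on a token node; single residual added
# after head concatenation and output projection
.attention_core <- function(tg, p, n_heads, prefix) {
  d <- ncol(tg$value)
  dk <- d %/% n_heads
  q <- ad_add_rowvec(ad_matmul(tg, .nd(p[[paste0(prefix, "wq")]])), .nd(p[[paste0(prefix, "bq")]]))
  k <- ad_add_rowvec(ad_matmul(tg, .nd(p[[paste0(prefix, "wk")]])), .nd(p[[paste0(prefix, "bk")]]))
  v <- ad_add_rowvec(ad_matmul(tg, .nd(p[[paste0(prefix, "wv")]])), .nd(p[[paste0(prefix, "bv")]]))
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1L) * dk + seq_len(dk)
    a <- ad_softmax_rows(ad_scale(ad_matmul(ad_cols(q, idx),
                                            ad_transpose(ad_cols(k, idx))),
                                  1 / sqrt(dk)))
    heads[[h]] <- ad_matmul(a, ad_cols(v, idx))
  }
  ad_add_rowvec(ad_matmul(ad_cbind(heads), .nd(p[[paste0(prefix, "wo")]])),
                .nd(p[[paste0(prefix, "bo")]]))
}

#' Multi-head self-attention with a single residual connection
#'
#' Per head, `softmax(Q K^T / sqrt(d_k)) V` over all tokens; heads are
#' concatenated, linearly projected, and the input tokens are added once as
#' the residual.
#'
#' @param tokens `(n x d)` token matrix or `ad_node`
#' @param params list with `wq, bq, wk, bk, wv, bv, wo, bo`
#' @param n_heads number of heads; must divide `d`
#' @return token matrix (or node) of the same shape
#' @export
self_attention <- function(tokens, params, n_heads) {
  tg <- .nd(tokens)
  if (any(!is.finite(tg$value))) afn_stop("NaN/Inf in tokens", "afn_value_error")
  if (ncol(tg$value) %% n_heads != 0L) {
    afn_stop("d must be divisible by n_heads", "afn_spec_error")
  }
  out <- ad_add(tg, .attention_core(tg, params, n_heads, ""))
  if (inherits(tokens, "ad_node")) out else ad_value(out)
}

# one pre-norm transformer block on a token node
.block_forward <- function(tg, p, spec, i) {
  pre <- paste0("b", i, "_")
  x1 <- ad_layernorm(tg, .nd(p[[paste0(pre, "ln1_g")]]), .nd(p[[paste0(pre, "ln1_b")]]))
  att <- ad_add(tg, .attention_core(x1, p, spec$n_heads, pre))
  x2 <- ad_layernorm(att, .nd(p[[paste0(pre, "ln2_g")]]), .nd(p[[paste0(pre, "ln2_b")]]))
  ff <- if (spec$ff_variant == "conv") {
    g <- spec$grid_shape
    xs <- ad_reshape(x2, c(g[1], g[2], spec$embed_dim))
    h1 <- ad_relu(ad_conv2d(xs, .nd(p[[paste0(pre, "fw1")]]),
                            .nd(p[[paste0(pre, "fb1")]]), 1L, 1L))
    h2 <- ad_conv2d(h1, .nd(p[[paste0(pre, "fw2")]]),
                    .nd(p[[paste0(pre, "fb2")]]), 1L, 1L)
    ad_reshape(h2, c(prod(g), spec$embed_dim))
  } else {
    h1 <- ad_relu(ad_add_rowvec(ad_matmul(x2, .nd(p[[paste0(pre, "fw1")]])),
                                .nd(p[[paste0(pre, "fb1")]])))
    ad_add_rowvec(ad_matmul(h1, .nd(p[[paste0(pre, "fw2")]])),
                  .nd(p[[paste0(pre, "fb2")]]))
  }
  ad_add(att, ff)
}

#' Apply one transformer block
#'
#' Pre-norm block: layer norm, multi-head attention with residual, layer
#' norm, feed-forward (convolutional or MLP variant) with residual. Output
#' shape equals input shape for both variants.
#'
#' @param tokens `(n x d)` token matrix or node
#' @param G an initialized generator (for spec and parameters)
#' @param i block index
#' @return token matrix (or node) of the same shape
#' @export
transformer_block <- function(tokens, G, i) {
  tg <- .nd(tokens)
  if (nrow(tg$value) != prod(G$spec$grid_shape)) {
    afn_stop("token count inconsistent with grid_shape", "afn_shape_error")
  }
  out <- .block_forward(tg, G$params, G$spec, i)
  if (inherits(tokens, "ad_node")) out else ad_value(out)
}

# full encoder on nodes; param list p may contain nodes or arrays
.encode_nodes <- function(image_node, p, spec) {
  tokens <- patch_embed(image_node, spec, p)
  tokens <- ad_add(tokens, ad_const(sinusoidal_positions(spec$grid_shape,
                                                         spec$embed_dim)))
  skips <- list()
  for (i in seq_len(spec$n_blocks)) {
    tokens <- .block_forward(tokens, p, spec, i)
    if (i %in% spec$skip_blocks) skips[[as.character(i)]] <- tokens
  }
  list(latent = tokens, skips = skips)
}

#' Encode a depth image to a latent token grid plus skip token grids
#'
#' @param image matrix of shape `spec$input_shape` (normalized model units)
#' @param G an initialized generator
#' @return list with `latent` (n x d matrix) and `skips` (named list keyed
#'   by block index)
#' @export
encode_image <- function(image, G) {
  enc <- .encode_nodes(ad_const(image), G$params, G$spec)
  list(latent = ad_value(enc$latent),
       skips = lapply(enc$skips, ad_value))
}

# decoder on nodes
.decode_nodes <- function(latent, skips, p, spec) {
  g <- spec$grid_shape
  x <- ad_reshape(latent, c(g[1], g[2], spec$embed_dim))
  # deeper blocks feed coarser stages: stage 1 (coarsest) takes the last
  # skip index, stage 3 the first
  order_idx <- rev(as.character(spec$skip_blocks))
  for (i in 1:3) {
    s <- skips[[order_idx[i]]]
    s3 <- ad_reshape(s, c(g[1], g[2], spec$embed_dim))
    cur <- dim_of(x$value)
    if (!all(dim_of(s3$value)[1:2] == cur[1:2])) {
      s3 <- ad_resize_bilinear(s3, cur[1], cur[2])
    }
    sp <- ad_conv2d(s3, .nd(p[[paste0("skip", i, "_w")]]),
                    .nd(p[[paste0("skip", i, "_b")]]), 1L, 0L)
    x <- ad_concat_ch(x, sp)
    x <- ad_relu(ad_conv2dt(x, .nd(p[[paste0("dec", i, "_w")]]),
                            .nd(p[[paste0("dec", i, "_b")]]), 2L, 1L))
  }
  y <- ad_conv2d(x, .nd(p$out_w), .nd(p$out_b), 1L, 0L)
  # internal maps are length x width; the pressure convention is
  # width x length, so resize then transpose the spatial axes
  y <- ad_resize_bilinear(y, spec$output_shape[2], spec$output_shape[1])
  y <- ad_transpose_hw(y)
  y <- ad_sigmoid(y)
  ad_reshape(y, spec$output_shape)
}

#' Decode a latent token grid (plus skips) to a pressure map
#'
#' @param latent `(n x d)` latent token matrix from [encode_image()]
#' @param skips named list of skip token matrices from [encode_image()]
#' @param G an initialized generator
#' @return pressure map in model units `[0, 1]`, shape `spec$output_shape`
#' @export
decode_latent <- function(latent, skips, G) {
  missing <- setdiff(as.character(G$spec$skip_blocks), names(skips))
  if (length(missing) > 0) {
    afn_stop(paste0("decoder stage missing skip tensor(s) for block(s) ",
                    paste(missing, collapse = ", ")), "afn_shape_error")
  }
  ad_value(.decode_nodes(ad_const(latent), lapply(skips, ad_const),
                         G$params, G$spec))
}

# build the full generator graph with parameter nodes; returns output node
# and the named parameter-node list (for gradient reads)
generator_graph <- function(G, image) {
  pnodes <- lapply(G$params, ad_param)
  enc <- .encode_nodes(ad_const(image), pnodes, G$spec)
  out <- .decode_nodes(enc$latent, enc$skips, pnodes, G$spec)
  list(out = out, pnodes = pnodes)
}

#' Run the generator forward
#'
#' @param G an initialized generator
#' @param image normalized depth matrix of shape `spec$input_shape`
#' @return generated pressure map in model units, shape `spec$output_shape`
#' @export
generator_forward <- function(G, image) {
  ad_value(generator_graph(G, image)$out)
}
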