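# PatchGAN discriminator and U-Net baseline generator.

#' PatchGAN discriminator specification
#'
#' The discriminator sees the depth image (resized to the pressure grid) and
#' a real or generated pressure map as a two-channel image and emits a 2-d
#' grid of patch logits, each judging one local receptive field.
#'
#' @param n_layers number of stride-2 convolution layers (kernel 4, pad 1)
#' @param base_channels channels of the first layer (doubling per layer)
#' @param input_shape common (rows, cols) grid of the pair
#' @return a `discriminator_spec` list; `receptive_field` gives the analytic
#'   receptive-field edge of one output logit in input pixels
#' @export
discriminator_spec <- function(n_layers = 3L, base_channels = 64L,
                               input_shape = c(27L, 64L)) {
  rf <- 1L
  for (i in seq_len(n_layers)) rf <- rf * 2L + 2L  # k=4, s=2: r <- r*s + (k-s)
  structure(list(n_layers = as.integer(n_layers),
                 base_channels = as.integer(base_channels),
                 input_shape = as.integer(input_shape),
                 receptive_field = rf),
            class = "discriminator_spec")
}

#' Initialize a PatchGAN discriminator
#' @param spec a [discriminator_spec()]
#' @param seed integer seed
#' @return a `patchgan_discriminator` list
#' @export
init_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  with_seed(derive_seed(seed, "discriminator_init"), {
    params <- list()
    cin <- 2L
    for (i in seq_len(spec$n_layers)) {
      cout <- spec$base_channels * 2L^(i - 1L)
      params[[paste0("c", i, "_w")]] <- .init_mat(4L, 4L, cin, cout)
      params[[paste0("c", i, "_b")]] <- numeric(cout)
      cin <- cout
    }
    params$out_w <- .init_mat(1L, 1L, cin, 1L)
    params$out_b <- numeric(1L)
    structure(list(spec = spec, params = params, seed = as.integer(seed)),
              class = "patchgan_discriminator")
  })
}

#' @export
print.patchgan_discriminator <- function(x, ...) {
  cat(sprintf("patchgan_discriminator: %d stride-2 layers, base %d channels, receptive field %d px, %s parameters\n",
              x$spec$n_layers, x$spec$base_channels, x$spec$receptive_field,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# resize a depth matrix to the pressure grid and flip to its orientation
condition_depth <- function(depth, input_shape) {
  Rh <- bilinear_matrix(nrow(depth), input_shape[2])
  Rw <- bilinear_matrix(ncol(depth), input_shape[1])
  t(Rh %*% depth %*% t(Rw))
}

# discriminator graph on nodes; pressure may be an ad_node (for generator
# updates), depth is always a constant conditioning input
discriminator_graph <- function(D, depth, pressure, trainable = TRUE) {
  spec <- D$spec
  pnodes <- lapply(D$params, if (trainable) ad_param else ad_const)
  dch <- condition_depth(depth, spec$input_shape)
  pn <- .nd(pressure)
  if (!all(dim_of(pn$value) == spec$input_shape)) {
    afn_stop("pressure map misaligned with discriminator input grid",
             "afn_shape_error")
  }
  x <- ad_concat_ch(ad_reshape(pn, c(spec$input_shape, 1L)),
                    ad_const(array(dch, c(spec$input_shape, 1L))))
  for (i in seq_len(spec$n_layers)) {
    x <- ad_lrelu(ad_conv2d(x, pnodes[[paste0("c", i, "_w")]],
                            pnodes[[paste0("c", i, "_b")]], 2L, 1L), 0.2)
  }
  logits <- ad_conv2d(x, pnodes$out_w, pnodes$out_b, 1L, 0L)
  list(logits = logits, pnodes = pnodes)
}

#' Run the discriminator on a depth/pressure pair
#'
#' @param D an initialized discriminator
#' @param depth depth matrix (any shape; resized to the pressure grid)
#' @param pressure pressure map matrix of shape `spec$input_shape`
#' @return list with `logits` (2-d patch logit map) and `prob` (scalar
#'   `D(x|y)`: the mean per-patch sigmoid probability)
#' @export
discriminator_forward <- function(D, depth, pressure) {
  gr <- discriminator_graph(D, depth, pressure, trainable = FALSE)
  lg <- ad_value(gr$logits)
  lg <- matrix(lg, dim(lg)[1], dim(lg)[2])
  list(logits = lg, prob = mean(1 / (1 + exp(-lg))))
}

#' U-Net baseline generator specification and initialization
#'
#' A standard contracting/expanding convolutional generator with mirror skip
#' concatenations and the same input/output contract as the transformer
#' generator.
#'
#' @param input_shape padded model input (rows, cols)
#' @param base_channels first-level channel count (doubling per level)
#' @param n_levels number of stride-2 down/up levels
#' @param output_shape generated pressure map shape
#' @param seed integer seed
#' @return a `unet_generator` list
#' @export
init_unet <- function(input_shape = c(128L, 56L), base_channels = 32L,
                      n_levels = 3L, output_shape = c(27L, 64L), seed = 1L) {
  spec <- structure(list(input_shape = as.integer(input_shape),
                         base_channels = as.integer(base_channels),
                         n_levels = as.integer(n_levels),
                         output_shape = as.integer(output_shape)),
                    class = "unet_spec")
  with_seed(derive_seed(seed, "unet_init"), {
    params <- list()
    cin <- 1L
    for (i in seq_len(n_levels)) {
      cout <- base_channels * 2L^(i - 1L)
      params[[paste0("enc", i, "_w")]] <- .init_mat(4L, 4L, cin, cout)
      params[[paste0("enc", i, "_b")]] <- numeric(cout)
      cin <- cout
    }
    for (i in seq_len(n_levels)) {
      lvl <- n_levels - i + 1L
      cout <- if (lvl > 1L) base_channels * 2L^(lvl - 2L) else base_channels
      # input: previous decoder output (or bottleneck) + mirror encoder skip
      skip_ch <- if (lvl > 1L) base_channels * 2L^(lvl - 2L) else 1L
      params[[paste0("dec", i, "_w")]] <- .init_mat(4L, 4L, cout, cin)
      params[[paste0("dec", i, "_b")]] <- numeric(cout)
      cin <- cout + skip_ch
    }
    params$out_w <- .init_mat(1L, 1L, cin, 1L)
    params$out_b <- numeric(1L)
    structure(list(spec = spec, params = params, seed = as.integer(seed)),
              class = "unet_generator")
  })
}

#' @export
print.unet_generator <- function(x, ...) {
  cat(sprintf("unet_generator: %d levels, base %d channels, %s parameters\n",
              x$spec$n_levels, x$spec$base_channels,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

unet_graph <- function(U, image) {
  spec <- U$spec
  pnodes <- lapply(U$params, ad_param)
  x <- ad_reshape(ad_const(image), c(spec$input_shape, 1L))
  feats <- list(x)
  for (i in seq_len(spec$n_levels)) {
    x <- ad_lrelu(ad_conv2d(x, pnodes[[paste0("enc", i, "_w")]],
                            pnodes[[paste0("enc", i, "_b")]], 2L, 1L), 0.2)
    feats[[i + 1L]] <- x
  }
  for (i in seq_len(spec$n_levels)) {
    x <- ad_relu(ad_conv2dt(x, pnodes[[paste0("dec", i, "_w")]],
                            pnodes[[paste0("dec", i, "_b")]], 2L, 1L))
    skip <- feats[[spec$n_levels - i + 1L]]
    x <- ad_concat_ch(x, skip)
  }
  y <- ad_conv2d(x, pnodes$out_w, pnodes$out_b, 1L, 0L)
  y <- ad_resize_bilinear(y, spec$output_shape[2], spec$output_shape[1])
  y <- ad_transpose_hw(y)
  y <- ad_sigmoid(y)
  list(out = ad_reshape(y, spec$output_shape), pnodes = pnodes)
}

# generic graph builder used by training; dispatches on generator class.
# function_generator wraps an arbitrary image -> map function (constant or
# oracle predictors for baselines and evaluation checks).
model_graph <- function(model, image) {
  if (inherits(model, "attnfnet_generator")) generator_graph(model, image)
  else if (inherits(model, "unet_generator")) unet_graph(model, image)
  else if (inherits(model, "function_generator")) {
    list(out = ad_const(model$fn(image)), pnodes = list())
  } else afn_stop("unknown generator class", "afn_spec_error")
}

#' Run the U-Net baseline forward
#' @param U an initialized U-Net from [init_unet()]
#' @param image normalized depth matrix of shape `spec$input_shape`
#' @return generated pressure map in model units
#' @export
unet_forward <- function(U, image) {
  ad_value(unet_graph(U, image)$out)
}
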