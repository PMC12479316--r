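# Alternating conditional-GAN optimization: one discriminator update on a
# detached generator output, then one generator update through a fresh
# discriminator evaluation, per sample (batch size 1).

#' Training configuration
#'
#' @param learning_rate Adam step size (full-scale defaults: 1e-4 for the
#'   transformer generator, 2e-4 for the U-Net baseline)
#' @param adam_beta1,adam_beta2 Adam decay rates
#' @param epochs training epochs
#' @param batch_size samples per update (1, as in the training recipe)
#' @param seed master integer seed (initialization + shuffling substreams)
#' @param checkpoint_every epochs between checkpoints
#' @param variant generator variant: `"attnfnet"`, `"vit_mlp"` or `"unet"`
#' @return a `train_config` list
#' @export
train_config <- function(learning_rate = 1e-4, adam_beta1 = 0.5,
                         adam_beta2 = 0.999, epochs = 90L, batch_size = 1L,
                         seed = 1L, checkpoint_every = 10L,
                         variant = c("attnfnet", "vit_mlp", "unet")) {
  variant <- match.arg(variant)
  if (learning_rate <= 0) afn_stop("learning_rate must be > 0", "afn_value_error")
  if (adam_beta1 < 0 || adam_beta1 >= 1 || adam_beta2 < 0 || adam_beta2 >= 1) {
    afn_stop("Adam betas must lie in [0, 1)", "afn_value_error")
  }
  if (epochs < 1) afn_stop("epochs must be >= 1", "afn_value_error")
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 variant = variant),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like), t = 0L)
}

# one Adam update; returns list(params, state)
adam_step <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# scalar D(x|y) node: mean per-patch sigmoid probability, clamped for logs
.dprob_node <- function(logits, eps = 1e-7) {
  ad_clamp(ad_mean(ad_sigmoid(logits)), eps, 1 - eps)
}

# discriminator loss on probability nodes
.dloss_node <- function(dr, df, cfg) {
  ad_neg(ad_add(
    ad_add(ad_scale(ad_log(dr), cfg$y_real),
           ad_scale(ad_log(ad_addc(ad_neg(dr), 1)), 1 - cfg$y_real)),
    ad_add(ad_scale(ad_log(df), cfg$y_gen),
           ad_scale(ad_log(ad_addc(ad_neg(df), 1)), 1 - cfg$y_gen))))
}

#' One alternating cGAN training step on a single preprocessed sample
#'
#' Runs the generator forward, updates the discriminator on the real pair
#' and the detached generated pair, then updates the generator through a
#' fresh evaluation of the updated discriminator (whose parameters receive
#' no gradient).
#'
#' @param x normalized depth matrix
#' @param y normalized ground-truth pressure map
#' @param G generator (transformer or U-Net)
#' @param D PatchGAN discriminator
#' @param opt_g,opt_d Adam states from `adam_init`
#' @param cfg a [train_config()]
#' @param loss_cfg a [loss_config()]
#' @return list with updated `G`, `D`, `opt_g`, `opt_d`, and the step's
#'   `loss_d`, `loss_g`
#' @export
train_step <- function(x, y, G, D, opt_g, opt_d, cfg, loss_cfg) {
  # generator forward (graph kept for the G update)
  gg <- model_graph(G, x)
  fake <- ad_value(gg$out)

  # --- discriminator update (generator output detached) ---
  dg_real <- discriminator_graph(D, x, ad_const(y), trainable = TRUE)
  dg_fake <- discriminator_graph(D, x, ad_const(fake), trainable = TRUE)
  ld <- .dloss_node(.dprob_node(dg_real$logits), .dprob_node(dg_fake$logits),
                    loss_cfg)
  if (!is.finite(ad_value(ld))) {
    afn_stop("non-finite discriminator loss", "afn_numeric_error")
  }
  ad_backward(ld)
  dgrads <- lapply(names(D$params), function(k) {
    ad_grad(dg_real$pnodes[[k]]) + ad_grad(dg_fake$pnodes[[k]])
  })
  names(dgrads) <- names(D$params)
  upd <- adam_step(D$params, dgrads, opt_d, cfg$learning_rate,
                   cfg$adam_beta1, cfg$adam_beta2)
  D$params <- upd$params
  opt_d <- upd$state

  # --- generator update through the updated, frozen discriminator ---
  dg_g <- discriminator_graph(D, x, gg$out, trainable = FALSE)
  lg <- ad_add(ad_neg(ad_log(.dprob_node(dg_g$logits))),
               ad_scale(ssiml2_ad(ad_const(y), gg$out, loss_cfg),
                        loss_cfg$lambda))
  if (!is.finite(ad_value(lg))) {
    afn_stop("non-finite generator loss", "afn_numeric_error")
  }
  ad_backward(lg)
  ggrads <- lapply(gg$pnodes, ad_grad)
  upd <- adam_step(G$params, ggrads, opt_g, cfg$learning_rate,
                   cfg$adam_beta1, cfg$adam_beta2)
  G$params <- upd$params
  opt_g <- upd$state

  list(G = G, D = D, opt_g = opt_g, opt_d = opt_d,
       loss_d = ad_value(ld), loss_g = ad_value(lg))
}

# validation MSE/SSIM in model units; no parameter updates
.validate <- function(G, xs, ys, loss_cfg) {
  mses <- numeric(length(xs))
  ssims <- numeric(length(xs))
  for (i in seq_along(xs)) {
    g <- ad_value(model_graph(G, xs[[i]])$out)
    mses[i] <- mean((ys[[i]] - g)^2)
    ssims[i] <- ssim(ys[[i]], g, loss_cfg$ssim)
  }
  list(mse = mean(mses), ssim = mean(ssims))
}

#' Train a conditional GAN on a synthetic dataset
#'
#' Preprocesses and normalizes the dataset (train-split statistics),
#' initializes generator and discriminator from the seed, and runs the
#' alternating optimization with per-epoch seeded shuffling. Validation MSE
#' and SSIM are computed each epoch without touching parameters; the
#' best-validation-MSE generator is retained alongside the final one.
#'
#' @param dataset a `synthetic_dataset` from [generate_dataset()]
#' @param cfg a [train_config()]
#' @param loss_cfg a [loss_config()]
#' @param gen_spec a [generator_spec()] (ignored for the `"unet"` variant)
#' @param disc_spec a [discriminator_spec()]
#' @param pp_config a [preprocess_config()]
#' @param unet_base base channels of the U-Net variant
#' @param verbose print one line per epoch
#' @return list with `G` (final), `G_best` (best validation MSE), `D`,
#'   `history` (per-epoch data frame), `prepared` (normalized data and
#'   statistics), and the configurations
#' @export
fit_cgan <- function(dataset, cfg = train_config(), loss_cfg = loss_config(),
                     gen_spec = generator_spec(),
                     disc_spec = discriminator_spec(),
                     pp_config = preprocess_config(),
                     unet_base = 32L, verbose = FALSE) {
  prepared <- prepare_training_data(dataset, pp_config)
  if (length(prepared$train$x) == 0 || length(prepared$val$x) == 0) {
    afn_stop("train and val splits must be nonempty", "afn_input_error")
  }
  G <- switch(cfg$variant,
    attnfnet = init_generator(gen_spec, seed = cfg$seed),
    vit_mlp = {
      gs <- gen_spec; gs$ff_variant <- "mlp"
      gs$ff_hidden <- 2L * gs$embed_dim
      init_generator(gs, seed = cfg$seed)
    },
    unet = init_unet(input_shape = pp_config$pad_to,
                     base_channels = unet_base,
                     output_shape = pp_config$target_pressure_shape,
                     seed = cfg$seed))
  # prior initialization of the output bias: the sigmoid output starts at
  # the train-split mean pressure level instead of 0.5, so optimization
  # spends its steps on structure rather than on the global offset
  prior <- mean(vapply(prepared$train$y, mean, numeric(1)))
  prior <- min(max(prior, 1e-3), 1 - 1e-3)
  G$params$out_b <- stats::qlogis(prior)
  D <- init_discriminator(disc_spec, seed = cfg$seed)
  opt_g <- adam_init(G$params)
  opt_d <- adam_init(D$params)
  n_train <- length(prepared$train$x)
  history <- data.frame(epoch = integer(), loss_g = numeric(),
                        loss_d = numeric(), val_mse = numeric(),
                        val_ssim = numeric())
  best_mse <- Inf
  G_best <- G
  checkpoints <- list()
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("shuffle_", ep)),
                     sample.int(n_train))
    lgs <- numeric(n_train)
    lds <- numeric(n_train)
    for (ii in seq_along(ord)) {
      i <- ord[ii]
      st <- train_step(prepared$train$x[[i]], prepared$train$y[[i]],
                       G, D, opt_g, opt_d, cfg, loss_cfg)
      G <- st$G; D <- st$D; opt_g <- st$opt_g; opt_d <- st$opt_d
      lgs[ii] <- st$loss_g
      lds[ii] <- st$loss_d
    }
    val <- .validate(G, prepared$val$x, prepared$val$y, loss_cfg)
    history <- rbind(history, data.frame(
      epoch = ep, loss_g = mean(lgs), loss_d = mean(lds),
      val_mse = val$mse, val_ssim = val$ssim))
    if (val$mse < best_mse) {
      best_mse <- val$mse
      G_best <- G
    }
    if (cfg$checkpoint_every > 0L && ep %% cfg$checkpoint_every == 0L) {
      checkpoints[[length(checkpoints) + 1L]] <- list(epoch = ep, G = G)
    }
    if (verbose) {
      cat(sprintf("epoch %3d  L_G %.4f  L_D %.4f  val MSE %.6f  val SSIM %.4f\n",
                  ep, mean(lgs), mean(lds), val$mse, val$ssim))
    }
  }
  list(G = G, G_best = G_best, D = D, history = history,
       prepared = prepared, checkpoints = checkpoints,
       cfg = cfg, loss_cfg = loss_cfg, pp_config = pp_config)
}

#' Predict a raw-unit pressure map from a normalized depth image
#'
#' Single deterministic forward pass followed by denormalization with the
#' train-split pressure statistics. Convert to kPa with
#' [calibrate_to_kpa()].
#'
#' @param G trained (or initialized) generator
#' @param depth_norm normalized depth matrix of shape `spec$input_shape`
#' @param pressure_stats `norm_stats` of the train-split pressure maps
#' @param pressure_range normalization range used for pressure
#' @return pressure map in raw sensor units, clamped nonnegative
#' @export
predict_pressure <- function(G, depth_norm, pressure_stats,
                             pressure_range = c(0, 1)) {
  g <- ad_value(model_graph(G, depth_norm)$out)
  pmax(denormalize_image(g, pressure_stats, pressure_range), 0)
}

#' Mean-map constant predictor baseline
#'
#' The constant predictor that outputs the pixelwise mean of the train-split
#' pressure maps; its validation MSE is the floor any learning model must
#' beat.
#'
#' @param prepared output of [prepare_training_data()]
#' @return list with `mean_map` and `val_mse`
#' @export
constant_baseline <- function(prepared) {
  mean_map <- Reduce(`+`, prepared$train$y) / length(prepared$train$y)
  val_mse <- mean(vapply(prepared$val$y,
                         function(y) mean((y - mean_map)^2), numeric(1)))
  list(mean_map = mean_map, val_mse = val_mse)
}

#' Desk-scale training preset
#'
#' A structurally identical, minutes-on-one-CPU configuration: 8 subjects on
#' a 64 x 56 depth grid (8 x 7 patch grid), 64-dimensional embeddings, 4
#' heads, 6 transformer blocks with skips from blocks 3/4/5, 5 epochs.
#'
#' @param seed master integer seed
#' @param variant generator variant
#' @return list with `data_args`, `gen_spec`, `disc_spec`, `train_cfg`,
#'   `loss_cfg`, `pp_config`
#' @export
tiny_preset <- function(seed = 1L, variant = "attnfnet") {
  list(
    data_args = list(n_subjects = 8L, poses_per_subject = 9L,
                     split_fractions = c(0.6, 0.2, 0.2), seed = seed,
                     grid_shape = c(64L, 56L)),
    gen_spec = generator_spec(input_shape = c(64L, 56L), patch_size = 8L,
                              embed_dim = 64L, n_blocks = 6L, n_heads = 4L,
                              skip_blocks = c(3L, 4L, 5L),
                              decoder_channels = c(48L, 32L, 16L),
                              skip_proj_channels = 8L),
    disc_spec = discriminator_spec(n_layers = 3L, base_channels = 16L),
    train_cfg = train_config(learning_rate = 2e-3, epochs = 5L, seed = seed,
                             checkpoint_every = 0L, variant = variant),
    loss_cfg = loss_config(),
    pp_config = preprocess_config(pad_to = c(64L, 56L))
  )
}
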