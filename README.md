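# attnfnet

Estimating the contact pressure between a bedridden person and their
mattress is central to pressure-ulcer prevention, but pressure-sensing mats
are expensive and drift-prone, while overhead depth cameras are cheap and
contactless. **attnfnet** translates a single depth image of a person lying
on a bed into the 27 × 64 contact-pressure map a sensing mat would record,
in calibrated kPa, so pressure hot-spots and even body weight can be
monitored from depth alone.

The package implements, in pure R:

* **AttnFnet**, a hybrid generator: a vision-transformer encoder — strided
  convolutional patch embedding to 712-dimensional tokens, fixed sinusoidal
  positional encodings, 12 pre-norm transformer blocks whose feed-forward
  stage is a pair of 3 × 3 convolutions over the token grid (the
  distinguishing *conv* variant; a token-wise MLP variant is one switch
  away) — feeding a lightweight deconvolutional decoder with skip
  connections from blocks 6, 8 and 10;
* a **PatchGAN discriminator** and label-smoothed conditional-GAN training
  (targets 0.9 / 0.1, Adam with β₁ = 0.5, β₂ = 0.999, batch size 1) with the
  mixed perceptual objective

  L_G = −log D(x | G(x)) + λ [ α (1 − SSIM(y, G(x))) + β MSE(y, G(x)) ],
  λ = 100, α = 300, β = 1;

* the preprocessing stack: no-return depth-pixel repair by iterated 3 × 3
  median, area-average downsampling of pressure maps to 27 × 64 with
  Gaussian smoothing (σ = 1.4), train-split min–max normalization, and
  per-subject raw-to-kPa calibration;
* the evaluation suite: pixel prediction accuracy, SSIM, MSE (raw and
  kPa²), PSNR, posture IOU (largest 4-connected super-threshold regions),
  Fréchet distance with a pluggable feature embedder, per-posture deviation
  maps, and body-weight estimation from calibrated pressure
  (Σp·A_sensor / g);
* a **synthetic body-on-mattress generator** (7-lobe Gaussian body model,
  three postures, exact force conservation: the pressure map integrates to
  the subject's weight) so the whole pipeline trains and evaluates on one
  CPU with no downloads;
* a **U-Net baseline** generator with the same input/output contract.

Because no deep-learning framework is assumed, the models run on a small
reverse-mode automatic-differentiation engine included in the package and
verified against numeric gradients.

## Worked example

Train the desk-scale preset (8 synthetic subjects, 64-dimensional tokens, 6
blocks, 5 epochs — structurally identical to the full-scale model) and
evaluate on held-out subjects:

```r
library(attnfnet)

preset  <- tiny_preset(seed = 1)
dataset <- do.call(generate_dataset, preset$data_args)
dataset
#> synthetic_dataset: 72 samples, 8 subjects (train 6 / val 1 / test 1), seed 1

fit <- fit_cgan(dataset, preset$train_cfg, preset$loss_cfg,
                preset$gen_spec, preset$disc_spec, preset$pp_config,
                verbose = TRUE)
#> epoch   1  L_G 11782.6250  L_D 1.3811  val MSE 0.003532  val SSIM 0.8358
#> ...
#> epoch   4  L_G 4659.4476  L_D 1.3860  val MSE 0.000507  val SSIM 0.9550
#> epoch   5  L_G 4102.2334  L_D 1.3869  val MSE 0.001114  val SSIM 0.8982

constant_baseline(fit$prepared)$val_mse   # the floor a learner must beat
#> [1] 0.002357323

report <- evaluate_model(fit$G_best, fit$prepared)
report
#> metric_report over 9 test samples:
#>   MPPA 0.8920  MSSIM 0.9364  MSE 5.967569 (raw) 0.0845 (kPa^2)
#>   MPSNR 28.10 dB  MIOU 0.8975  MFID 3.8305  mean |dW| 8.27 kg
```

The generator's best validation MSE (0.00051, model units) is ~4.7× below
the constant-mean-predictor baseline: the network has learned the
depth→pressure mapping, not just the average map. On the held-out subject,
predictions match the true pressure maps with SSIM 0.94 and locate the main
pressure region with IOU 0.90; integrating the predicted maps recovers body
weight to 8.3 kg at this desk scale. Ground-truth synthetic pressure maps
recover weight exactly (`estimate_weight(render_pressure(...))` is
conservative by construction). The MFID value uses the built-in seeded
random-projection embedder, so it is comparable across runs of this package
but not to FID values computed with a pretrained Inception network.

Estimate weight from any calibrated map:

```r
estimate_weight(matrix(1, 27, 64), sensor_area_m2 = 0.001)
#> [1] 176.1468       # uniform 1 kPa over 1728 cells of 10 cm^2
```

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "attnfnet.R", package = "attnfnet"))')" \
  simulate --n-subjects 8 --seed 1 --out data/
```

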