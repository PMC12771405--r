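# gardenseg

Pixel-level segmentation of plant disease lesions in R, built around two
ideas for the two things that make lesion imagery hard:

* **Lesion scale varies wildly.** Per-image lesion area fractions in real
  collections are strongly right-skewed — many minute spots, a long tail
  of large coalesced regions. A **multi-scale context aggregation (MSCA)**
  bottleneck pools the deepest encoder map at several fixed sizes
  (default pyramid 1, 2, 3, 6), reduces each branch with a 1×1
  convolution, upsamples and concatenates:
  `f_MSCA = Concat(f_in, ⊕_s Up(Conv1x1(AvgPool_s(f_in))))`.
* **Lesion boundaries are soft.** Every decoder stage runs a
  **boundary-aware selective scanning (BASS)** block: a learnable,
  Sobel-initialized gradient operator predicts a continuous boundary
  prior `M_b = σ(Conv1x1(Concat(G_x, G_y)))`; a gate `α = σ(γ·M_b + β)`
  converts it into a per-pixel mixing field; four directional selective
  state-space scans (`h_t = Ā_t h_{t-1} + B̄_t u_t`, `y_t = C_t·h_t + D u_t`
  along the four raster traversals) provide long-range evidence `Z(d)`;
  and the block blends `Z̃(d) = (1−α)⊙X̂ + α⊙Z(d)` before fusing,
  projecting back and adding the residual. Boundary-uncertain pixels get
  long-range support; confident interiors keep local evidence.

The rest of the network is a standard four-stage U-shaped encoder–decoder
with channel-wise cross-attention (CCA) on the skip connections. The
package also ships the training protocol (Adam 1e-4, combined
0.5·Dice + 0.5·cross-entropy loss on logits, reduce-on-plateau schedule
0.5/10, batch 8), overlap metrics (Dice, mIoU, precision, recall,
specificity, accuracy from global pixel counts), a synthetic leaf-lesion
generator whose per-image lesion fraction follows a truncated lognormal
matching published collection statistics, and a lesion-scale statistics
tool. There is no deep-learning framework underneath: the network, the
reverse-mode autodiff and all kernels (convolution, pooling, bilinear
resampling, the selective scan) are implemented in R and C++ in this
package.

Intended users: researchers in quantitative plant pathology / agricultural
image analysis who want a transparent, dependency-light reference
implementation of boundary-gated selective scanning, and methods
developers who want its components (`selective_scan_1d`, `cross_scan`,
`ggbp_forward`, `bass_forward`, `msca_forward`, `cca_refine`) as
building blocks.

## Worked example

Generate a synthetic lesion benchmark, train a compact model, evaluate,
and analyze lesion scale:

```r
library(gardenseg)

profile  <- synthetic_profile(image_size = 64, n_images = 250, seed = 0)
generate_dataset(profile, "data/synth")

cfg  <- garden_config(base_width = 8, msca = msca_config(c(1, 2, 3)),
                      image_size = 64)
tcfg <- train_config(epochs = 15, image_size = 64, seed = 0)
run  <- run_training(cfg, tcfg, "data/synth", "runs/demo", verbose = TRUE)
#> epoch   1  lr 1.00e-04  train 0.6442  val 0.6250  dice 0.0000
#> ...
#> epoch   9  lr 1.00e-04  train 0.3474  val 0.3451  dice 0.7466
#> ...
#> epoch  15  lr 1.00e-04  train 0.2628  val 0.2768  dice 0.8168

unlist(evaluate_model(run$best_path, "data/synth", "test"))
#>    accuracy        dice   precision specificity      recall      iou_fg
#>   0.9549268   0.8195908   0.9574429   0.9946905   0.7164383   0.6943276
#>        miou
#>   0.8220567

st <- lesion_stats("data/synth/train/masks")
round(c(st$mean, st$median, st$std), 2)
#> 15.50 13.04 10.79
```

Readings: the held-out Dice (0.82 here) is the overlap between predicted
and true lesion masks over the whole test split's pixels; mIoU averages
foreground and background IoU and sits close to Dice. Early validation
Dice is 0 by construction — the head starts at the minority-class prior,
so no pixel crosses the 0.5 threshold until the lesion evidence builds
up, while the loss falls from the first epoch. The mask statistics show
the generator's right-skewed scale distribution (mean well above
median), the regime the MSCA bottleneck is designed for.
`predict_mask(run$best_path, "leaf.png", "mask.png")` writes a
{0, 255} mask at the input's native resolution. A thin CLI over the same
functions is installed at `inst/cli/garden.R`
(`train` / `eval` / `predict` / `synth` / `stats`).

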