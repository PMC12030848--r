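# dynspec

Pixel-wise land-cover classification of multispectral satellite imagery,
built for vegetation mapping workflows (crop/forest monitoring over
4-band B/G/R/NIR or 12-band Sentinel-2-like scenes), plus the land-cover
change-dynamics bookkeeping that usually follows classification.

## The model

Each labelled pixel is a reflectance spectrum `x ∈ R^C` (C bands). Two
feature branches act in parallel on the spectrum:

* **Omni-dimensional dynamic convolution (ODConv).** The effective kernel
  is an attention-weighted combination of `n` candidate kernels,

  `y = (α_w1 ⊙ α_f1 ⊙ α_c1 ⊙ α_s1 ⊙ W_1 + … + α_wn ⊙ α_fn ⊙ α_cn ⊙ α_sn ⊙ W_n) * x`,

  where the four attention vectors modulate each candidate kernel along
  the spatial (`α_s`), input-channel (`α_c`), output-channel (`α_f`) and
  kernel (`α_w`, softmax — a convex combination) axes. The attentions are
  computed per input by a pooled bottleneck MLP, so the convolution adapts
  its weights to each pixel's spectrum.

* **Improved large-selective-kernel block (LSK).** A large receptive
  field decomposed into serial depthwise branches (5×5, then 7×7 with
  dilation 3), each 1×1-projected; channel-wise average and max pooling
  give two spatial descriptors, `SA = F_{2→N}([SA_avg; SA_max])` maps them
  to one raw attention per branch, sigmoid masks `σ(SA_i)` gate each
  branch, and a 1×1 convolution fuses `Σ_i σ(SA_i)·U_i`. The improved
  variant first refines the block input by multi-head self-attention over
  the spatial tokens (residual).

The fused features are read band-by-band as a sequence by a two-layer
gated recurrent unit (update gate `z`, reset gate `r`, hidden width 128),
and the final state is classified by an MLP head (128 → 256 → M classes,
ReLU, softmax). Training minimises mean cross-entropy
`L = −(1/N) Σ_i Σ_c y_ic log p_ic` with Adam, batch size 32, and a 0.9
per-epoch learning-rate decay. Accuracy is reported as overall accuracy
(OA), average per-class accuracy (AA) and Cohen's kappa
`(P_l − P_x)/(1 − P_x)` from the confusion matrix.

Because no public labelled scenes accompany this workflow, the package
ships a seeded simulator: class-conditional Gaussian spectra (seven-class
legend — River, Buildup, Sugarcane, Tree, Barren, Pond, Other — with the
NDVI-like near-infrared elevation for vegetation) arranged in spatially
contiguous regions, with optional mixed boundary pixels.

## Worked example

```r
library(dynspec)

spec <- scene_spec(height = 96, width = 96, bands = 12, n_classes = 7,
                   seed = 42)
sim <- generate_scene(spec)
roi <- generate_roi(sim$labels, n_per_class = 120, seed = 43,
                    class_names = spec$class_names)

samples <- sim$scene |>
  extract_samples(roi) |>
  split_samples(train_frac = 0.6, seed = 44)

fit <- fit_network(samples, network_config(bands = 12, n_classes = 7),
                   train_config(max_epochs = 15, seed = 45))
evaluate_network(fit, samples)
#> <metrics_report> OA 93.75%  AA 93.75% (mean_recall)  Kappa 0.9271
#> # A tibble: 7 × 3
#>   class         n accuracy
#>   <chr>     <int>    <dbl>
#> 1 River        48     79.2
#> 2 Buildup      48    100
#> 3 Sugarcane    48     97.9
#> 4 Tree         48     97.9
#> 5 Barren       48     97.9
#> 6 Pond         48     83.3
#> 7 Other        48    100
```

The report reads: 93.75% of the 336 held-out pixels are classified
correctly after 15 epochs, kappa 0.93 corrects that figure for chance
agreement, and the per-class rows show the residual confusion sits in the
two spectrally similar water classes (River vs Pond). `glance(fit)`
summarises the fit (15 epochs, 186,484 parameters, final training
accuracy 95.6%); `autoplot(fit)` draws the loss/accuracy curves and
`autoplot(evaluate_network(fit, samples))` the confusion heatmap.

Change analysis works on any pair of classified maps:

```r
class_areas(sim$labels, pixel_size = 10,
            class_names = spec$class_names)   # km² per class
change_rate(908.91, 1225.16)                  # +34.79 %
```

A command-line front end (subcommands `simulate`, `train`, `classify`,
`evaluate`, `change`, each driven by a YAML config with `--seed`/`--out`)
is installed at `system.file("cli", "dynspec-cli.R", package = "dynspec")`.

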