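# untca

Segmentation of corneal stromal cells (keratocytes) in confocal
microscopy images with **U-NTCA**: a U-shaped nnUNet-style
encoder–decoder augmented with recursive gated convolution (gnConv)
high-order channel attention and nested transformer blocks that
transmit multi-scale context bottom-up through the decoder.

Keratocyte segmentation supports the clinical assessment of corneal
disease (keratoconus, herpes simplex keratitis), but confocal fields are
frequently degraded by vessel occlusion and defocus. Plain skip
connections propagate those degradations; U-NTCA instead lets each
decoder junction attend jointly to its encoder skip $x_d$, its
up-sampled stream $x_u$, and a channel-attention-enhanced view
$g^n(x_u)$, and forwards a fused multi-scale bundle to the junction
above:

* gnConv: channels re-gridded onto a $\sqrt{C_0}\times\sqrt{C_0}$ plane
  (484 channels ↔ a 22×22 grid), width doubled by $\varphi_{in}$, then
  $n$ recursive gates $p_{k+1} = f_k(q_k)\odot g_k(p_k)$ with the
  channel schedule $C_k = C/2^{\,n-k-1}$;
* nested transformer: $\hat x_u = x_u + \mathrm{Attn}(x_u, x_d, g^n(x_u))$,
  $\hat x_c = x_c + \mathrm{Attn}(x_c, \hat x_u, x_d)$, a residual
  rectified FFN, and the convex fusion
  $\tilde x_u = \alpha x_u + (1-\alpha)\tilde x_c$ with $\alpha = 0.3$;
* recursive transmission: each junction emits
  $x_c^{(i+1)} = H(x_d, \hat x_u, x_c, g^n(x_u))$, with concatenation
  (default) or fixed-weight interpolation fusion in $H$.

The package is a complete, self-contained implementation: the network
core is a reverse-mode autodiff tape over dense arrays with C++
convolution kernels, plus a training pipeline (soft-Dice +
cross-entropy, SGD momentum 0.99, polynomial decay, 5-fold
cross-validation, paired augmentation), pixel metrics (Dice, accuracy,
recall, precision, AUC with stratified reporting), a seeded synthetic
generator of cell-like scenes in three imaging regimes (clear /
vessel-occluded / blurred), image I/O, heatmap export and a CLI. The
clinical dataset behind the published numbers is private; every
experiment here runs on the synthetic generator.

## Worked example

Generate a small synthetic dataset, train the reduced desk-scale model
for a few steps, and evaluate a held-out field:

```r
library(untca)
ds <- generateDataset(8, mix = c(5, 2, 1), size = 64, seed = 7, nCells = 6)
cfg <- reducedConfig()            # depth 3, widths 8/16/32, token width 64
m <- buildModel(cfg, seed = 1)
m
#> UNTCAModel: depth 3, widths [8,16,32], token widths [64,64], grid 16
#>   gnConv on (n = 3), transformer on, encoding 'concatenation'
#>   144 parameter arrays, 702,058 parameters, seed 1

fit <- trainModel(ds$samples[1:6], cfg,
                  trainConfig(steps = 150, batchSize = 2, seed = 1,
                              evalEvery = 50),
                  valDataset = ds$samples[7:8])
tail(fit$history, 2)
#>     step      loss  softDice           lr
#> 149  149 0.1347104 0.7508412 0.0002053264
#> 150  150 0.1086066 0.7976192 0.0001100317

pred <- predictMask(fit$model, ds$samples[[7]]$image)
evaluateSegmentation(list(pred$prob), list(ds$samples[[7]]$mask),
                     tags = ds$samples[[7]]$tag)
#> MetricReport (macro aggregation, 1 images)
#>       tag n  dice   acc recall precision   auc
#>  occluded 1 86.54 99.66  80.36     93.75 90.99
#>       all 1 86.54 99.66  80.36     93.75 90.99
```

The loss is the equally weighted soft-Dice + cross-entropy; `softDice`
is the differentiable batch Dice of the training step (0.80 above means
the model already reconstructs most cell area after 150 steps). The
report columns are percentages; on this vessel-occluded field the model
reaches Dice 86.5% with AUC 91.0% against the uncorrupted reference
mask. `exportHeatmap(pred$prob, "field7.png")` writes the cold-to-warm
confidence rendering.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/untca.R synth --n 40 --size 384 --mix 24,10,6 --seed 7 --out data/
Rscript inst/cli/untca.R train --data data/ --out runs/ --fold 1
Rscript inst/cli/untca.R predict --model runs/fold1.rds --data data/ --out preds/
Rscript inst/cli/untca.R eval --pred preds/ --truth data/ --tags data/manifest.csv --out report.csv
Rscript inst/cli/untca.R ablate --data data/ --out ablation/   # gnConv x transformer grid
```

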