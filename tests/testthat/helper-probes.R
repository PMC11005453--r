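# Desk-scale training probe on the synthetic generator, shared between
# the overfit-capacity and loss-decrease checks (run once per session).

.probeCache <- new.env(parent = emptyenv())

overfitProbe <- function() {
  if (!is.null(.probeCache$res)) return(.probeCache$res)
  ds <- tinyDataset(16, size = 64, seed = 11, nCells = 6)
  cfg <- reducedConfig()
  tc <- trainConfig(steps = 350L, batchSize = 2L, seed = 1L,
                    evalEvery = 1000L)
  fit <- trainModel(ds, cfg, tc)
  .probeCache$res <- list(fit = fit,
                          trainDice = evaluateDice(fit$model, ds))
  .probeCache$res
}
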