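# Desk-scale aligned models are expensive (minutes); fit each design once
# and cache it for every test block that needs it.
.modelCache <- new.env(parent = emptyenv())

alignedModel <- function(design, n = 300, liftDim = 100, seed = 3) {
  key <- paste(design, n, liftDim, seed, sep = "_")
  if (!is.null(.modelCache[[key]])) return(.modelCache[[key]])
  sim <- simulatePair(design, n = n, liftDim = liftDim, seed = seed)
  sr <- searchHyperparameters(
    sim@x, sim@y,
    grid = list(lambda_ortho = c(1, 0.1), lambda_topo = 1e-4),
    mode = "unsupervised",
    baseConfig = otConfig(max_epochs = 300, seed = seed))
  .modelCache[[key]] <- list(sim = sim, fit = sr$best, table = sr$table)
  .modelCache[[key]]
}
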