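# frozen study protocol used by the acceptance-style checks: a scaled
# version of the default simulation (sizes stated in the methods vignette)
# with the model configurations fixed ahead of the runs

protoCfg <- function(seed, nTarget = 150, sigma = 0.25) {
  simConfig(nTarget = nTarget, nDiscovery = 1500, nVariants = 2000,
            nChromosomes = 4, chromLen = 1e6, nCells = 160,
            nSpecificPeaks = 40, nSharedPeaks = 60, sigma = sigma,
            seed = seed)
}

# prioritization config: lasso on, so only consistently informative cells
# keep nonzero readout weights
protoPriorConfig <- function(seed = 1)
  scprsConfig(T = 1, lambda1 = 1, lambda2 = 1, lambda3 = 1,
              task = "regression", epochs = 150, seed = seed)

# prediction config: no lasso, ridge + Laplacian smoothing
protoPredConfig <- function(seed = 1)
  scprsConfig(T = 1, lambda1 = 0, lambda2 = 1, lambda3 = 1,
              task = "regression", epochs = 200, seed = seed)

protoPrep <- function(seed, nTarget = 150, sigma = 0.25) {
  st <- suppressWarnings(simStudy(protoCfg(seed, nTarget, sigma)))
  memb <- assignVariantsToPeaks(st$gwas$sumstats, peakRanges(st$atlas$cpm))
  tensor <- cellPRSTensor(st$target$genotypes, st$gwas$sumstats,
                          st$atlas$cpm, st$ld, memb)
  graph <- buildCellGraph(st$atlas$cpm, k = 15)
  list(st = st, tensor = tensor, graph = graph,
       labels = cellTypes(st$atlas$cpm))
}

# per-seed prepared studies for the prediction experiments, cached so the
# noise-ladder and ablation checks reuse the same five studies
.protoCache <- new.env(parent = emptyenv())
protoPrepCached <- function(seed, nTarget = 300) {
  key <- paste0("s", seed, "_", nTarget)
  if (is.null(.protoCache[[key]]))
    .protoCache[[key]] <- protoPrep(seed, nTarget = nTarget, sigma = 0)
  .protoCache[[key]]
}

# train on a split and return the held-out test Pearson r
protoTestR <- function(prep, y, fitSeed, splitSeed) {
  sp <- splitData(y, seed = splitSeed, stratify = FALSE)
  tn <- normalizePRS(prep$tensor, fitSamples = sp$train)
  fit <- scprsFit(prsScores(tn), prep$graph, y, protoPredConfig(fitSeed),
                  splits = sp)
  sc <- scprsPredict(fit, prsScores(tn)[sp$test, , , drop = FALSE],
                     prep$graph)
  cor(sc, y[sp$test])
}
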