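# scPRS: single-cell-resolved polygenic risk scoring

A polygenic risk score (PRS) summarizes a person's genetic liability to a
disease as one number, but it is silent about *where* that liability acts.
scPRS decomposes the PRS along a reference single-cell chromatin
accessibility atlas (scATAC-seq), producing per-cell genetic risk features,
and learns which cells carry disease-relevant risk. It is aimed at
statistical geneticists and single-cell biologists who have GWAS summary
statistics, an individual-level target cohort, and a cell-by-peak atlas, and
who want both prediction and cell-level interpretation from the same model.

## The method

For every cell *j* of the atlas, a clumping-and-thresholding (C+T) PRS is
computed with index variants restricted to that cell's open chromatin:

    PRS_nj = ( sum_{i in cCRE_j} beta_i * G_ni ) / (P * M_n)

with `beta_i` the GWAS effect size, `G_ni` the effect-allele dosage, ploidy
`P = 2` and `M_n` the individual's nonmissing variants among the index set.
Run over the grid r² ∈ {0.1, 0.3, 0.5} × p ∈ {1e-5, ..., 0.5} this yields
21 features per cell — a tensor `X` of individuals × cells × 21.

A small graph neural model over the mutual-kNN cell graph maps `X` to the
phenotype: a shared nonnegative embedding `h⁰ = X·abs(W0)`, T rounds of
degree-normalized neighbour averaging with nonnegative weights and a leaky
ReLU, and a readout `y = σ(β·h^T + b)`. The loss adds
`λ1‖β‖₁ + λ2‖β‖₂² + λ3 βᵀG_L β` (G_L the symmetric normalized graph
Laplacian) to the cross-entropy or squared error, trained with Adam
(lr 1e-3, batch 32, 200 epochs). Because every weight upstream of β is
nonnegative, larger risk features can never decrease a latent cell feature,
so the per-cell readout coefficients β are interpretable as cell relevance:
an ensemble of models over random seeds, a one-sided t-test of each cell's
weights against the pooled top-15% weights with Benjamini–Yekutieli
correction, and a Fisher exact test per cell type (Benjamini–Hochberg) turn
β into prioritized cells and cell types.

The package also ships the surrounding machinery: sumstats/genotype QC and
allele harmonization, LD estimation, LSI embeddings, nonpeak and
cell-type-level baseline PRSs, model-agnostic variant effect Z/Q scores,
variant-enrichment statistics, a covariate-adjusted differential
accessibility test, and a full simulation framework (block-LD genotypes,
synthetic atlas, simulated GWAS and phenotypes) so the entire pipeline runs
and is tested offline.

## Worked example

Simulate a study in which one cell type ("mono") carries the causal
variants inside its specific peaks, then recover that type:

```r
library(scPRS)

cfg <- simConfig(nTarget = 150, nDiscovery = 1500, nVariants = 2000,
                 nChromosomes = 4, chromLen = 1e6, nCells = 160,
                 nSpecificPeaks = 40, nSharedPeaks = 60,
                 sigma = 0.25, seed = 42)
study <- simStudy(cfg)

memb   <- assignVariantsToPeaks(study$gwas$sumstats,
                                peakRanges(study$atlas$cpm))
tensor <- cellPRSTensor(study$target$genotypes, study$gwas$sumstats,
                        study$atlas$cpm, study$ld, memb)
tensor
#> CellPRSTensor: 150 individuals x 160 cells x 21 grid points

graph <- buildCellGraph(study$atlas$cpm, k = 15)
graph
#> CellGraph: 160 cells, k=15, 744 undirected edges

ens <- fitEnsemble(prsScores(normalizePRS(tensor)), graph,
                   study$phenotype$yTilde,
                   scprsConfig(T = 1, lambda1 = 1, lambda2 = 1, lambda3 = 1,
                               task = "regression", epochs = 150),
                   nModels = 20, baseSeed = 1)
cells <- prioritizeCells(ens)
sum(cells$selected)
#> [1] 7

types <- celltypeEnrichment(cells$selected, cellTypes(study$atlas$cpm),
                            minCells = 30)
types[, c("cellType", "nCells", "nSelectedInType", "oddsRatio", "pAdj")]
#>   cellType nCells nSelectedInType oddsRatio         pAdj
#> 2     mono     40               7       Inf 0.0001599442
#> 1    bcell     40               0         0 1.0000000000
#> 3       nk     40               0         0 1.0000000000
#> 4    tcell     40               0         0 1.0000000000

evaluateScores(colMeans(cellWeights(ens)),
               as.integer(cellTypes(study$atlas$cpm) == "mono"))$auroc
#> [1] 0.9939583
```

All 7 BY-selected cells are of the causal type (Fisher BH-adjusted
p = 1.6e-4), and ranking every cell by its mean ensemble weight separates
causal from non-causal cells with AUC 0.99.

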