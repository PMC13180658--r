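---
title: "Single-cell-resolved polygenic risk scoring: models and methods"
author: "scPRS package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell-resolved polygenic risk scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

A standard polygenic risk score (PRS) collapses a person's genetic liability
into one number and says nothing about where in the body that liability acts.
This package decomposes the PRS along a reference single-cell chromatin
accessibility atlas: for every cell of the atlas, a clumping-and-thresholding
(C+T) PRS is computed in which index variants are restricted to that cell's
open chromatin, producing a cells-by-parameters matrix of genetic risk
features per individual. A small graph neural model over the mutual
k-nearest-neighbour (M-kNN) cell graph then maps these features to the
phenotype, and the per-cell readout coefficients are interpreted to rank
cells and cell types by disease relevance.

The pipeline is: `readSumstats`/`readGenotypes`/`readCellPeakMatrix` and QC
-> `harmonizeAlleles` -> `ldR2` + `assignVariantsToPeaks` ->
`cellPRSTensor` -> `buildCellGraph` -> `normalizePRS` -> `scprsFit` (or
`fitEnsemble`) -> `prioritizeCells` / `celltypeEnrichment`, with
model-agnostic variant scoring (`zqScores`), enrichment statistics and a
differential accessibility test downstream. A simulation module generates
coupled genotypes, GWAS summary statistics, atlases and phenotypes so that
every stage is testable offline.

# Conditioned C+T PRS

For a fixed index set the score of individual $n$ is

$$\mathrm{PRS}_n = \frac{\sum_i \beta_i G_{ni}}{P\,M_n},$$

with $\beta_i$ the per-effect-allele GWAS effect size, $G_{ni}$ the
effect-allele dosage, ploidy $P = 2$ and $M_n$ the individual's count of
nonmissing variants among the scored set ($M_n = 0$ gives a score of exactly
0). Index selection is greedy clumping: candidates are processed in
ascending p-value (ties broken by chromosome and position for determinism);
each selected index removes every variant — candidate or not — within 250 kb
whose LD $r^2$ with it reaches the threshold. Per cell, the candidates are
the variants inside peaks with nonzero accessibility in that cell
(index-first conditioning); a peak "captured in" a cell means count > 0, as
no count threshold is part of the method.

The feature grid crosses $r^2 \in \{0.1, 0.3, 0.5\}$ with
$p \in \{10^{-5}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1, 0.5\}$ — 21 features
per cell. Because candidates are processed in ascending p-value, the index
set at a smaller p threshold is exactly the p-filtered index set of a clump
run at the largest threshold; `cellPRSTensor` therefore clumps once per
$r^2$ level and thresholds, and memoizes over distinct candidate variant
sets (cells sharing a candidate set share features bit-for-bit; an explicit
cache-free mode exists and is tested for equality). LD is the squared
Pearson correlation of dosages over pairwise-complete observations,
estimated in-sample by default or from any reference panel read through the
same genotype reader.

$M_n$ counts nonmissing variants among the selected index set only; the
per-feature normalization is a z-score with statistics from the training
samples (stored and reapplied to unseen samples); both choices are stated
here because the method description leaves the universe of $M$ and the
normalization scheme open, and these are the conventional readings.

# Cell graph

Embeddings are latent semantic indexing: per-cell term frequency scaled by
$\log(1 + M/(1 + \mathrm{df}))$ inverse document frequency, then a truncated
SVD with the first (depth-correlated) component dropped by default.
Externally batch-corrected embeddings can be supplied instead. The directed
kNN graph under Euclidean distance (self excluded, ties broken by cell
index) is symmetrized as $G = \hat G \circ \hat G^{\top}$, keeping only
mutual neighbours. The penalty matrix is the symmetric normalized Laplacian
$G_L = I - D^{-1/2} A D^{-1/2}$; the method's printed form
$D^{1/2}(D-A)D^{-1/2}$ is asymmetric as written and is read as a typo for
the standard symmetric operator its name denotes. Isolated cells get a zero
row and column, so they contribute nothing to the penalty, and they are kept
in the graph (their latent features only flow through the self term).

# Model, loss and optimization

With $X_n \in \mathbb{R}^{M\times 21}$ the normalized features of individual
$n$:

- embedding: $h^{(0)} = X_n \cdot \mathrm{abs}(W_0)$, one scalar per cell;
- propagation ($t = 0,\dots,T-1$):
  $g_v^{(t+1)} = \frac{1}{\deg(v)} \sum_{u\in N(v)}
  (\mathrm{abs}(w_1^{(t)}) h_u^{(t)} + \mathrm{abs}(w_2^{(t)}) h_v^{(t)})$,
  followed by a leaky ReLU with slope $\alpha = 0.1$; for $\deg(v) = 0$ the
  neighbour sum is empty and the self term is used with normalization
  constant 1;
- readout: $y = \sigma(\beta \cdot h^{(T)} + b)$, logistic for
  classification, identity for regression. Optional extra blocks (nonpeak
  PRS features, covariates) concatenate at the readout with their own
  coefficients.

All embedding and propagation weights pass through $\mathrm{abs}(\cdot)$, so
the map from $X$ to $h^{(T)}$ is monotonically increasing — larger risk
features can never lower a latent cell feature, which is what makes a large
$\beta_m$ interpretable as cell relevance. The weights are stored
unconstrained and reparameterized by `abs()` at forward time, exactly as the
equations state, rather than projected.

The loss is mean binary cross-entropy (or mean squared error for
regression) plus $\lambda_1\lVert\beta\rVert_1 +
\lambda_2\lVert\beta\rVert_2^2 + \lambda_3 \beta^{\top} G_L \beta$. The
$\lambda_2$ term is the squared (ridge) norm by default — the conventional
reading of $\lVert\beta\rVert_2$ — with the unsquared norm behind a flag.
Optimization is mini-batch Adam (learning rate $10^{-3}$, batch size 32, 200
epochs, no early stopping or schedule; epochs configurable), with analytic
gradients — the model is small enough (a 21-vector, two scalars per layer,
an $M$-vector and a bias) that the backward pass is a few matrix products,
so no deep-learning framework is involved. Batches are reshuffled each epoch
from the run seed; the last partial batch is kept; the subgradient of
$|\cdot|$ and $\mathrm{abs}(\cdot)$ at 0 is taken as 0. Initialization draws
$W_0 \sim U(0.05, 0.15)$ and $w_1, w_2 \sim U(0.4, 0.6)$ (positive, so the
abs reparameterization starts away from the kink) and sets $\beta = 0$,
which keeps the readout unbiased at the start; seed-to-seed variability for
the ensemble comes from initialization and batch order. Two fits with the
same data, configuration and seed are bit-identical; a non-finite loss
aborts with diagnostics.

Splits are random 60/20/20 (train/validation/test), stratified by class for
binary tasks (the method description does not say whether its splits were
stratified; stratification is the default here and a flag exposes the
alternative). Model selection is by validation AUROC (Pearson r for
regression) at the final epoch, over the hyperparameter grids $T \in
\{0,1,2\}$, $\lambda_1 \in \{0,1,10\}$, $\lambda_2 \in
\{1,10,50,100,250,500,750\}$, $\lambda_3 \in
\{0.01,0.1,0.5,1,2.5,5,10,50,100\}$, $k \in \{25,50\}$;
`crossValidate` implements the five-fold, five-repeat protocol used before
ensemble training and refits the winner on all samples.

# Prioritization

`fitEnsemble` trains models that differ only in seed (100 in the reference
protocol) on the whole cohort and stacks their readout vectors. For each
cell, a one-sided Welch t-test compares its weights across models with the
pooled top-15% weights per model ("top-ranking" background); the cell's own
weights are not excluded from the background (leave-self-out is a flag), and
the Welch form is used because only "one-sided t-test" is specified.
Benjamini–Yekutieli adjustment over cells (valid under the strong dependence
between cells of one ensemble) at $\alpha = 0.1$ defines the selected cells;
a one-sided Fisher's exact test per cell type with Benjamini–Hochberg
adjustment at $\alpha = 0.1$ defines enriched types, excluding types below
150 cells (a size filter that scales with the atlas — the scaled simulation
protocol below uses 30). `subpopulationSplit` splits a type by marker-peak
accessibility and tests the selected-cell distribution across subtypes with
a two-sided chi-square test without continuity correction, so the statistic
matches the closed form.

# Downstream variant scores

`zqScores` standardizes externally supplied per-variant accessibility deltas
($y_{\mathrm{alt}} - y_{\mathrm{ref}}$ from any sequence model — producing
them is out of scope) into $Z = (\delta - \mu)/\sigma$ over a global pool by
default and $Q$ = quantile rank of $|Z|$. A fully constant pool yields
$Z = 0$ with a warning rather than an error, which keeps the degenerate case
well-defined. $Q$ is exactly invariant to positive affine transforms of the
deltas; a nonlinear monotone transform moves the pool mean and can reorder
$|Z|$, so rank-invariance beyond the affine family is not claimed.
`gwasPeakEnrichment` clumps genome-wide at $r^2 = 0.1$, then tests
significant-by-membership 2x2 tables with a two-sided Fisher's exact test;
degenerate tables report a Haldane–Anscombe (+0.5) corrected odds-ratio
point estimate, flagged, with the p-value from the uncorrected exact test.
`daTest` mirrors an LR-test differential accessibility call: logistic models
of group membership on binarized accessibility with the per-cell total
fragment count as covariate, pre-filters `min.pct = 0.02` and
`|log2FC| >= 0.1` (detection-fraction fold change with pseudocount $10^{-9}$,
since the reference tool's pseudocount is version-dependent), BH adjustment,
and a positive log2FC requirement for the DA call.

# Simulation framework

The generator emulates the structure the method assumes, not any particular
organism's genome:

- **Genotypes** (`simGenotypes`): per chromosome, an ancestral pool of
  haplotypes (default 20) with variant frequencies drawn from
  $U(0.05, 0.5)$; individual haplotypes are recombinant mosaics of pool
  members (Poisson breakpoints, mean 1 per chromosome). The pool size is the
  single LD knob: 2 gives near-perfect within-block LD, `Inf` gives
  independent fresh draws. Hardy–Weinberg equilibrium holds by construction.
- **Atlas** (`simCellAtlas`): non-overlapping peaks (default 1 kb) tile the
  chromosomes; each of 4 cell types has 60 specific peaks (accessible with
  probability 0.8 in-type, 0.05 out-of-type) plus 100 shared peaks (0.7),
  independent dropout 0.2, small positive integer counts.
- **GWAS** (`simGWAS`): causal effects $\beta^* \sim N(0, 0.15^2)$ on
  variants inside the causal-type-specific peaks; discovery phenotype
  $G\beta^* + N(0,1)$; reported effects and p-values from per-variant
  marginal regressions, so LD-induced proxy associations exist as in real
  GWAS.
- **Phenotype** (`simPhenotype`): the standardized C+T PRS of the target
  cohort restricted to the causal peaks (defaults $r^2 = 0.1$, $p = 0.5$,
  recorded in the truth file, as the generating C+T parameters are not
  otherwise pinned down), plus $N(0, \sigma^2)$ noise; the noisy phenotype
  is deliberately not re-standardized. A `peakNoiseFrac` fraction of causal
  peaks can be swapped for decoy peaks specific to other types, and a median
  split yields binary labels so the classification pathway is testable
  (the underlying simulation design is regression-only).

Default sizes are 600 target individuals, 4,000 discovery individuals, 5,000
variants over five 1.25-Mb chromosomes and 1,500 cells. What the generator
does **not** emulate: realistic human LD maps, population structure,
covariate confounding, batch effects, sex chromosomes, and peak-calling
artifacts — so passing tests demonstrate correctness of the machinery and
recoverability under the stated statistical structure, not performance on
real cohorts.

# Study protocol and problem sizes used in the checks

The end-to-end checks (tests and `scripts/acceptance.R`) run a scaled
version of the default study, chosen once as this package's desk-scale
protocol: 1,500 discovery individuals, 2,000 variants over four 1-Mb
chromosomes, 160 cells (4 types x 40), 40 specific + 60 shared peaks per the
atlas defaults above; 150 target individuals for ensemble/prioritization
runs and 300 for prediction runs; graph k = 15 (the reference k = 25 over a
~10,000-cell atlas, scaled to 160 cells); Fisher-test size filter 30. Model
configurations are fixed up front: prioritization uses $T=1, \lambda_1=1,
\lambda_2=1, \lambda_3=1$, 150 epochs (the lasso term drives the readout of
uninformative cells to exactly zero, which is what makes permuted-label
nulls clean), prediction uses $T=1, \lambda_1=0, \lambda_2=1, \lambda_3=1$,
200 epochs. The negative control removes the causal type plus any cell with
more than 1 accessible causal-specific peak — the reference protocol's
cutoff (40 of 1,500 causal peaks, ~2.7%) scaled to the 40-peak causal set.

# Numerical choices and degenerate inputs

- Coordinates: BED peaks are 0-based half-open, variants 1-based; a variant
  at position $q$ lies in $[\mathrm{start}, \mathrm{end})$ iff
  $\mathrm{start} \le q-1 < \mathrm{end}$. Chromosome names are normalized
  (leading "chr" stripped) on read.
- HWE: Pearson chi-square with 1 df by default, computed on the whole cohort
  (cases and controls jointly; the reference leaves this open); the exact
  mid-p test is behind a flag. Multiallelic VCF records are dropped by
  default or split on request.
- Monomorphic variants have undefined LD, treated as $r^2 = 0$ with a
  warning; sparse LD storage keeps pairs with $r^2 \ge$ 0.01 by default
  (clumping thresholds start at 0.1).
- Zero-variance features normalize to 0; an all-zero candidate set gives a
  zero feature vector and zero index counts; a fully degenerate weight
  ensemble yields p = 1 for every cell with a warning.
- BCE probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the loss.
- The kb window is measured index-to-variant (PLINK-style), not pairwise.

# Known limitations

- The bilinear structure (one shared 21-vector embedding across cells)
  bounds attainable prediction below an unconstrained linear model on the
  same features; on the noiseless scaled study the held-out r plateaus
  around 0.93 while an unconstrained ridge on the flattened features reaches
  ~0.99. This is a property of the method, retained by design.
- Per-cell clumping is exact via memoization over distinct candidate sets;
  atlases where dropout makes nearly every cell's candidate set unique lose
  the memoization benefit and scale linearly in cells.
- LSI uses a dense SVD, adequate for atlases up to a few thousand cells;
  larger atlases should supply an external embedding.
- The prioritization t-test treats ensemble members as independent samples;
  they share the data, so the BY correction (valid under arbitrary
  dependence) is relied on, and the permuted-label null is verified
  empirically rather than guaranteed analytically.
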