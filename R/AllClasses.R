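#' @import methods
#' @importFrom Matrix Matrix t colSums rowSums crossprod tcrossprod Diagonal sparseMatrix
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' SumstatsTable: GWAS summary statistics
#'
#' Per-variant GWAS effect sizes, p-values, alleles, minor-allele frequency
#' (MAF) and imputation INFO score, together with provenance metadata. The
#' effect size `beta` is the per-effect-allele additive effect; `effect_allele`
#' must be one of `ref`/`alt`.
#'
#' @slot variants data.frame with columns chrom, pos, ref, alt, effect_allele,
#'   beta, pval, maf, info (info may be NA throughout when the source has no
#'   imputation score, e.g. WGS-based GWAS).
#' @slot source character(1) free-text source label.
#' @slot build character(1) genome build tag (e.g. "GRCh38", or "synthetic").
#'
#' @export
setClass("SumstatsTable",
  representation(variants = "data.frame", source = "character",
                 build = "character"))

setValidity("SumstatsTable", function(object) {
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "effect_allele", "beta", "pval",
            "maf", "info")
  if (!all(need %in% names(v)))
    return(paste("missing columns:", paste(setdiff(need, names(v)), collapse = ", ")))
  if (nrow(v)) {
    if (any(v$pval <= 0 | v$pval > 1)) return("pval must lie in (0, 1]")
    if (any(v$pos < 1)) return("pos must be >= 1 (1-based)")
    if (any(v$maf < 0 | v$maf > 0.5, na.rm = TRUE))
      return("maf must lie in [0, 0.5]")
    if (any(v$effect_allele != v$ref & v$effect_allele != v$alt))
      return("effect_allele must equal ref or alt")
  }
  TRUE
})

#' GenotypeMatrix: individual-level diploid dosages
#'
#' Samples-by-variants matrix of effect-allele dosages in \{0, 1, 2\} with
#' `NA` for missing genotypes, plus the variant key table (chrom, pos, ref,
#' alt). Dosages count copies of `alt` until [harmonizeAlleles()] recodes them
#' to count the summary-statistics effect allele.
#'
#' @slot dosages numeric matrix, rownames = sample ids, entries in [0,2] or NA.
#' @slot variants data.frame with columns chrom, pos, ref, alt.
#'
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  if (ncol(d) != nrow(object@variants))
    return("ncol(dosages) must equal nrow(variants)")
  if (is.null(rownames(d))) return("dosages must carry sample ids as rownames")
  if (anyDuplicated(rownames(d))) return("sample ids must be unique")
  rng <- range(d, na.rm = TRUE)
  if (nrow(object@variants) && nrow(d) && (rng[1] < 0 || rng[2] > 2))
    return("dosages must lie in [0, 2] when present")
  TRUE
})

#' CellPeakMatrix: single-cell chromatin accessibility
#'
#' Sparse cells-by-peaks count matrix (nonnegative), the peak intervals as a
#' [GenomicRanges::GRanges] (0-based half-open on disk, 1-based closed once in
#' GRanges, as usual for BED input), and optional per-cell type labels.
#'
#' @slot counts dgCMatrix, cells x peaks; rownames = barcodes.
#' @slot peaks GRanges of length ncol(counts); names = peak ids.
#' @slot cellType character vector of length nrow(counts), or character(0).
#'
#' @export
setClass("CellPeakMatrix",
  representation(counts = "Matrix", peaks = "GRanges", cellType = "character"))

setValidity("CellPeakMatrix", function(object) {
  if (length(object@peaks) != ncol(object@counts))
    return("length(peaks) must equal ncol(counts)")
  if (length(object@cellType) && length(object@cellType) != nrow(object@counts))
    return("cellType must be empty or one label per cell")
  if (is.null(rownames(object@counts))) return("counts must have barcode rownames")
  if (min(object@counts) < 0) return("accessibility counts must be nonnegative")
  TRUE
})

#' LDMatrix: sparse pairwise linkage disequilibrium
#'
#' Squared Pearson correlations (r2) of dosages for same-chromosome variant
#' pairs within a physical window, stored sparsely. The diagonal is 1 for all
#' variants present.
#'
#' @slot r2 symmetric sparse Matrix of r2 values in [0,1].
#' @slot variants data.frame (chrom, pos, ref, alt) aligned to r2 rows.
#' @slot windowKb numeric(1) window used, in kb.
#' @slot source character(1), "in_sample" or "reference_panel".
#'
#' @export
setClass("LDMatrix",
  representation(r2 = "Matrix", variants = "data.frame", windowKb = "numeric",
                 source = "character"))

setValidity("LDMatrix", function(object) {
  if (nrow(object@r2) != ncol(object@r2)) return("r2 must be square")
  if (nrow(object@r2) != nrow(object@variants))
    return("r2 dimension must match variant table")
  TRUE
})

#' CellGraph: mutual-kNN cell-cell similarity graph
#'
#' Binary symmetric adjacency (no self loops), node degrees, the k used, and
#' the symmetric normalized Laplacian used as a smoothness penalty on the
#' per-cell readout weights.
#'
#' @slot adjacency binary symmetric sparse Matrix, zero diagonal.
#' @slot laplacian symmetric sparse Matrix (PSD); isolated cells contribute a
#'   zero row/column.
#' @slot degrees numeric vector of node degrees.
#' @slot k integer(1) neighbour count used to build the kNN graph.
#'
#' @export
setClass("CellGraph",
  representation(adjacency = "Matrix", laplacian = "Matrix",
                 degrees = "numeric", k = "integer"))

setValidity("CellGraph", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (length(object@degrees) != nrow(A)) return("degrees length mismatch")
  if (any(Matrix::diag(A) != 0)) return("adjacency must have zero diagonal")
  if (max(abs(A - Matrix::t(A))) > 0) return("adjacency must be symmetric")
  TRUE
})

#' CellPRSTensor: per-cell conditioned PRS features
#'
#' Individuals x cells x grid array of clumping+thresholding PRSs where, for
#' each cell, index variants are restricted to that cell's accessible peaks.
#' Carries the per-(cell, parameter) count of index variants and, after
#' [normalizePRS()], the training-sample normalization statistics.
#'
#' @slot scores numeric array N x M x F (individuals, cells, grid points).
#' @slot nIndex integer matrix M x F: index variants used per cell and grid point.
#' @slot grid data.frame with columns r2 and p (the C+T parameter grid).
#' @slot normStats list with elements mean, sd (M x F matrices) and fitSamples,
#'   or empty list before normalization.
#' @slot normalized logical(1).
#'
#' @export
setClass("CellPRSTensor",
  representation(scores = "array", nIndex = "matrix", grid = "data.frame",
                 normStats = "list", normalized = "logical"))

setValidity("CellPRSTensor", function(object) {
  d <- dim(object@scores)
  if (length(d) != 3) return("scores must be a 3-d array")
  if (!all(dim(object@nIndex) == d[2:3]))
    return("nIndex must be cells x grid")
  if (nrow(object@grid) != d[3]) return("grid must have one row per feature")
  if (any(!is.finite(object@scores))) return("scores must be finite")
  TRUE
})

#' ScprsFit: a trained scPRS model
#'
#' Learned parameters (stored unconstrained; the forward pass applies `abs()`
#' to the embedding and propagation weights), the training configuration,
#' per-epoch loss trace, validation metric and the data split used.
#'
#' @slot params list: W0 (length-21), w1, w2 (length-T), beta (length-M),
#'   b (scalar), gamma (extra-feature readout coefficients, possibly empty).
#' @slot config list of hyperparameters (T, lambda1..3, lr, batchSize, epochs,
#'   task, seed, ...).
#' @slot lossTrace numeric per-epoch training loss.
#' @slot valMetric numeric(1) validation AUROC (binary) or Pearson r
#'   (regression); NA when no validation set was supplied.
#' @slot splits list of train/val/test index vectors.
#'
#' @export
setClass("ScprsFit",
  representation(params = "list", config = "list", lossTrace = "numeric",
                 valMetric = "numeric", splits = "list"))

#' CellWeightEnsemble: readout weights across random seeds
#'
#' One row of learned per-cell readout coefficients beta per trained model;
#' used to test which cells carry consistently large weights.
#'
#' @slot weights numeric matrix, models x cells.
#' @slot seeds integer vector of seeds used (one per retained model).
#' @slot config list: the shared training configuration.
#'
#' @export
setClass("CellWeightEnsemble",
  representation(weights = "matrix", seeds = "integer", config = "list"))

setValidity("CellWeightEnsemble", function(object) {
  if (nrow(object@weights) != length(object@seeds))
    return("one seed per ensemble row required")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  TRUE
})
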