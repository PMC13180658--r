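#' Default clumping+thresholding parameter grid
#'
#' Cartesian product of LD thresholds r2 in \{0.1, 0.3, 0.5\} and p-value
#' thresholds \{1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5\}: 21 (r2, p) pairs,
#' the grid of conditioned PRSs computed per cell.
#'
#' @param r2 LD r2 thresholds.
#' @param p p-value thresholds.
#' @param windowKb clumping window in kb (index-to-variant distance).
#' @return data.frame with columns r2, p, windowKb; one row per grid point.
#' @export
defaultCTGrid <- function(r2 = c(0.1, 0.3, 0.5),
                          p = c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5),
                          windowKb = 250) {
  g <- expand.grid(p = p, r2 = r2, KEEP.OUT.ATTRS = FALSE)[, c("r2", "p")]
  if (anyDuplicated(g)) stop("grid combinations must be unique")
  g$windowKb <- windowKb
  rownames(g) <- sprintf("r2=%g,p=%g", g$r2, g$p)
  g
}

#' Pairwise LD (r2) within a physical window
#'
#' Squared Pearson correlation of dosages for all same-chromosome variant
#' pairs within `windowKb`, using pairwise-complete observations. Values
#' below `r2Min` are not stored (the sparse matrix is used only to find
#' clumping neighbours at r2 >= 0.1 by default). Monomorphic variants yield
#' undefined correlations, treated as 0 with a warning.
#'
#' @param g a [GenotypeMatrix-class] (target cohort for in-sample LD, or a
#'   reference panel read through the same reader for out-sample LD).
#' @param windowKb window in kb.
#' @param r2Min smallest r2 retained in storage.
#' @param source tag recorded on the result ("in_sample" or
#'   "reference_panel").
#' @return an [LDMatrix-class] aligned to the variants of `g`.
#' @export
ldR2 <- function(g, windowKb = 250, r2Min = 0.01, source = "in_sample") {
  v <- g@variants
  n <- nrow(v)
  win <- windowKb * 1000
  iL <- list(); jL <- list(); xL <- list()
  monomorphic <- FALSE
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    m <- length(idx)
    if (m < 2) next
    # block the chromosome so dense correlation stays small; blocks overlap
    # by the window so no within-window pair is missed
    pos <- v$pos[idx]
    blockSize <- 1500L
    starts <- seq(1L, m, by = blockSize)
    for (s in starts) {
      e <- min(m, s + blockSize - 1L)
      # extend right so pairs spanning the block boundary are covered
      e2 <- e
      while (e2 < m && pos[e2 + 1] - pos[e] <= win) e2 <- e2 + 1L
      sel <- idx[s:e2]
      D <- g@dosages[, sel, drop = FALSE]
      cc <- suppressWarnings(cor(D, use = "pairwise.complete.obs"))
      if (anyNA(cc)) { monomorphic <- TRUE; cc[is.na(cc)] <- 0 }
      r2 <- cc^2
      p2 <- v$pos[sel]
      pr <- which(abs(outer(p2, p2, "-")) <= win & upper.tri(r2), arr.ind = TRUE)
      if (nrow(pr)) {
        keep <- r2[pr] >= r2Min & (pr[, 1] + s - 1L) <= e  # left end in block
        pr <- pr[keep, , drop = FALSE]
        iL[[length(iL) + 1]] <- sel[pr[, 1]]
        jL[[length(jL) + 1]] <- sel[pr[, 2]]
        xL[[length(xL) + 1]] <- r2[pr[, c(1, 2), drop = FALSE]]
      }
    }
  }
  if (monomorphic)
    warning("monomorphic variant(s): undefined r2 treated as 0")
  i <- c(unlist(iL), seq_len(n))
  j <- c(unlist(jL), seq_len(n))
  x <- c(unlist(xL), rep(1, n))
  r2m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                              symmetric = TRUE, use.last.ij = TRUE)
  new("LDMatrix", r2 = r2m, variants = v, windowKb = windowKb,
      source = source)
}

# column neighbours of a CsparseMatrix general form; returns idx/x
.ldColumns <- function(ld) {
  methods::as(ld@r2, "generalMatrix")
}

#' Greedy LD clumping with restricted index candidates
#'
#' Repeatedly takes the smallest-p remaining candidate with p <= `pThresh`
#' as an index variant and removes from further consideration every variant
#' (candidate or not) within `windowKb` whose r2 with the index is at least
#' `r2Thresh`. Equal p-values are broken by (chrom, pos) ascending so the
#' result is deterministic. Index candidates may be restricted (e.g. to
#' variants inside a cell's accessible peaks), mirroring index-first
#' clumping.
#'
#' @param ss a [SumstatsTable-class]; variant order must match `ld`.
#' @param ld an [LDMatrix-class].
#' @param candidates integer indices into `ss` eligible as index variants
#'   (default: all).
#' @param r2Thresh LD r2 threshold.
#' @param pThresh p-value threshold for index variants.
#' @param windowKb clumping window (kb), index-to-variant distance.
#' @return integer vector of index variant positions (rows of `ss`) in
#'   selection order. Empty candidate set yields an empty result.
#' @export
clumpVariants <- function(ss, ld, candidates = seq_len(nrow(variantTable(ss))),
                          r2Thresh = 0.1, pThresh = 1, windowKb = 250) {
  v <- ss@variants
  if (nrow(v) != nrow(ld@r2))
    stop("sumstats and LD matrix must cover the same variants")
  if (!length(candidates)) return(integer(0))
  ldg <- .ldColumns(ld)
  .clumpCore(v, ldg, candidates, r2Thresh, pThresh, windowKb)
}

# core greedy loop over a precomputed general CsparseMatrix of r2
.clumpCore <- function(v, ldg, candidates, r2Thresh, pThresh, windowKb) {
  win <- windowKb * 1000
  p <- v$pval[candidates]
  ord <- order(p, v$chrom[candidates], v$pos[candidates])
  cand <- candidates[ord]
  cand <- cand[v$pval[cand] <= pThresh]
  if (!length(cand)) return(integer(0))
  removed <- logical(nrow(v))
  pp <- ldg@p; ii <- ldg@i; xx <- ldg@x
  pos <- v$pos; chrom <- v$chrom
  out <- integer(0)
  for (cv in cand) {
    if (removed[cv]) next
    out <- c(out, cv)
    k <- (pp[cv] + 1L):pp[cv + 1L]
    if (length(k) == 0L || pp[cv] == pp[cv + 1L]) { removed[cv] <- TRUE; next }
    nb <- ii[k] + 1L
    hit <- xx[k] >= r2Thresh & abs(pos[nb] - pos[cv]) <= win &
      chrom[nb] == chrom[cv]
    removed[nb[hit]] <- TRUE
    removed[cv] <- TRUE
  }
  out
}

#' Clumping+thresholding PRS for a fixed index set
#'
#' PRS_n = sum_i beta_i * G_i / (P * M_n) with ploidy P = 2 and M_n the
#' individual's count of nonmissing variants among the index set; G_i counts
#' copies of the effect allele. Individuals with M_n = 0 score exactly 0.
#'
#' @param g harmonized [GenotypeMatrix-class] (dosages count the sumstats alt
#'   allele).
#' @param ss harmonized [SumstatsTable-class] aligned to `g`.
#' @param indexSet integer variant indices to score.
#' @return numeric vector of per-individual scores.
#' @export
ctPRS <- function(g, ss, indexSet) {
  n <- nrow(g@dosages)
  if (!length(indexSet))
    return(setNames(numeric(n), rownames(g@dosages)))
  v <- ss@variants
  D <- g@dosages[, indexSet, drop = FALSE]
  flip <- v$effect_allele[indexSet] == v$ref[indexSet]
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  b <- v$beta[indexSet]
  if (!anyNA(D)) {
    drop(D %*% b) / (2 * length(indexSet))
  } else {
    M <- rowSums(!is.na(D))
    num <- rowSums(sweep(D, 2, b, `*`), na.rm = TRUE)
    ifelse(M == 0, 0, num / (2 * M))
  }
}

# effect-allele dosage matrix, precomputed once for tensor scoring
.effectDosages <- function(g, ss) {
  v <- ss@variants
  D <- g@dosages
  flip <- v$effect_allele == v$ref
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  D
}

# score many nested index sets sharing one clump result:
# indices 'idx' (selection order) are filtered per p threshold
.scoreThresholds <- function(Deff, beta, pval, idx, pThresholds) {
  n <- nrow(Deff)
  out <- matrix(0, n, length(pThresholds))
  cnt <- integer(length(pThresholds))
  for (t in seq_along(pThresholds)) {
    set <- idx[pval[idx] <= pThresholds[t]]
    cnt[t] <- length(set)
    if (!length(set)) next
    D <- Deff[, set, drop = FALSE]
    if (!anyNA(D)) {
      out[, t] <- drop(D %*% beta[set]) / (2 * length(set))
    } else {
      M <- rowSums(!is.na(D))
      num <- rowSums(sweep(D, 2, beta[set], `*`), na.rm = TRUE)
      out[, t] <- ifelse(M == 0, 0, num / (2 * M))
    }
  }
  list(scores = out, n = cnt)
}

#' Per-cell conditioned PRS tensor
#'
#' For every cell, index candidates are restricted to variants inside peaks
#' with nonzero accessibility in that cell; clumping and scoring then run for
#' every (r2, p) grid point, giving the individuals x cells x grid feature
#' tensor. Because p-thresholding of a clump run at the largest p in the grid
#' yields exactly the clump result at any smaller p (candidates are processed
#' in ascending p order), one clump per r2 serves all seven p thresholds.
#' Cells with identical candidate variant sets share cached results; with
#' `cache = FALSE` every cell is recomputed independently (identical output,
#' used for verification).
#'
#' @param g,ss harmonized genotypes and sumstats (aligned).
#' @param cpm a [CellPeakMatrix-class].
#' @param ld an [LDMatrix-class] aligned to `ss`.
#' @param membership variants x peaks sparse matrix from
#'   [assignVariantsToPeaks()].
#' @param grid data.frame from [defaultCTGrid()].
#' @param cache memoize over distinct candidate sets.
#' @param verbose print progress.
#' @return a [CellPRSTensor-class].
#' @export
cellPRSTensor <- function(g, ss, cpm, ld, membership,
                          grid = defaultCTGrid(), cache = TRUE,
                          verbose = FALSE) {
  v <- ss@variants
  stopifnot(nrow(v) == nrow(membership))
  Deff <- .effectDosages(g, ss)
  ldg <- .ldColumns(ld)
  nCells <- nrow(cpm@counts)
  nInd <- nrow(Deff)
  nF <- nrow(grid)
  scores <- array(0, dim = c(nInd, nCells, nF),
                  dimnames = list(rownames(Deff), rownames(cpm@counts),
                                  rownames(grid)))
  nIndex <- matrix(0L, nCells, nF,
                   dimnames = list(rownames(cpm@counts), rownames(grid)))
  r2Levels <- unique(grid$r2)
  memo <- new.env(parent = emptyenv())
  # peaks accessible per cell: binarized counts
  acc <- methods::as(cpm@counts > 0, "CsparseMatrix") * 1
  # variant candidates per cell = any accessible peak contains the variant
  candMat <- methods::as((membership * 1) %*% Matrix::t(acc) > 0,
                         "CsparseMatrix")
  for (j in seq_len(nCells)) {
    cand <- which(candMat[, j])
    key <- if (cache) paste0("k", paste(cand, collapse = ",")) else NULL
    res <- if (cache && !is.null(memo[[key]])) memo[[key]] else {
      block <- matrix(0, nInd, nF)
      cnt <- integer(nF)
      if (length(cand)) {
        for (r2c in r2Levels) {
          rows <- which(grid$r2 == r2c)
          pmax_ <- max(grid$p[rows])
          idx <- .clumpCore(v, ldg, cand, r2c, pmax_, grid$windowKb[rows[1]])
          sc <- .scoreThresholds(Deff, v$beta, v$pval, idx, grid$p[rows])
          block[, rows] <- sc$scores
          cnt[rows] <- sc$n
        }
      }
      r <- list(block = block, cnt = cnt)
      if (cache) memo[[key]] <- r
      r
    }
    scores[, j, ] <- res$block
    nIndex[j, ] <- res$cnt
    if (verbose && j %% 200 == 0)
      message(sprintf("  cell %d / %d", j, nCells))
  }
  new("CellPRSTensor", scores = scores, nIndex = nIndex, grid = grid,
      normStats = list(), normalized = FALSE)
}

#' Nonpeak PRS features
#'
#' The 21-point C+T grid computed with index candidates restricted to
#' variants lying in no peak of the atlas; the complement of the conditioned
#' features, concatenated to the latent cell features in extended models.
#'
#' @inheritParams cellPRSTensor
#' @return list with `features` (individuals x grid matrix) and `nIndex`.
#' @export
nonpeakPRS <- function(g, ss, ld, membership, grid = defaultCTGrid()) {
  v <- ss@variants
  Deff <- .effectDosages(g, ss)
  ldg <- .ldColumns(ld)
  cand <- which(Matrix::rowSums(membership) == 0)
  out <- matrix(0, nrow(Deff), nrow(grid),
                dimnames = list(rownames(Deff), rownames(grid)))
  cnt <- integer(nrow(grid))
  for (r2c in unique(grid$r2)) {
    rows <- which(grid$r2 == r2c)
    idx <- .clumpCore(v, ldg, cand, r2c, max(grid$p[rows]),
                      grid$windowKb[rows[1]])
    sc <- .scoreThresholds(Deff, v$beta, v$pval, idx, grid$p[rows])
    out[, rows] <- sc$scores
    cnt[rows] <- sc$n
  }
  list(features = out, nIndex = setNames(cnt, rownames(grid)))
}

#' Single-cell-type PRS blocks
#'
#' For each cell type, index candidates are the variants inside any peak
#' accessible in at least one cell of that type; the full C+T grid is then
#' scored, giving one 21-feature block per type. A type whose peaks contain
#' no variants yields a zero block with a warning.
#'
#' @inheritParams cellPRSTensor
#' @param labels per-cell type labels (defaults to the labels in `cpm`).
#' @return named list of individuals x grid matrices, one per cell type.
#' @export
celltypePRS <- function(g, ss, cpm, ld, membership, grid = defaultCTGrid(),
                        labels = cellTypes(cpm)) {
  if (!length(labels)) stop("cell-type labels are required")
  v <- ss@variants
  Deff <- .effectDosages(g, ss)
  ldg <- .ldColumns(ld)
  acc <- cpm@counts > 0
  out <- list()
  for (ty in unique(labels)) {
    peaksTy <- which(Matrix::colSums(acc[labels == ty, , drop = FALSE]) > 0)
    cand <- which(Matrix::rowSums(membership[, peaksTy, drop = FALSE]) > 0)
    block <- matrix(0, nrow(Deff), nrow(grid),
                    dimnames = list(rownames(Deff), rownames(grid)))
    if (!length(cand)) {
      warning(sprintf("cell type '%s' has no peak variants; zero block", ty))
    } else {
      for (r2c in unique(grid$r2)) {
        rows <- which(grid$r2 == r2c)
        idx <- .clumpCore(v, ldg, cand, r2c, max(grid$p[rows]),
                          grid$windowKb[rows[1]])
        block[, rows] <- .scoreThresholds(Deff, v$beta, v$pval, idx,
                                          grid$p[rows])$scores
      }
    }
    out[[ty]] <- block
  }
  out
}

#' Combine single-cell-type PRS blocks by logistic regression
#'
#' Fits a logistic model of the binary outcome on all cell-type PRS features
#' using the training samples only and returns the linear predictor for every
#' individual (a multi-cell-type baseline PRS).
#'
#' @param blocks named list from [celltypePRS()].
#' @param labels binary outcome (0/1) for all individuals.
#' @param train integer indices of training samples.
#' @return numeric vector of combined scores for all individuals.
#' @export
combineMultiCelltype <- function(blocks, labels, train) {
  X <- do.call(cbind, blocks)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  keep <- apply(X[train, , drop = FALSE], 2, sd) > 0
  df <- as.data.frame(X[, keep, drop = FALSE])
  fit <- suppressWarnings(
    glm(labels[train] ~ ., data = df[train, , drop = FALSE],
        family = binomial()))
  unname(predict(fit, newdata = df))
}

#' Normalize PRS features
#'
#' Centers and scales every (cell, grid point) feature by mean and standard
#' deviation computed on `fitSamples` only; zero-variance features are set to
#' 0. The statistics are stored on the result so held-out or unseen samples
#' are transformed with training-set statistics (pass `stats` to reuse them).
#'
#' @param tensor a [CellPRSTensor-class].
#' @param fitSamples integer indices of samples used to fit the statistics
#'   (ignored when `stats` is given).
#' @param stats optional previously stored `normStats` list to apply as-is.
#' @return normalized [CellPRSTensor-class].
#' @export
normalizePRS <- function(tensor, fitSamples = seq_len(dim(tensor@scores)[1]),
                         stats = NULL) {
  x <- tensor@scores
  d <- dim(x)
  if (is.null(stats)) {
    if (!length(fitSamples)) stop("fitSamples must be nonempty")
    sub <- x[fitSamples, , , drop = FALSE]
    mu <- apply(sub, c(2, 3), mean)
    sg <- apply(sub, c(2, 3), sd)
    stats <- list(mean = mu, sd = sg, fitSamples = fitSamples)
  }
  mu <- stats$mean; sg <- stats$sd
  sgSafe <- ifelse(sg == 0 | is.na(sg), 1, sg)
  for (f in seq_len(d[3])) {
    x[, , f] <- sweep(sweep(x[, , f, drop = TRUE], 2, mu[, f], `-`),
                      2, sgSafe[, f], `/`)
    zero <- sg[, f] == 0 | is.na(sg[, f])
    if (any(zero)) x[, zero, f] <- 0
  }
  new("CellPRSTensor", scores = x, nIndex = tensor@nIndex, grid = tensor@grid,
      normStats = stats, normalized = TRUE)
}
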