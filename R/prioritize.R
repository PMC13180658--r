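#' Train an ensemble of models across random seeds
#'
#' Fits `nModels` models on the entire cohort that differ only in their seed
#' (initialization and batch order) and collects the learned per-cell
#' readout coefficients beta, one row per model. A diverging fit is recorded
#' and excluded with a warning; the ensemble must retain at least 80% of the
#' requested fits.
#'
#' @param X normalized feature array.
#' @param graph a [CellGraph-class].
#' @param labels outcome vector.
#' @param config shared configuration (typically selected by
#'   [crossValidate()]); its seed field is overridden per model.
#' @param nModels number of models (100 in the reference protocol).
#' @param baseSeed seeds are `baseSeed + 0:(nModels-1)`.
#' @param extra optional extra feature matrix.
#' @return a [CellWeightEnsemble-class].
#' @export
fitEnsemble <- function(X, graph, labels, config = scprsConfig(),
                        nModels = 100, baseSeed = 1, extra = NULL) {
  rows <- list(); seeds <- integer(0); failed <- 0
  for (i in seq_len(nModels)) {
    cfg <- config
    cfg$seed <- as.integer(baseSeed + i - 1)
    fit <- tryCatch(scprsFit(X, graph, labels, cfg, extra = extra),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failed <- failed + 1
      warning(sprintf("model with seed %d excluded: %s", cfg$seed,
                      conditionMessage(fit)))
      next
    }
    rows[[length(rows) + 1]] <- fit@params$beta
    seeds <- c(seeds, cfg$seed)
  }
  if (length(rows) < 0.8 * nModels)
    stop(sprintf("only %d of %d ensemble fits converged", length(rows),
                 nModels))
  new("CellWeightEnsemble", weights = do.call(rbind, rows), seeds = seeds,
      config = config)
}

#' Prioritize disease-relevant cells
#'
#' For each repeat, the top `ceil(topFrac * M)` cell weights form a
#' reference sample of "top-ranking" weights, pooled across repeats. Each
#' cell's weights across repeats are then compared to this pooled background
#' with a one-sided Welch t-test (alternative: cell mean greater), and the M
#' p-values are adjusted by the Benjamini-Yekutieli procedure (valid under
#' arbitrary dependence). Cells with adjusted p below `alpha` are selected
#' -- cells whose weights are consistently larger than those of the
#' majority of cells. A cell's own weights are not excluded from the
#' background by default (`excludeSelf = TRUE` removes them).
#'
#' @param ensemble a [CellWeightEnsemble-class] with at least 10 rows.
#' @param topFrac fraction of weights defining the top-ranking background.
#' @param alpha selection threshold on BY-adjusted p-values.
#' @param excludeSelf leave-self-out background.
#' @return data.frame with columns cell, meanWeight, p, pAdj, selected;
#'   invariant to cell reordering (results permute with the cells).
#' @export
prioritizeCells <- function(ensemble, topFrac = 0.15, alpha = 0.1,
                            excludeSelf = FALSE) {
  W <- ensemble@weights
  R <- nrow(W); M <- ncol(W)
  if (R < 10) stop("need at least 10 ensemble rows")
  nTop <- ceiling(topFrac * M)
  topIdx <- t(apply(W, 1, function(w)
    order(w, decreasing = TRUE)[seq_len(nTop)]))
  p <- numeric(M)
  warned <- FALSE
  for (m in seq_len(M)) {
    bg <- unlist(lapply(seq_len(R), function(r) {
      sel <- topIdx[r, ]
      if (excludeSelf) sel <- sel[sel != m]
      W[r, sel]
    }))
    x <- W[, m]
    if (sd(x) == 0 && sd(bg) == 0) {
      p[m] <- 1; warned <- TRUE
    } else {
      p[m] <- tryCatch(
        t.test(x, bg, alternative = "greater", var.equal = FALSE)$p.value,
        error = function(e) { warned <<- TRUE; 1 })
    }
  }
  if (warned) warning("zero-variance weight vectors: p set to 1")
  pAdj <- p.adjust(p, method = "BY")
  data.frame(cell = if (!is.null(colnames(W))) colnames(W) else
               paste0("cell_", seq_len(M)),
             meanWeight = colMeans(W), p = p, pAdj = pAdj,
             selected = pAdj < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Cell-type enrichment of prioritized cells
#'
#' One-sided Fisher's exact test of the 2x2 table
#' (selected/unselected x in-type/out-of-type) per cell type, with
#' Benjamini-Hochberg adjustment across tested types. Types with fewer than
#' `minCells` cells are excluded from testing.
#'
#' @param selected logical per-cell selection flags (from
#'   [prioritizeCells()]).
#' @param labels per-cell type labels.
#' @param minCells minimum cells per tested type.
#' @param alpha enrichment threshold on BH-adjusted p-values.
#' @return data.frame with per-type counts, odds ratio, p, pAdj, enriched.
#' @export
celltypeEnrichment <- function(selected, labels, minCells = 150,
                               alpha = 0.1) {
  stopifnot(length(selected) == length(labels))
  sizes <- table(labels)
  types <- names(sizes)[sizes >= minCells]
  if (!length(types))
    stop(sprintf("no cell type reaches the minimum size of %d", minCells))
  res <- lapply(types, function(ty) {
    inTy <- labels == ty
    a <- sum(selected & inTy); b <- sum(!selected & inTy)
    c_ <- sum(selected & !inTy); d <- sum(!selected & !inTy)
    ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                      alternative = "greater")
    data.frame(cellType = ty, nCells = a + b, nSelectedInType = a,
               nSelectedOutType = c_, oddsRatio = unname(ft$estimate),
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pAdj <- p.adjust(out$p, method = "BH")
  out$enriched <- out$pAdj < alpha
  out[order(out$p), ]
}

#' Marker-based subtype split and selection enrichment
#'
#' Within one cell type, splits cells into a marker-positive subtype (any
#' marker peak accessible, count > 0) and a marker-negative subtype, then
#' tests whether prioritized cells are unevenly distributed across the two
#' subtypes with a two-sided chi-square test (no continuity correction).
#' Reports observed and expected selected-cell counts per subtype. An empty
#' subtype skips the test with a warning.
#'
#' @param cpm a [CellPeakMatrix-class].
#' @param selected logical per-cell selection flags.
#' @param markerPeaks peak ids or column indices of the marker peaks.
#' @param cells optional logical/integer subset restricting to one cell type.
#' @return list with `subtype` (character per analysed cell), `table`
#'   (observed counts), `expected`, `chisq`, `p`.
#' @export
subpopulationSplit <- function(cpm, selected, markerPeaks, cells = NULL) {
  cnt <- cpm@counts
  if (is.character(markerPeaks))
    markerPeaks <- match(markerPeaks, colnames(cnt))
  if (anyNA(markerPeaks)) stop("unknown marker peak id(s)")
  if (!is.null(cells)) {
    cnt <- cnt[cells, , drop = FALSE]
    selected <- selected[cells]
  }
  pos <- Matrix::rowSums(cnt[, markerPeaks, drop = FALSE] > 0) > 0
  subtype <- ifelse(pos, "marker_pos", "marker_neg")
  if (!any(pos) || all(pos)) {
    warning("a subtype is empty; chi-square test skipped")
    return(list(subtype = subtype, table = table(subtype, selected),
                expected = NULL, chisq = NA_real_, p = NA_real_))
  }
  tab <- table(factor(subtype, c("marker_pos", "marker_neg")),
               factor(selected, c(FALSE, TRUE)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(subtype = subtype, table = tab, expected = ct$expected,
       chisq = unname(ct$statistic), p = ct$p.value)
}
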