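#' Variant effect Z and Q scores
#'
#' Standardizes predicted accessibility changes y(alt) - y(ref) per variant
#' and cell type: Z = (delta - mu) / sigma with mu, sigma over the
#' normalization pool (all entries by default, matching a single global pool
#' of variant scores; per-cell-type pooling behind the flag), and Q the
#' empirical quantile rank of |Z| within the same pool. The deltas come from
#' any accessibility predictor; this scoring is model-agnostic.
#'
#' @param deltas variants x cell-types numeric matrix of predicted effects.
#' @param pool "global" or "per_celltype".
#' @return list with matrices `delta`, `z`, `q` and the `pool` used.
#' @export
zqScores <- function(deltas, pool = c("global", "per_celltype")) {
  pool <- match.arg(pool)
  deltas <- as.matrix(deltas)
  if (nrow(deltas) < 2) stop("need at least 2 variants")
  zq <- function(x) {
    s <- sd(x)
    if (s == 0) {
      warning("zero standard deviation in normalization pool; Z set to 0")
      s <- 1
    }
    z <- (x - mean(x)) / s
    q <- rank(abs(z), ties.method = "average") / length(z)
    list(z = z, q = q)
  }
  if (pool == "global") {
    r <- zq(as.vector(deltas))
    z <- matrix(r$z, nrow(deltas), dimnames = dimnames(deltas))
    q <- matrix(r$q, nrow(deltas), dimnames = dimnames(deltas))
  } else {
    z <- deltas; q <- deltas
    for (j in seq_len(ncol(deltas))) {
      r <- zq(deltas[, j])
      z[, j] <- r$z; q[, j] <- r$q
    }
  }
  list(delta = deltas, z = z, q = q, pool = pool)
}

# 2x2 Fisher summary with Haldane-Anscombe point estimate for degenerate
# tables (p-value always from the uncorrected exact test)
.fisher2x2 <- function(a, b, c_, d, alternative = "two.sided") {
  ft <- fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                    alternative = alternative)
  degenerate <- any(c(a, b, c_, d) == 0)
  orPoint <- if (degenerate)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  ci <- if (!is.null(ft$conf.int)) as.numeric(ft$conf.int) else
    c(NA_real_, NA_real_)
  list(counts = c(a = a, b = b, c = c_, d = d), oddsRatio = orPoint,
       orCondMLE = unname(ft$estimate), ci = ci, p = ft$p.value,
       alternative = alternative, degenerate = degenerate)
}

#' Enrichment of genome-wide-significant variants in peaks
#'
#' Clumps all variants globally (every variant an index candidate) at
#' `clumpR2` to obtain an independent variant set, then tests the 2x2 table
#' of (GWAS p < `gwasSig`) x (inside/outside the supplied peaks) with a
#' two-sided Fisher's exact test. The peaks are typically the differentially
#' accessible peaks of prioritized cells; the comparison is against the
#' genome-wide variant distribution.
#'
#' @param ss harmonized [SumstatsTable-class].
#' @param ld [LDMatrix-class] aligned to `ss`.
#' @param membership variants x peaks sparse matrix
#'   ([assignVariantsToPeaks()] against the peak set of interest).
#' @param gwasSig genome-wide significance threshold.
#' @param clumpR2 LD r2 used for global clumping.
#' @param windowKb clumping window.
#' @return list: counts, oddsRatio (Haldane-corrected when a cell is zero,
#'   flagged `degenerate`), confidence interval, p, thresholds used.
#' @export
gwasPeakEnrichment <- function(ss, ld, membership, gwasSig = 5e-8,
                               clumpR2 = 0.1, windowKb = 250) {
  idx <- clumpVariants(ss, ld, r2Thresh = clumpR2, pThresh = 1,
                       windowKb = windowKb)
  v <- ss@variants
  sig <- v$pval[idx] < gwasSig
  if (!any(sig)) stop("no genome-wide-significant variants after clumping")
  inPeak <- Matrix::rowSums(membership[idx, , drop = FALSE]) > 0
  res <- .fisher2x2(sum(sig & inPeak), sum(!sig & inPeak),
                    sum(sig & !inPeak), sum(!sig & !inPeak))
  c(res, list(gwasSig = gwasSig, clumpR2 = clumpR2, nIndex = length(idx)))
}

#' Odds-ratio curve of functional variants within regions
#'
#' Among disease-associated variants (GWAS p < `pMax`), compares the
#' abundance of functional variants (Q score at or above each cutoff) inside
#' a region set against the background with a two-sided Fisher's exact test,
#' one test per cutoff. Cutoffs producing an empty stratum are skipped with
#' a warning. Because Q depends only on ranks, the curve is invariant to
#' monotone transforms of the underlying delta scores.
#'
#' @param q per-variant Q scores (one cell type).
#' @param inRegion logical per variant: inside the region set.
#' @param gwasP per-variant GWAS p-values.
#' @param pMax GWAS p cutoff defining disease-associated variants.
#' @param qCutoffs Q-score cutoffs defining functional variants.
#' @return data.frame with one row per tested cutoff: counts, oddsRatio,
#'   ciLow, ciHigh, p.
#' @export
functionalEnrichment <- function(q, inRegion, gwasP, pMax = 0.05,
                                 qCutoffs = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  keep <- gwasP < pMax
  q <- q[keep]; inRegion <- inRegion[keep]
  rows <- list()
  for (qc in qCutoffs) {
    fun <- q >= qc
    if (!any(fun) || all(fun) || !any(inRegion) || all(inRegion)) {
      warning(sprintf("cutoff %g skipped: empty stratum", qc))
      next
    }
    r <- .fisher2x2(sum(fun & inRegion), sum(!fun & inRegion),
                    sum(fun & !inRegion), sum(!fun & !inRegion))
    rows[[length(rows) + 1]] <-
      data.frame(qCutoff = qc, nFunctionalIn = r$counts["a"],
                 nOtherIn = r$counts["b"], nFunctionalOut = r$counts["c"],
                 nOtherOut = r$counts["d"], oddsRatio = r$oddsRatio,
                 ciLow = r$ci[1], ciHigh = r$ci[2], p = r$p,
                 row.names = NULL)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Differential accessibility of selected cells
#'
#' Compares binarized peak accessibility between a selected cell group and
#' all other cells with a likelihood-ratio test on logistic models of group
#' membership (group ~ peak + fragments vs group ~ fragments), adjusting
#' for per-cell total fragment counts. Peaks pass to testing only when
#' detected in at least `minPct` of either group and when
#' |log2 fold change| of the detection fractions (pseudocount 1e-9) reaches
#' `logfcMin`. BH adjustment over tested peaks; differentially accessible =
#' adjusted p < `alpha` with positive log2 fold change.
#'
#' @param cpm a [CellPeakMatrix-class].
#' @param selected logical per-cell group flags.
#' @param depth per-cell total fragment counts; defaults to row sums of the
#'   count matrix.
#' @param minPct minimum detection fraction in either group.
#' @param logfcMin minimum |log2FC| to test.
#' @param alpha significance threshold on BH-adjusted p.
#' @return data.frame per peak: pct1, pct2, log2FC, tested, p, pAdj, da.
#' @export
daTest <- function(cpm, selected, depth = NULL, minPct = 0.02,
                   logfcMin = 0.1, alpha = 0.1) {
  if (!any(selected) || all(selected))
    stop("both cell groups must be nonempty")
  bin <- as.matrix(cpm@counts > 0) * 1
  if (is.null(depth)) depth <- Matrix::rowSums(cpm@counts)
  depth <- as.numeric(scale(depth))
  if (anyNA(depth)) depth <- rep(0, length(selected))
  y <- as.numeric(selected)
  pct1 <- colMeans(bin[selected, , drop = FALSE])
  pct2 <- colMeans(bin[!selected, , drop = FALSE])
  log2FC <- log2((pct1 + 1e-9) / (pct2 + 1e-9))
  tested <- pmax(pct1, pct2) >= minPct & abs(log2FC) >= logfcMin
  p <- rep(NA_real_, ncol(bin))
  null <- glm(y ~ depth, family = binomial())
  for (j in which(tested)) {
    full <- suppressWarnings(glm(y ~ bin[, j] + depth, family = binomial()))
    p[j] <- pchisq(null$deviance - full$deviance, df = 1, lower.tail = FALSE)
  }
  pAdj <- rep(NA_real_, length(p))
  pAdj[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(peak = if (!is.null(colnames(bin))) colnames(bin) else
               paste0("peak_", seq_along(p)),
             pct1 = pct1, pct2 = pct2, log2FC = log2FC, tested = tested,
             p = p, pAdj = pAdj,
             da = !is.na(pAdj) & pAdj < alpha & log2FC > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
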