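# independent oracle implementations used to verify the package's
# primitives; deliberately naive (enumeration / brute force), never calling
# the code paths they check

# greedy clumping by exhaustive scan over a dense r2 matrix
oracleClump <- function(pval, chrom, pos, r2dense, candidates, r2Thresh,
                        pThresh, windowKb) {
  removed <- rep(FALSE, length(pval))
  out <- integer(0)
  repeat {
    elig <- candidates[!removed[candidates] & pval[candidates] <= pThresh]
    if (!length(elig)) break
    o <- elig[order(pval[elig], chrom[elig], pos[elig])][1]
    out <- c(out, o)
    for (v in seq_along(pval)) {
      if (chrom[v] == chrom[o] && abs(pos[v] - pos[o]) <= windowKb * 1000 &&
          r2dense[v, o] >= r2Thresh)
        removed[v] <- TRUE
    }
    removed[o] <- TRUE
  }
  out
}

# hypergeometric tail enumeration for a one- or two-sided Fisher 2x2 test
oracleFisherP <- function(a, b, c_, d, alternative = "two.sided") {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  pr <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  pObs <- dhyper(a, m, n, k)
  if (alternative == "greater") sum(pr[(lo:hi) >= a])
  else if (alternative == "less") sum(pr[(lo:hi) <= a])
  else sum(pr[pr <= pObs * (1 + 1e-7)])
}

# textbook step-up adjustments with explicit monotonicity enforcement
oracleStepUp <- function(p, by = FALSE) {
  m <- length(p)
  ord <- order(p)
  cm <- if (by) sum(1 / seq_len(m)) else 1
  adj <- p[ord] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# AUROC as concordant pair counting (ties count 1/2)
oracleAUROC <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Laplacian quadratic form as the explicit edge sum
oracleEdgeSum <- function(A, beta) {
  d <- Matrix::rowSums(A)
  ij <- Matrix::which(A > 0, arr.ind = TRUE)
  ij <- ij[ij[, 1] < ij[, 2], , drop = FALSE]
  s <- 0
  for (r in seq_len(nrow(ij))) {
    u <- ij[r, 1]; v <- ij[r, 2]
    s <- s + (beta[u] / sqrt(d[u]) - beta[v] / sqrt(d[v]))^2
  }
  s
}

# build an LDMatrix + SumstatsTable pair directly from a dense r2 matrix,
# for clumping tests that need full control of the LD structure
syntheticLD <- function(r2dense, pval, chrom, pos, beta = NULL) {
  n <- length(pval)
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = "A", alt = "G", effect_allele = "G",
                  beta = if (is.null(beta)) rep(0.1, n) else beta,
                  pval = pval, maf = 0.25, info = 1,
                  stringsAsFactors = FALSE)
  ss <- new("SumstatsTable", variants = v, source = "test",
            build = "synthetic")
  r2s <- methods::as(Matrix::forceSymmetric(
    Matrix::Matrix(r2dense, sparse = TRUE)), "CsparseMatrix")
  ld <- new("LDMatrix", r2 = r2s, variants = v[, 1:4], windowKb = 250,
            source = "in_sample")
  list(ss = ss, ld = ld)
}

# random symmetric r2 matrix with unit diagonal
randomR2 <- function(n, density = 0.15) {
  m <- matrix(0, n, n)
  pairs <- which(upper.tri(m))
  on <- sample(pairs, ceiling(density * length(pairs)))
  m[on] <- runif(length(on))
  m <- m + t(m)
  diag(m) <- 1
  m
}

# one small simulated study, computed once per test run and shared
.studyCache <- new.env(parent = emptyenv())
tinyStudy <- function() {
  if (is.null(.studyCache$st)) {
    cfg <- simConfig(nTarget = 120, nDiscovery = 800, nVariants = 1200,
                     nChromosomes = 3, chromLen = 8e5, nCells = 90,
                     cellTypes = c("tcell", "bcell", "mono"),
                     causalType = "mono", nSpecificPeaks = 30,
                     nSharedPeaks = 45, sigma = 0.25, seed = 11)
    .studyCache$st <- suppressWarnings(simStudy(cfg))
    st <- .studyCache$st
    .studyCache$memb <- assignVariantsToPeaks(st$gwas$sumstats,
                                              peakRanges(st$atlas$cpm))
    .studyCache$tensor <- cellPRSTensor(st$target$genotypes,
                                        st$gwas$sumstats, st$atlas$cpm,
                                        st$ld, .studyCache$memb)
    .studyCache$graph <- buildCellGraph(st$atlas$cpm, k = 10)
  }
  list(st = .studyCache$st, memb = .studyCache$memb,
       tensor = .studyCache$tensor, graph = .studyCache$graph)
}
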