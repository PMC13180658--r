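test_that("the default C+T grid has 21 unique parameter pairs", {
  g <- defaultCTGrid()
  expect_equal(nrow(g), 21)
  expect_equal(anyDuplicated(g[, c("r2", "p")]), 0)
  expect_setequal(unique(g$r2), c(0.1, 0.3, 0.5))
  expect_setequal(unique(g$p), c(1e-5, 1e-4, 1e-3, 0.01, 0.05, 0.1, 0.5))
})

test_that("LD r2 matches hand-computed correlations and handles duplicates", {
  set.seed(3)
  d <- matrix(sample(0:2, 5 * 40, TRUE), 40, 5)
  d[, 2] <- d[, 1]                      # perfect duplicate
  rownames(d) <- paste0("S", 1:40)
  g <- new("GenotypeMatrix", dosages = d,
           variants = data.frame(chrom = "1", pos = c(1, 100, 5000, 9000,
                                                      20000),
                                 ref = "A", alt = "G",
                                 stringsAsFactors = FALSE))
  ld <- ldR2(g, windowKb = 250, r2Min = 0)
  r2 <- as.matrix(ld@r2)
  expect_equal(r2[1, 2], 1)
  hand <- cor(d)^2
  expect_equal(unname(r2), unname(hand), tolerance = 1e-12)
  expect_equal(diag(r2), rep(1, 5), ignore_attr = TRUE)
})

test_that("window restriction and monomorphic handling work", {
  set.seed(4)
  d <- matrix(sample(0:2, 3 * 30, TRUE), 30, 3)
  d[, 3] <- 1                            # monomorphic
  rownames(d) <- paste0("S", 1:30)
  g <- new("GenotypeMatrix", dosages = d,
           variants = data.frame(chrom = "1", pos = c(1, 3e5, 3.1e5),
                                 ref = "A", alt = "G",
                                 stringsAsFactors = FALSE))
  expect_warning(ld <- ldR2(g, windowKb = 250, r2Min = 0), "monomorphic")
  r2 <- as.matrix(ld@r2)
  expect_equal(r2[1, 2], 0)              # beyond 250 kb: not stored
  expect_equal(r2[2, 3], 0)              # undefined -> 0
})

test_that("mean off-diagonal r2 of independent variants is about 1/n", {
  set.seed(5)
  n <- 2000
  d <- matrix(rbinom(n * 12, 2, 0.3), n, 12)
  rownames(d) <- paste0("S", seq_len(n))
  g <- new("GenotypeMatrix", dosages = d,
           variants = data.frame(chrom = "1", pos = seq_len(12) * 10,
                                 ref = "A", alt = "G",
                                 stringsAsFactors = FALSE))
  ld <- ldR2(g, r2Min = 0)
  r2 <- as.matrix(ld@r2)
  off <- r2[upper.tri(r2)]
  expect_lt(abs(mean(off) - 1 / n), 3 / n)
})

test_that("clumping keeps the smallest-p variant among linked candidates", {
  r2 <- diag(2); r2[1, 2] <- r2[2, 1] <- 1
  syn <- syntheticLD(r2, pval = c(1e-4, 1e-6), chrom = c(1, 1),
                     pos = c(100, 200))
  idx <- clumpVariants(syn$ss, syn$ld, r2Thresh = 0.5, pThresh = 0.01)
  expect_equal(idx, 2L)
  # single candidate below threshold
  idx2 <- clumpVariants(syn$ss, syn$ld, candidates = 1L, r2Thresh = 0.5,
                        pThresh = 0.01)
  expect_equal(idx2, 1L)
  # empty candidate set is allowed
  expect_equal(clumpVariants(syn$ss, syn$ld, candidates = integer(0)),
               integer(0))
})

test_that("clumping agrees with the brute-force greedy oracle", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    r2 <- randomR2(n)
    pos <- sort(sample.int(5e5, n))
    chrom <- rep("1", n)
    pv <- runif(n)^2
    syn <- syntheticLD(r2, pv, chrom, pos)
    cand <- sort(sample.int(n, sample(5:n, 1)))
    r2t <- sample(c(0.1, 0.3, 0.5), 1)
    pt_ <- sample(c(0.05, 0.2, 1), 1)
    wk <- sample(c(50, 250), 1)
    got <- clumpVariants(syn$ss, syn$ld, candidates = cand, r2Thresh = r2t,
                         pThresh = pt_, windowKb = wk)
    want <- oracleClump(pv, chrom, pos, r2, cand, r2t, pt_, wk)
    expect_identical(got, as.integer(want))
  }
})

test_that("C+T PRS follows the ploidy-normalized formula", {
  mk <- function(d, beta, ea = rep("G", length(beta))) {
    v <- data.frame(chrom = "1", pos = seq_along(beta) * 100, ref = "A",
                    alt = "G", effect_allele = ea, beta = beta, pval = 0.5,
                    maf = 0.2, info = 1, stringsAsFactors = FALSE)
    rownames(d) <- paste0("S", seq_len(nrow(d)))
    list(g = new("GenotypeMatrix", dosages = d, variants = v[, 1:4]),
         ss = new("SumstatsTable", variants = v, source = "t", build = "b"))
  }
  # one variant, beta 0.5, dosage 2 -> (0.5*2)/(2*1) = 0.5
  x <- mk(matrix(2, 1, 1), 0.5)
  expect_equal(unname(ctPRS(x$g, x$ss, 1L)), 0.5)
  # two variants, beta (0.1, -0.2), dosages (1, 2) -> -0.075
  x <- mk(matrix(c(1, 2), 1, 2), c(0.1, -0.2))
  expect_equal(unname(ctPRS(x$g, x$ss, 1:2)), -0.075)
  # all dosages zero -> 0
  x <- mk(matrix(0, 2, 2), c(0.3, 0.4))
  expect_equal(unname(ctPRS(x$g, x$ss, 1:2)), c(0, 0))
  # missing dosages shrink the per-individual denominator
  d <- matrix(c(2, NA, 2, 2), 2, 2)    # S1: one nonmissing, S2: two
  x <- mk(d, c(0.5, 0.5))
  expect_equal(unname(ctPRS(x$g, x$ss, 1:2)), c((0.5 * 2) / (2 * 1),
                                        (0.5 * 2 + 0.5 * 2) / (2 * 2)))
  # effect allele = ref counts the complementary dosage
  x <- mk(matrix(2, 1, 1), 0.5, ea = "A")
  expect_equal(unname(ctPRS(x$g, x$ss, 1L)), 0)
  # linearity: doubling beta doubles the score
  set.seed(9)
  d <- matrix(sample(0:2, 12, TRUE), 3, 4)
  x1 <- mk(d, c(0.1, 0.2, -0.1, 0.3))
  x2 <- mk(d, 2 * c(0.1, 0.2, -0.1, 0.3))
  expect_equal(2 * ctPRS(x1$g, x1$ss, 1:4), ctPRS(x2$g, x2$ss, 1:4))
})

test_that("the cell PRS tensor handles degenerate cells and caching", {
  s <- tinyStudy()
  st <- s$st
  tens <- s$tensor
  expect_equal(dim(prsScores(tens))[3], 21)
  # a cell with zero accessible peaks yields all-zero features
  cpm <- st$atlas$cpm
  cnt <- peakCounts(cpm)
  cnt2 <- rbind(cnt[1:4, ], Matrix::sparseMatrix(i = integer(0),
                                                 j = integer(0),
                                                 dims = c(1, ncol(cnt))))
  cnt2[5, ] <- 0
  rownames(cnt2) <- c(rownames(cnt)[1:4], "empty_cell")
  cnt2[3, ] <- cnt2[2, ]                 # duplicate of cell 2
  cpm2 <- new("CellPeakMatrix", counts = methods::as(cnt2, "CsparseMatrix"),
              peaks = peakRanges(cpm), cellType = character(0))
  t2 <- cellPRSTensor(st$target$genotypes, st$gwas$sumstats, cpm2, st$ld,
                      s$memb)
  expect_true(all(prsScores(t2)[, 5, ] == 0))
  expect_equal(t2@nIndex[5, ], t2@nIndex[5, ] * 0L, ignore_attr = TRUE)
  # duplicated accessibility rows give identical feature vectors
  expect_equal(prsScores(t2)[, 2, ], prsScores(t2)[, 3, ])
  # caching is exact: cache-free recomputation is bit-identical
  t3 <- cellPRSTensor(st$target$genotypes, st$gwas$sumstats, cpm2, st$ld,
                      s$memb, cache = FALSE)
  expect_identical(prsScores(t2), prsScores(t3))
  expect_identical(t2@nIndex, t3@nIndex)
})

test_that("per-cell index sets stay within the cell's peak variants", {
  s <- tinyStudy()
  st <- s$st
  v <- variantTable(st$gwas$sumstats)
  acc <- peakCounts(st$atlas$cpm) > 0
  memb <- s$memb
  ldg <- scPRS:::.ldColumns(st$ld)
  grid <- defaultCTGrid()
  for (j in sample(nrow(acc), 6)) {
    cand <- which(Matrix::rowSums(memb[, which(acc[j, ]),
                                       drop = FALSE]) > 0)
    for (r2c in unique(grid$r2)) {
      idx <- scPRS:::.clumpCore(v, ldg, cand, r2c, 1, 250)
      expect_true(all(idx %in% cand))
    }
  }
})

test_that("nonpeak PRS composes clump and scoring on the complement set", {
  s <- tinyStudy()
  st <- s$st
  grid <- defaultCTGrid()[c(1, 10, 21), ]
  np <- nonpeakPRS(st$target$genotypes, st$gwas$sumstats, st$ld, s$memb,
                   grid = grid)
  cand <- which(Matrix::rowSums(s$memb) == 0)
  # disjoint from every peak-conditioned candidate set
  expect_equal(length(intersect(cand,
                                which(Matrix::rowSums(s$memb) > 0))), 0)
  for (k in seq_len(nrow(grid))) {
    idx <- clumpVariants(st$gwas$sumstats, st$ld, candidates = cand,
                         r2Thresh = grid$r2[k], pThresh = grid$p[k])
    manual <- ctPRS(st$target$genotypes, st$gwas$sumstats, idx)
    expect_equal(unname(np$features[, k]), unname(manual), tolerance = 1e-12)
  }
  # all variants inside peaks -> all features zero
  membAll <- s$memb
  membAll[] <- TRUE
  npAll <- nonpeakPRS(st$target$genotypes, st$gwas$sumstats, st$ld, membAll,
                      grid = grid)
  expect_true(all(npAll$features == 0))
})

test_that("cell-type PRS blocks match per-type manual clump+score", {
  s <- tinyStudy()
  st <- s$st
  grid <- defaultCTGrid()[c(3, 15), ]
  blocks <- celltypePRS(st$target$genotypes, st$gwas$sumstats,
                        st$atlas$cpm, st$ld, s$memb, grid = grid)
  lab <- cellTypes(st$atlas$cpm)
  expect_setequal(names(blocks), unique(lab))
  acc <- peakCounts(st$atlas$cpm) > 0
  ty <- unique(lab)[1]
  peaksTy <- which(Matrix::colSums(acc[lab == ty, , drop = FALSE]) > 0)
  cand <- which(Matrix::rowSums(s$memb[, peaksTy, drop = FALSE]) > 0)
  for (k in seq_len(nrow(grid))) {
    idx <- clumpVariants(st$gwas$sumstats, st$ld, candidates = cand,
                         r2Thresh = grid$r2[k], pThresh = grid$p[k])
    expect_equal(unname(blocks[[ty]][, k]),
                 unname(ctPRS(st$target$genotypes, st$gwas$sumstats, idx)),
                 tolerance = 1e-12)
  }
  # a single type covering all cells equals the union-peak block
  cpmOne <- new("CellPeakMatrix", counts = peakCounts(st$atlas$cpm),
                peaks = peakRanges(st$atlas$cpm),
                cellType = rep("all", nrow(acc)))
  b1 <- celltypePRS(st$target$genotypes, st$gwas$sumstats, cpmOne, st$ld,
                    s$memb, grid = grid)
  peaksAny <- which(Matrix::colSums(acc) > 0)
  candAll <- which(Matrix::rowSums(s$memb[, peaksAny, drop = FALSE]) > 0)
  idx <- clumpVariants(st$gwas$sumstats, st$ld, candidates = candAll,
                       r2Thresh = grid$r2[1], pThresh = grid$p[1])
  expect_equal(unname(b1$all[, 1]),
               unname(ctPRS(st$target$genotypes, st$gwas$sumstats, idx)))
})

test_that("multi-cell-type combination fits on training samples only", {
  s <- tinyStudy()
  st <- s$st
  grid <- defaultCTGrid()[c(5, 20), ]
  blocks <- celltypePRS(st$target$genotypes, st$gwas$sumstats,
                        st$atlas$cpm, st$ld, s$memb, grid = grid)
  keep <- match(sampleIds(st$target$genotypes),
                sampleIds(st$target$genotypes))
  y <- st$phenotype$labels
  train <- seq_len(80)
  sc <- combineMultiCelltype(blocks, y, train)
  expect_length(sc, length(y))
  expect_true(all(is.finite(sc)))
})

test_that("normalization centers and scales with stored statistics", {
  s <- tinyStudy()
  tens <- s$tensor
  n <- dim(prsScores(tens))[1]
  fit <- seq_len(floor(0.6 * n))
  tn <- normalizePRS(tens, fitSamples = fit)
  x <- prsScores(tn)
  sub <- x[fit, , , drop = FALSE]
  mu <- apply(sub, c(2, 3), mean)
  sg <- apply(sub, c(2, 3), sd)
  live <- sg > 0
  expect_lt(max(abs(mu[live])), 1e-12)
  expect_lt(max(abs(sg[live] - 1)), 1e-12)
  # constant features become exactly zero
  dead <- which(!live, arr.ind = TRUE)
  if (nrow(dead))
    for (r in seq_len(nrow(dead)))
      expect_true(all(x[, dead[r, 1], dead[r, 2]] == 0))
  # held-out samples transform with training statistics
  hold <- setdiff(seq_len(n), fit)
  raw <- prsScores(tens)
  st0 <- tn@normStats
  manual <- (raw[hold[1], 3, 5] - st0$mean[3, 5]) /
    ifelse(st0$sd[3, 5] == 0, 1, st0$sd[3, 5])
  if (st0$sd[3, 5] == 0) manual <- 0
  expect_equal(x[hold[1], 3, 5], manual)
  # reapplying stored stats to the raw tensor reproduces the result
  tn2 <- normalizePRS(tens, stats = st0)
  expect_identical(prsScores(tn2), prsScores(tn))
})
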