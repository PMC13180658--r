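#' Simulation configuration
#'
#' Study conditions for the coupled genotype-atlas-phenotype simulation:
#' block-LD genotypes drawn from a haplotype pool with recombination, a cell
#' atlas with cell-type-specific peaks, GWAS summary statistics from a
#' simulated discovery cohort, and phenotypes built as a standardized
#' peak-restricted PRS plus Gaussian noise.
#'
#' @param nTarget target-cohort individuals.
#' @param nDiscovery discovery-cohort individuals (GWAS).
#' @param nVariants total variants across chromosomes.
#' @param nChromosomes chromosome count.
#' @param chromLen chromosome length in bp.
#' @param haplotypePoolSize haplotypes in the ancestral pool per chromosome;
#'   the single LD knob (2 = near-perfect within-block LD, `Inf` = fresh
#'   independent haplotypes per draw).
#' @param recombMean expected recombination breakpoints per haplotype per
#'   chromosome.
#' @param mafRange range minor-allele frequencies are drawn from.
#' @param nCells atlas cells (split evenly across types).
#' @param cellTypes cell type names.
#' @param causalType the type whose specific peaks harbour causal variants.
#' @param nSpecificPeaks type-specific peaks per type.
#' @param nSharedPeaks peaks accessible across all types.
#' @param peakWidth peak width in bp.
#' @param pOn accessibility probability of a type's own specific peaks.
#' @param pOff accessibility probability of other types' specific peaks.
#' @param pShared accessibility probability of shared peaks.
#' @param dropoutRate independent dropout applied after accessibility.
#' @param effectScale sd of causal effect sizes beta*.
#' @param sigma phenotype noise sd added to the standardized PRS.
#' @param peakNoiseFrac fraction of causal peaks replaced by decoys when
#'   scoring the phenotype.
#' @param seed master seed; all generator randomness derives from it.
#' @return named list of class "simConfig".
#' @export
simConfig <- function(nTarget = 600, nDiscovery = 4000, nVariants = 5000,
                      nChromosomes = 5, chromLen = 1.25e6,
                      haplotypePoolSize = 20, recombMean = 1,
                      mafRange = c(0.05, 0.5), nCells = 1500,
                      cellTypes = c("tcell", "bcell", "nk", "mono"),
                      causalType = "mono", nSpecificPeaks = 60,
                      nSharedPeaks = 100, peakWidth = 1000, pOn = 0.8,
                      pOff = 0.05, pShared = 0.7, dropoutRate = 0.2,
                      effectScale = 0.15, sigma = 0.25, peakNoiseFrac = 0,
                      seed = 1) {
  cfg <- as.list(environment())
  if (!causalType %in% cellTypes) stop("causalType must be one of cellTypes")
  for (f in c("dropoutRate", "pOn", "pOff", "pShared", "peakNoiseFrac"))
    .stopifnotScalarFraction(cfg[[f]], f)
  if (any(c(nTarget, nDiscovery, nVariants, nCells) <= 0))
    stop("counts must be positive")
  class(cfg) <- "simConfig"
  cfg
}

.subSeed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + k) %%
                                           2147483647)

# variant map shared by all cohorts of one configuration
.simVariantMap <- function(cfg) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(cfg$seed, 1))
  perChrom <- rep(floor(cfg$nVariants / cfg$nChromosomes), cfg$nChromosomes)
  perChrom[1] <- perChrom[1] + cfg$nVariants - sum(perChrom)
  v <- do.call(rbind, lapply(seq_len(cfg$nChromosomes), function(ch) {
    pos <- sort(sample.int(cfg$chromLen - 1, perChrom[ch]))
    data.frame(chrom = as.character(ch), pos = pos)
  }))
  bases <- c("A", "C", "G", "T")
  v$ref <- sample(bases, nrow(v), replace = TRUE)
  # alt differs from ref and avoids strand-ambiguous pairs
  v$alt <- vapply(v$ref, function(r)
    sample(setdiff(bases, c(r, .complement(r))), 1), character(1))
  v$maf <- runif(nrow(v), cfg$mafRange[1], cfg$mafRange[2])
  v
}

#' Simulate block-LD genotypes
#'
#' Per chromosome, an ancestral pool of haplotypes is drawn with per-variant
#' allele frequencies; each individual haplotype is a recombinant mosaic of
#' pool members (Poisson breakpoints), which yields realistic local LD for
#' clumping while keeping Hardy-Weinberg equilibrium. Deterministic under
#' `seed`.
#'
#' @param cfg a [simConfig()].
#' @param n individuals to draw (defaults to `cfg$nTarget`).
#' @param seed seed for this cohort (defaults to the config seed; use a
#'   different value for an independent cohort such as the discovery panel).
#' @param prefix sample-id prefix.
#' @return list with `genotypes` (a [GenotypeMatrix-class], dosages counting
#'   the alt allele) and `trueMAF` (the generating frequencies).
#' @export
simGenotypes <- function(cfg, n = cfg$nTarget, seed = cfg$seed,
                         prefix = "S") {
  vmap <- .simVariantMap(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(seed, 2))
  d <- matrix(0L, n, nrow(vmap))
  fresh <- !is.finite(cfg$haplotypePoolSize)
  for (ch in unique(vmap$chrom)) {
    idx <- which(vmap$chrom == ch)
    m <- length(idx)
    f <- vmap$maf[idx]
    if (fresh) {
      h1 <- matrix(rbinom(n * m, 1, rep(f, each = n)), n, m)
      h2 <- matrix(rbinom(n * m, 1, rep(f, each = n)), n, m)
      d[, idx] <- h1 + h2
      next
    }
    P <- cfg$haplotypePoolSize
    pool <- matrix(rbinom(P * m, 1, rep(f, each = P)), P, m)
    pos <- vmap$pos[idx]
    drawHap <- function() {
      nb <- rpois(1, cfg$recombMean)
      cuts <- sort(runif(nb, 0, cfg$chromLen))
      seg <- findInterval(pos, cuts) + 1L
      src <- sample.int(P, nb + 1L, replace = TRUE)
      pool[cbind(src[seg], seq_len(m))]
    }
    for (i in seq_len(n)) d[i, idx] <- drawHap() + drawHap()
  }
  storage.mode(d) <- "double"
  rownames(d) <- sprintf("%s%05d", prefix, seq_len(n))
  g <- new("GenotypeMatrix", dosages = d,
           variants = vmap[, c("chrom", "pos", "ref", "alt")])
  list(genotypes = g, trueMAF = pmin(vmap$maf, 1 - vmap$maf))
}

#' Simulate a cell atlas with type-specific peaks
#'
#' Non-overlapping peaks tile the simulated chromosomes; each cell type has
#' its own specific peaks (accessible with probability `pOn` in the type,
#' `pOff` elsewhere) plus shared peaks accessible in all types; independent
#' dropout is applied on top and accessible entries carry small positive
#' integer counts.
#'
#' @param cfg a [simConfig()].
#' @param seed seed (defaults to the config seed).
#' @return list with `cpm` (a [CellPeakMatrix-class] with labels),
#'   `specificPeaks` (named list: peak ids per type) and `sharedPeaks`.
#' @export
simCellAtlas <- function(cfg, seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(seed, 3))
  nTypes <- length(cfg$cellTypes)
  nPeaks <- nTypes * cfg$nSpecificPeaks + cfg$nSharedPeaks
  slotsPerChrom <- floor(cfg$chromLen / (2 * cfg$peakWidth))
  if (nPeaks > slotsPerChrom * cfg$nChromosomes)
    stop("too many peaks for the simulated genome")
  slots <- expand.grid(chrom = seq_len(cfg$nChromosomes),
                       slot = seq_len(slotsPerChrom))
  pick <- sample.int(nrow(slots), nPeaks)
  start0 <- (slots$slot[pick] - 1L) * 2L * cfg$peakWidth
  peaks <- GenomicRanges::GRanges(
    as.character(slots$chrom[pick]),
    IRanges::IRanges(start = start0 + 1L, width = cfg$peakWidth))
  names(peaks) <- sprintf("peak_%04d", seq_len(nPeaks))
  role <- c(rep(cfg$cellTypes, each = cfg$nSpecificPeaks),
            rep("shared", cfg$nSharedPeaks))
  labels <- rep(cfg$cellTypes, length.out = cfg$nCells)[
    sample.int(cfg$nCells)]
  pAcc <- matrix(cfg$pOff, cfg$nCells, nPeaks)
  pAcc[, role == "shared"] <- cfg$pShared
  for (ty in cfg$cellTypes)
    pAcc[labels == ty, role == ty] <- cfg$pOn
  acc <- matrix(rbinom(length(pAcc), 1, pAcc), cfg$nCells, nPeaks)
  acc <- acc * matrix(rbinom(length(acc), 1, 1 - cfg$dropoutRate),
                      cfg$nCells, nPeaks)
  cnt <- acc * (1 + matrix(rpois(length(acc), 0.5), cfg$nCells, nPeaks))
  m <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
  dimnames(m) <- list(sprintf("cell_%05d", seq_len(cfg$nCells)),
                      names(peaks))
  cpm <- new("CellPeakMatrix", counts = m, peaks = peaks,
             cellType = labels)
  list(cpm = cpm,
       specificPeaks = split(names(peaks)[role != "shared"],
                             role[role != "shared"])[cfg$cellTypes],
       sharedPeaks = names(peaks)[role == "shared"])
}

#' Simulate GWAS summary statistics
#'
#' True effects beta* ~ N(0, effectScale^2) are planted on variants inside
#' the causal-type-specific peaks (zero elsewhere); a discovery phenotype
#' G beta* + N(0,1) noise is drawn for the discovery cohort, and per-variant
#' marginal regressions yield the reported beta and p -- so LD-induced
#' non-causal associations exist, as in real GWAS.
#'
#' @param cfg a [simConfig()].
#' @param discovery discovery-cohort [GenotypeMatrix-class]
#'   (from [simGenotypes()] with its own seed).
#' @param causalPeaks GRanges of causal-type-specific peaks.
#' @param seed seed (defaults to the config seed).
#' @return list with `sumstats` (a [SumstatsTable-class]), `trueBeta`
#'   (per-variant causal effects) and `causalVariants` (indices).
#' @export
simGWAS <- function(cfg, discovery, causalPeaks, seed = cfg$seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(seed, 4))
  G <- discovery@dosages
  v <- discovery@variants
  memb <- assignVariantsToPeaks(discovery, causalPeaks)
  causal <- which(Matrix::rowSums(memb) > 0)
  trueBeta <- numeric(nrow(v))
  trueBeta[causal] <- rnorm(length(causal), 0, cfg$effectScale)
  y <- drop(G %*% trueBeta) + rnorm(nrow(G))
  n <- nrow(G)
  r <- suppressWarnings(as.vector(cor(G, y)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -0.999999), 0.999999)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pval <- 2 * pt(-abs(tstat), df = n - 2)
  pval[pval <= 0] <- .Machine$double.xmin
  sdG <- apply(G, 2, sd)
  beta <- ifelse(sdG > 0, r * sd(y) / ifelse(sdG > 0, sdG, 1), 0)
  f <- colMeans(G) / 2
  ss <- new("SumstatsTable",
            variants = data.frame(v, effect_allele = v$alt, beta = beta,
                                  pval = pval, maf = pmin(f, 1 - f),
                                  info = NA_real_,
                                  stringsAsFactors = FALSE),
            source = "simulated_gwas", build = "synthetic")
  list(sumstats = ss, trueBeta = trueBeta, causalVariants = causal)
}

#' Simulate the target phenotype
#'
#' The noiseless phenotype is the standardized C+T PRS of the target cohort
#' with index candidates restricted to the scoring peak set: the causal
#' peaks, a fraction of which (`peakNoiseFrac`) is replaced by randomly
#' selected decoy peaks specific to other types. Gaussian noise with sd
#' `sigma` is then added (the noisy phenotype is not re-standardized). A
#' median split provides binary labels for the classification pathway.
#'
#' @param g target [GenotypeMatrix-class] (harmonized with `ss`).
#' @param ss [SumstatsTable-class] aligned to `g`.
#' @param causalPeaks GRanges of causal peaks.
#' @param decoyPeaks GRanges pool of non-causal-type-specific peaks
#'   (required when `peakNoiseFrac > 0`).
#' @param sigma noise sd.
#' @param peakNoiseFrac fraction of causal peaks replaced by decoys.
#' @param seed RNG seed (noise and decoy choice).
#' @param ld optional [LDMatrix-class]; computed in-sample when NULL.
#' @param r2,p,windowKb C+T parameters used for scoring.
#' @return list with `y` (standardized noiseless PRS), `yTilde` (noisy),
#'   `labels` (median split of `yTilde`), `indexVariants`, `scoringPeaks`.
#' @export
simPhenotype <- function(g, ss, causalPeaks, decoyPeaks = NULL, sigma = 0.25,
                         peakNoiseFrac = 0, seed = 1, ld = NULL, r2 = 0.1,
                         p = 0.5, windowKb = 250) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(seed, 5))
  scoring <- causalPeaks
  if (peakNoiseFrac > 0) {
    if (is.null(decoyPeaks)) stop("decoyPeaks required when peakNoiseFrac > 0")
    nSwap <- round(peakNoiseFrac * length(causalPeaks))
    keep <- sample(seq_along(causalPeaks),
                   length(causalPeaks) - nSwap)
    decoys <- decoyPeaks[sample(seq_along(decoyPeaks),
                                min(nSwap, length(decoyPeaks)))]
    scoring <- c(causalPeaks[keep], decoys)
  }
  if (!length(scoring)) stop("scoring peak set is empty")
  memb <- assignVariantsToPeaks(ss, scoring)
  cand <- which(Matrix::rowSums(memb) > 0)
  if (!length(cand)) stop("scoring peak set contains no variants")
  if (is.null(ld)) ld <- ldR2(g, windowKb = windowKb)
  idx <- clumpVariants(ss, ld, candidates = cand, r2Thresh = r2,
                       pThresh = p, windowKb = windowKb)
  raw <- ctPRS(g, ss, idx)
  if (sd(raw) == 0) stop("PRS is constant; cannot standardize")
  y <- as.numeric(scale(raw))
  yTilde <- y + rnorm(length(y), 0, sigma)
  list(y = y, yTilde = yTilde,
       labels = as.integer(yTilde > stats::median(yTilde)),
       indexVariants = idx, scoringPeaks = scoring)
}

#' Generate a full simulated study in memory
#'
#' Convenience wrapper chaining [simGenotypes()] (target and discovery),
#' [simCellAtlas()], [simGWAS()] and [simPhenotype()] under one
#' configuration. The in-sample LD of the target cohort is computed once and
#' reused.
#'
#' @param cfg a [simConfig()].
#' @param sigma phenotype noise sd (defaults to `cfg$sigma`).
#' @param peakNoiseFrac defaults to `cfg$peakNoiseFrac`.
#' @return list with target, discovery, atlas, gwas, ld, phenotype.
#' @export
simStudy <- function(cfg, sigma = cfg$sigma,
                     peakNoiseFrac = cfg$peakNoiseFrac) {
  target <- simGenotypes(cfg, n = cfg$nTarget, seed = cfg$seed)
  discovery <- simGenotypes(cfg, n = cfg$nDiscovery,
                            seed = .subSeed(cfg$seed, 11), prefix = "D")
  atlas <- simCellAtlas(cfg)
  peaks <- peakRanges(atlas$cpm)
  causalPeaks <- peaks[atlas$specificPeaks[[cfg$causalType]]]
  decoyIds <- unlist(atlas$specificPeaks[setdiff(cfg$cellTypes,
                                                 cfg$causalType)])
  gwas <- simGWAS(cfg, discovery$genotypes, causalPeaks)
  ld <- ldR2(target$genotypes)
  pheno <- simPhenotype(target$genotypes, gwas$sumstats, causalPeaks,
                        decoyPeaks = peaks[decoyIds], sigma = sigma,
                        peakNoiseFrac = peakNoiseFrac, seed = cfg$seed,
                        ld = ld)
  list(target = target, discovery = discovery, atlas = atlas, gwas = gwas,
       ld = ld, phenotype = pheno, causalPeaks = causalPeaks,
       config = cfg)
}

#' Remove causal-type and causal-like cells from an atlas
#'
#' Negative-control ablation: drops all cells of the causal type plus any
#' remaining cell whose count of accessible causal-type-specific peaks
#' exceeds `maxCausalPeaks`.
#'
#' @param cpm a [CellPeakMatrix-class] with labels.
#' @param causalType causal cell type name.
#' @param causalPeakIds peak ids of the causal-type-specific peaks.
#' @param maxCausalPeaks threshold on accessible causal peaks.
#' @return logical keep vector over cells.
#' @export
ablateCausalCells <- function(cpm, causalType, causalPeakIds,
                              maxCausalPeaks) {
  nCausal <- Matrix::rowSums(
    cpm@counts[, causalPeakIds, drop = FALSE] > 0)
  cellTypes(cpm) != causalType & nCausal <= maxCausalPeaks
}

#' Subset a CellPeakMatrix by cells
#'
#' @param cpm a [CellPeakMatrix-class].
#' @param keep logical or integer cell index.
#' @return a [CellPeakMatrix-class] over the retained cells.
#' @export
subsetCells <- function(cpm, keep) {
  new("CellPeakMatrix", counts = cpm@counts[keep, , drop = FALSE],
      peaks = cpm@peaks,
      cellType = if (length(cpm@cellType)) cpm@cellType[keep]
                 else character(0))
}

#' Write a simulated study to a fixture directory
#'
#' Writes target genotypes (VCF), summary statistics (TSV), peaks (BED,
#' 0-based half-open), the cell matrix (MatrixMarket + barcodes + labels),
#' phenotype/labels (TSV) and a truth file (YAML: causal type, causal peaks,
#' true effects, seed) -- all readable by the package readers with zero
#' configuration. Identical configuration and seed give byte-identical
#' bundles; on a partial write the directory is removed and an error is
#' raised.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created; must not already contain a
#'   fixture).
#' @param study optional precomputed [simStudy()] result.
#' @return invisibly, the list of files written.
#' @export
makeFixture <- function(cfg, outDir, study = simStudy(cfg)) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(outDir, recursive = TRUE))
  gm <- study$target$genotypes
  v <- gm@variants
  # genotypes: minimal GT-only VCF
  gtCode <- c("0/0", "0/1", "1/1")
  D <- gm@dosages
  gtxt <- matrix(gtCode[D + 1], nrow(D), ncol(D))
  gtxt[is.na(D)] <- "./."
  vcf <- file.path(outDir, "genotypes.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=scPRSsim",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(D)), collapse = "\t"))
  body <- paste(v$chrom, v$pos, sprintf("var_%05d", seq_len(nrow(v))),
                v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gtxt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcf)
  # sumstats
  st <- file.path(outDir, "sumstats.tsv")
  write.table(study$gwas$sumstats@variants, st, sep = "\t", quote = FALSE,
              row.names = FALSE)
  # peaks BED (back to 0-based half-open) + matrix + barcodes + labels
  cpm <- study$atlas$cpm
  pk <- peakRanges(cpm)
  bed <- file.path(outDir, "peaks.bed")
  write.table(data.frame(as.character(GenomicRanges::seqnames(pk)),
                         GenomicRanges::start(pk) - 1L,
                         GenomicRanges::end(pk), names(pk)),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  mtx <- file.path(outDir, "matrix.mtx")
  Matrix::writeMM(cpm@counts, mtx)
  bcf <- file.path(outDir, "barcodes.tsv")
  writeLines(barcodes(cpm), bcf)
  lbf <- file.path(outDir, "labels.tsv")
  write.table(data.frame(barcode = barcodes(cpm),
                         cell_type = cellTypes(cpm)),
              lbf, sep = "\t", quote = FALSE, row.names = FALSE)
  # phenotype
  phf <- file.path(outDir, "phenotype.tsv")
  write.table(data.frame(sample = rownames(D), y = study$phenotype$y,
                         y_tilde = study$phenotype$yTilde,
                         label = study$phenotype$labels),
              phf, sep = "\t", quote = FALSE, row.names = FALSE)
  # truth
  trf <- file.path(outDir, "truth.yaml")
  yaml::write_yaml(list(
    causal_type = cfg$causalType,
    causal_peaks = as.list(study$atlas$specificPeaks[[cfg$causalType]]),
    true_beta = as.list(round(study$gwas$trueBeta[study$gwas$causalVariants],
                              10)),
    causal_variants = as.list(study$gwas$causalVariants),
    scoring_ct_params = list(r2 = 0.1, p = 0.5),
    sigma = cfg$sigma, peak_noise_frac = cfg$peakNoiseFrac,
    seed = cfg$seed), trf)
  ok <- TRUE
  invisible(list(genotypes = vcf, sumstats = st, peaks = bed, matrix = mtx,
                 barcodes = bcf, labels = lbf, phenotype = phf, truth = trf))
}

#' Read a fixture directory back
#'
#' @param dir directory written by [makeFixture()].
#' @return list with genotypes, sumstats, cpm, phenotype (data.frame) and
#'   truth (list).
#' @export
readFixture <- function(dir) {
  list(genotypes = readGenotypes(file.path(dir, "genotypes.vcf"), "vcf"),
       sumstats = readSumstats(file.path(dir, "sumstats.tsv"),
                               source = "fixture", build = "synthetic"),
       cpm = readCellPeakMatrix(file.path(dir, "matrix.mtx"),
                                file.path(dir, "peaks.bed"),
                                file.path(dir, "barcodes.tsv"),
                                file.path(dir, "labels.tsv")),
       phenotype = read.delim(file.path(dir, "phenotype.tsv")),
       truth = yaml::read_yaml(file.path(dir, "truth.yaml")))
}
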