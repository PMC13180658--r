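#' Read GWAS summary statistics
#'
#' Parses a delimited text file of GWAS summary statistics into a
#' [SumstatsTable-class]. Columns are resolved through `columnMap`, so any
#' header naming convention can be used. Rows with unparseable or
#' out-of-domain `beta`/`pval` (p must lie in (0, 1]) are rejected with a
#' warning reporting the count. Duplicate variant keys are retained here and
#' flagged; [qcSumstats()] removes them.
#'
#' @param path file path; tab- or comma-delimited with a header.
#' @param columnMap named character vector mapping internal names
#'   (chrom, pos, ref, alt, effect_allele, beta, pval, maf, info) to file
#'   column names. `effect_allele`, `maf` and `info` are optional; when
#'   `effect_allele` is unmapped the alt allele is taken as the effect allele.
#' @param source free-text source label stored as provenance.
#' @param build genome build tag stored as provenance.
#' @return a [SumstatsTable-class].
#' @export
readSumstats <- function(path,
                         columnMap = c(chrom = "chrom", pos = "pos",
                                       ref = "ref", alt = "alt",
                                       effect_allele = "effect_allele",
                                       beta = "beta", pval = "pval",
                                       maf = "maf", info = "info"),
                         source = basename(path), build = "unknown") {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "beta", "pval")
  for (f in required) {
    cn <- columnMap[[f]]
    if (is.null(cn) || !cn %in% names(raw))
      stop(sprintf("required column '%s' (mapped to '%s') not found in %s",
                   f, if (is.null(cn)) "<unmapped>" else cn, path))
  }
  pick <- function(f, default = NA) {
    cn <- columnMap[[f]]
    if (!is.null(cn) && cn %in% names(raw)) raw[[cn]] else rep(default, nrow(raw))
  }
  v <- data.frame(
    chrom = .normChrom(pick("chrom")),
    pos = as.integer(pick("pos")),
    ref = toupper(as.character(pick("ref"))),
    alt = toupper(as.character(pick("alt"))),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    pval = suppressWarnings(as.numeric(pick("pval"))),
    maf = suppressWarnings(as.numeric(pick("maf"))),
    info = suppressWarnings(as.numeric(pick("info"))),
    stringsAsFactors = FALSE)
  v$effect_allele[is.na(v$effect_allele)] <- v$alt[is.na(v$effect_allele)]
  ok <- !is.na(v$beta) & !is.na(v$pval) & v$pval > 0 & v$pval <= 1 &
    !is.na(v$pos) & v$pos >= 1 &
    (v$effect_allele == v$ref | v$effect_allele == v$alt)
  if (any(!ok))
    warning(sprintf("%d malformed row(s) rejected while reading %s",
                    sum(!ok), path))
  new("SumstatsTable", variants = v[ok, , drop = FALSE], source = source,
      build = build)
}

#' Quality-control GWAS summary statistics
#'
#' Removes variants with low MAF or imputation INFO, all rows sharing a
#' duplicated (chrom, pos, ref, alt) key, and strand-ambiguous (A/T, C/G)
#' variants. When the INFO column is entirely absent (e.g. WGS-based
#' sumstats) the INFO filter is skipped with a message.
#'
#' @param ss a [SumstatsTable-class].
#' @param mafMin minimum MAF retained.
#' @param infoMin minimum INFO retained.
#' @param dropAmbiguous drop strand-ambiguous A/T and C/G variants.
#' @return filtered [SumstatsTable-class]. Idempotent.
#' @export
qcSumstats <- function(ss, mafMin = 0.001, infoMin = 0.6,
                       dropAmbiguous = TRUE) {
  .stopifnotScalarFraction(mafMin, "mafMin")
  .stopifnotScalarFraction(infoMin, "infoMin")
  v <- ss@variants
  keep <- rep(TRUE, nrow(v))
  if (!all(is.na(v$maf))) keep <- keep & !is.na(v$maf) & v$maf >= mafMin
  if (all(is.na(v$info))) {
    message("INFO column absent; imputation-score filter skipped")
  } else {
    keep <- keep & !is.na(v$info) & v$info >= infoMin
  }
  key <- .variantKey(v)
  keep <- keep & !(key %in% key[duplicated(key)])
  if (dropAmbiguous) keep <- keep & !.isAmbiguous(v$ref, v$alt)
  if (!any(keep)) stop("no variants survive summary-statistics QC")
  new("SumstatsTable", variants = v[keep, , drop = FALSE],
      source = ss@source, build = ss@build)
}

#' Read target-cohort genotypes
#'
#' Reads diploid genotypes from a (GT-only) VCF or a dosage TSV into a
#' [GenotypeMatrix-class]. VCF genotypes are converted as 0/0 -> 0,
#' 0/1 -> 1, 1/1 -> 2 and ./. -> missing; phased separators are accepted.
#' Dosage TSVs carry columns chrom, pos, ref, alt followed by one column per
#' sample with entries 0/1/2 or NA.
#'
#' @param path file path.
#' @param format "vcf" or "dosage_tsv".
#' @param multiallelic "reject" drops multiallelic VCF records with a warning;
#'   "split" expands them into one biallelic record per alternate allele.
#' @return a [GenotypeMatrix-class] with dosages counting the alt allele.
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage_tsv"),
                          multiallelic = c("reject", "split")) {
  format <- match.arg(format)
  multiallelic <- match.arg(multiallelic)
  if (format == "dosage_tsv") {
    raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    meta <- c("chrom", "pos", "ref", "alt")
    if (!all(meta %in% names(raw)))
      stop("dosage TSV must have columns chrom, pos, ref, alt")
    smp <- setdiff(names(raw), meta)
    d <- t(as.matrix(raw[, smp, drop = FALSE]))
    storage.mode(d) <- "double"
    rownames(d) <- smp
    v <- data.frame(chrom = .normChrom(raw$chrom), pos = as.integer(raw$pos),
                    ref = toupper(raw$ref), alt = toupper(raw$alt),
                    stringsAsFactors = FALSE)
    return(new("GenotypeMatrix", dosages = d, variants = v))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    if (multiallelic == "reject") {
      warning(sprintf("%d multiallelic record(s) dropped", sum(multi)))
    } else {
      # expand each multiallelic record into per-alt biallelic rows
      addFix <- list(); addGT <- list()
      for (i in which(multi)) {
        alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
        for (ai in seq_along(alts)) {
          f <- fix[i, , drop = FALSE]; f$ALT <- alts[ai]
          addFix[[length(addFix) + 1]] <- f
          addGT[[length(addGT) + 1]] <- gsub(sprintf("(?<![0-9])%d(?![0-9])", ai),
                                             "x", gt[i, ], perl = TRUE)
        }
      }
      gtNew <- do.call(rbind, lapply(addGT, function(g) {
        g <- gsub("[0-9]+", "0", g); gsub("x", "1", g)
      }))
      fix <- rbind(fix[!multi, , drop = FALSE], do.call(rbind, addFix))
      gt <- rbind(gt[!multi, , drop = FALSE], gtNew)
      multi <- rep(FALSE, nrow(fix))
    }
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  code <- function(g, id) {
    out <- rep(NA_real_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    miss <- is.na(g) | g %in% c("./.", ".")
    parts <- strsplit(g[!miss], "/", fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad))
      stop(sprintf("non-diploid genotype at record %s", id))
    out[!miss] <- vapply(parts, function(p) sum(p == "1"), numeric(1))
    out
  }
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), NULL))
  for (j in seq_len(nrow(gt)))
    d[, j] <- code(gt[j, ], paste0(fix$CHROM[j], ":", fix$POS[j]))
  v <- data.frame(chrom = .normChrom(fix$CHROM), pos = as.integer(fix$POS),
                  ref = toupper(fix$REF), alt = toupper(fix$ALT),
                  stringsAsFactors = FALSE)
  new("GenotypeMatrix", dosages = d, variants = v)
}

#' In-cohort minor-allele frequencies
#'
#' @param g a [GenotypeMatrix-class].
#' @return numeric vector of per-variant MAF (folded to [0, 0.5]), computed
#'   from nonmissing dosages.
#' @export
cohortMAF <- function(g) {
  f <- colMeans(g@dosages, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Quality-control target genotypes
#'
#' Variant-level filters: missing call rate, in-cohort MAF and
#' Hardy-Weinberg equilibrium (Pearson chi-square test, 1 df, computed on the
#' whole cohort; `hweMidP = TRUE` switches to the exact mid-p test). Sample
#' -level filters: genotype missingness and heterozygosity rate beyond
#' `hetSd` standard deviations from the cohort mean. Idempotent.
#'
#' @param g a [GenotypeMatrix-class].
#' @param missMax maximum per-variant missing call rate.
#' @param mafMin minimum in-cohort MAF.
#' @param hwePmin minimum HWE p-value.
#' @param sampleMissMax maximum per-sample missingness.
#' @param hetSd heterozygosity-rate cutoff in standard deviations.
#' @param hweMidP use the exact mid-p HWE test instead of chi-square.
#' @return filtered [GenotypeMatrix-class].
#' @export
qcGenotypes <- function(g, missMax = 0.01, mafMin = 0.01, hwePmin = 1e-6,
                        sampleMissMax = 0.01, hetSd = 3, hweMidP = FALSE) {
  d <- g@dosages
  if (!nrow(d) || !ncol(d)) stop("empty genotype matrix")
  miss <- colMeans(is.na(d))
  maf <- cohortMAF(g)
  hwe <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]; x <- x[!is.na(x)]
    .hweP(sum(x == 0), sum(x == 1), sum(x == 2), midp = hweMidP)
  }, numeric(1))
  keepV <- miss <= missMax & !is.na(maf) & maf >= mafMin &
    (is.na(hwe) | hwe >= hwePmin)
  d <- d[, keepV, drop = FALSE]
  v <- g@variants[keepV, , drop = FALSE]
  sMiss <- rowMeans(is.na(d))
  het <- rowMeans(d == 1, na.rm = TRUE)
  mu <- mean(het); s <- sd(het)
  keepS <- sMiss <= sampleMissMax &
    (s == 0 | is.na(s) | abs(het - mu) <= hetSd * s)
  if (!any(keepS)) stop("all samples removed by genotype QC")
  new("GenotypeMatrix", dosages = d[keepS, , drop = FALSE], variants = v)
}

#' Harmonize alleles between summary statistics and genotypes
#'
#' Intersects the two variant sets on (chrom, pos) and resolves allele
#' orientation: direct match, swapped ref/alt (dosages reflected so that they
#' count the sumstats alt allele), strand-flipped to the complementary
#' alleles, or flipped and swapped. Unresolvable sites are dropped. The
#' returned genotype dosages count the sumstats alt allele; effect-allele
#' counting for scoring is handled in [ctPRS()].
#'
#' @param ss a QCed [SumstatsTable-class].
#' @param g a QCed [GenotypeMatrix-class].
#' @return list with elements `sumstats`, `genotypes` (identical variant keys,
#'   same order) and `report` (named counts of each resolution category).
#' @export
harmonizeAlleles <- function(ss, g) {
  sv <- ss@variants
  gv <- g@variants
  sKey <- paste(sv$chrom, sv$pos)
  gKey <- paste(gv$chrom, gv$pos)
  gIdx <- match(gKey, sKey)        # first sumstats row at each genotype site
  cat0 <- rep("unmatched", nrow(gv))
  flip <- function(x) .complement(x)
  si <- gIdx
  has <- !is.na(si)
  sRef <- sv$ref[si]; sAlt <- sv$alt[si]
  direct <- has & gv$ref == sRef & gv$alt == sAlt
  swapped <- has & !direct & gv$ref == sAlt & gv$alt == sRef
  fRef <- flip(gv$ref); fAlt <- flip(gv$alt)
  flipD <- has & !direct & !swapped & fRef == sRef & fAlt == sAlt
  flipS <- has & !direct & !swapped & !flipD & fRef == sAlt & fAlt == sRef
  cat0[direct] <- "direct"; cat0[swapped] <- "swapped"
  cat0[flipD] <- "strand_flipped"; cat0[flipS] <- "flipped_swapped"
  keep <- direct | swapped | flipD | flipS
  if (!any(keep)) stop("no variants overlap between sumstats and genotypes")
  d <- g@dosages[, keep, drop = FALSE]
  refl <- (swapped | flipS)[keep]
  d[, refl] <- 2 - d[, refl]
  si <- si[keep]
  report <- c(direct = sum(direct), swapped = sum(swapped),
              strand_flipped = sum(flipD), flipped_swapped = sum(flipS),
              dropped = sum(!keep))
  outSS <- new("SumstatsTable", variants = sv[si, , drop = FALSE],
               source = ss@source, build = ss@build)
  outG <- new("GenotypeMatrix", dosages = d,
              variants = sv[si, c("chrom", "pos", "ref", "alt")])
  list(sumstats = outSS, genotypes = outG, report = report)
}

#' Read a cell-by-peak accessibility matrix
#'
#' Loads a MatrixMarket coordinate file together with its BED peak intervals,
#' barcode list and optional cell-type labels into a [CellPeakMatrix-class].
#' Orientation is auto-detected from the dimensions (cells x peaks is
#' canonical); BED lines with start >= end are rejected (their matrix columns
#' are dropped with a warning).
#'
#' @param mtxPath MatrixMarket (.mtx) coordinate file.
#' @param peaksBed BED3(+name) peak intervals, 0-based half-open.
#' @param barcodesPath one barcode per line.
#' @param labelsPath optional TSV with columns barcode, cell_type.
#' @param orientation "auto", "cells_x_peaks" or "peaks_x_cells".
#' @return a [CellPeakMatrix-class].
#' @export
readCellPeakMatrix <- function(mtxPath, peaksBed, barcodesPath,
                               labelsPath = NULL,
                               orientation = c("auto", "cells_x_peaks",
                                               "peaks_x_cells")) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(mtxPath)
  m <- methods::as(m, "CsparseMatrix")
  bc <- readLines(barcodesPath)
  bed <- read.delim(peaksBed, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  ids <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    paste0("peak_", seq_len(nrow(bed)))
  nC <- length(bc); nP <- nrow(bed)
  if (orientation == "auto") {
    orientation <- if (nrow(m) == nC && ncol(m) == nP) "cells_x_peaks"
      else if (nrow(m) == nP && ncol(m) == nC) "peaks_x_cells"
      else stop(sprintf(
        "dimension mismatch: matrix %d x %d vs %d barcodes and %d peaks",
        nrow(m), ncol(m), nC, nP))
  }
  if (orientation == "peaks_x_cells") m <- Matrix::t(m)
  if (nrow(m) != nC || ncol(m) != nP)
    stop(sprintf(
      "dimension mismatch: matrix %d x %d vs %d barcodes and %d peaks",
      nrow(m), ncol(m), nC, nP))
  ok <- bed$start < bed$end
  if (any(!ok)) {
    warning(sprintf("%d BED interval(s) with start >= end rejected", sum(!ok)))
    bed <- bed[ok, , drop = FALSE]; ids <- ids[ok]
    m <- m[, ok, drop = FALSE]
  }
  peaks <- GenomicRanges::GRanges(
    .normChrom(bed$chrom),
    IRanges::IRanges(start = bed$start + 1L, end = bed$end))
  names(peaks) <- ids
  dimnames(m) <- list(bc, ids)
  labels <- character(0)
  if (!is.null(labelsPath)) {
    lab <- read.delim(labelsPath, header = TRUE, stringsAsFactors = FALSE)
    labels <- lab$cell_type[match(bc, lab$barcode)]
    if (anyNA(labels)) stop("labels file does not cover all barcodes")
  }
  new("CellPeakMatrix", counts = m, peaks = peaks, cellType = labels)
}

#' Assign variants to peaks
#'
#' Maps each variant to the peaks containing it. A variant at 1-based
#' position q belongs to a 0-based half-open peak [start, end) iff
#' start <= q-1 < end.
#'
#' @param ss a [SumstatsTable-class] (or any object with a variant table).
#' @param peaks GRanges of peaks (as stored in a [CellPeakMatrix-class]).
#' @return sparse logical membership matrix, variants x peaks.
#' @export
assignVariantsToPeaks <- function(ss, peaks) {
  v <- variantTable(ss)
  gv <- GenomicRanges::GRanges(.normChrom(v$chrom),
                               IRanges::IRanges(v$pos, width = 1L))
  ov <- GenomicRanges::findOverlaps(gv, peaks)
  Matrix::sparseMatrix(i = S4Vectors::queryHits(ov),
                       j = S4Vectors::subjectHits(ov),
                       x = TRUE, dims = c(nrow(v), length(peaks)),
                       dimnames = list(.variantKey(v), names(peaks)))
}
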